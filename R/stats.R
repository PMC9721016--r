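#' @title Statistical layer for fiber degradation profiles
#' @description Group comparisons, stratified PERMANOVA, a repeated-holdout
#'   random-forest harness, the in vitro agreement permutation test, and the
#'   country-level t-statistic matrix, all over samples-by-features profile
#'   matrices with a sample metadata table.
#' @name ifdp-stats
NULL

check_metadata <- function(profile, metadata) {
  stopifnot(is.matrix(profile), "sample_id" %in% names(metadata))
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id(s) in metadata", call. = FALSE)
  }
  if (!all(rownames(profile) %in% metadata$sample_id)) {
    stop("profile rows missing from metadata: ",
         paste(setdiff(rownames(profile), metadata$sample_id), collapse = ", "),
         call. = FALSE)
  }
  metadata[match(rownames(profile), metadata$sample_id), , drop = FALSE]
}

#' Shannon diversity of a profile row
#'
#' @param x Non-negative numeric vector (one sample), not all zero.
#' @param base Logarithm base (default 2, i.e. bits).
#' @return Shannon index of the relative abundances.
#' @export
shannon_diversity <- function(x, base = 2) {
  stopifnot(is.numeric(x), all(x >= 0))
  if (sum(x) == 0) stop("all-zero row: diversity undefined", call. = FALSE)
  unname(vegan::diversity(x, index = "shannon") / log(base))
}

#' Two-group Mann-Whitney volcano test
#'
#' Per feature, a two-sided Mann-Whitney U test between the two groups and a
#' log2 fold change of group means with a pseudocount (half the smallest
#' nonzero value in the profile by default). P values are adjusted across
#' features (Benjamini-Hochberg by default).
#'
#' @param profile Samples x features matrix.
#' @param metadata data.frame with `sample_id` and the grouping column.
#' @param group_col Name of the grouping column (must have exactly 2 levels,
#'   each with >= 2 samples).
#' @param correction Method for [stats::p.adjust()].
#' @param pseudocount Pseudocount for the fold change; default half the
#'   smallest nonzero profile value.
#' @return data.frame with `feature`, `log2_fold_change`, `p_raw`,
#'   `p_adjusted`, `direction` (sign of the fold change, group1 vs group2).
#' @export
volcano_group_test <- function(profile, metadata, group_col,
                               correction = "BH", pseudocount = NULL) {
  md <- check_metadata(profile, metadata)
  g <- factor(md[[group_col]])
  if (nlevels(g) != 2) {
    stop("expected exactly 2 groups in '", group_col, "' (got ", nlevels(g),
         "); for more groups run pairwise comparisons", call. = FALSE)
  }
  if (any(table(g) < 2)) stop("each group needs >= 2 samples", call. = FALSE)
  if (is.null(pseudocount)) {
    nz <- profile[profile > 0]
    pseudocount <- if (length(nz) > 0) min(nz) / 2 else 0.5
  }
  i1 <- g == levels(g)[1]
  res <- lapply(colnames(profile), function(f) {
    x1 <- profile[i1, f]; x2 <- profile[!i1, f]
    p <- suppressWarnings(stats::wilcox.test(x1, x2, exact = NULL,
                                             alternative = "two.sided"))$p.value
    lfc <- log2((mean(x1) + pseudocount) / (mean(x2) + pseudocount))
    data.frame(feature = f, log2_fold_change = lfc, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = correction)
  out$direction <- sign(out$log2_fold_change)
  out
}

# PERMANOVA pseudo-F (Anderson 2001) from a squared-distance matrix.
permanova_f <- function(d2, labels) {
  n <- length(labels)
  a <- length(unique(labels))
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (lev in unique(labels)) {
    i <- labels == lev
    ssw <- ssw + sum(d2[i, i]) / (2 * sum(i))
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' PERMANOVA with restricted (cluster-sampled) label permutations
#'
#' Computes the PERMANOVA pseudo-F on Euclidean distances of the principal
#' components of the profile (all components by default, which is equivalent
#' to Euclidean distance on the centered profile), and a permutation p-value
#' under one of three null-label schemes:
#' \describe{
#'   \item{none}{labels permuted freely across samples (ordinary PERMANOVA);}
#'   \item{cluster_by_species}{the species-to-label map is permuted, so all
#'     samples of a species always carry the same label (cluster sampling);}
#'   \item{within_class}{labels are permuted only among samples sharing a
#'     phylogeny class (stratified permutation).}
#' }
#' The p-value uses the add-one correction
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm), so it is never zero.
#'
#' @param profile Samples x features matrix.
#' @param metadata data.frame with `sample_id`, the label column and (as
#'   needed) the species / phylogeny-class columns.
#' @param label_col Column with the group labels being tested.
#' @param strata_mode One of "none", "cluster_by_species", "within_class".
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @param species_col,class_col Metadata columns used by the two restricted
#'   schemes.
#' @param n_components Optionally use only the top-k principal components.
#' @return List with `F`, `p`, `n_perm`, `strata_mode`.
#' @export
permanova_stratified <- function(profile, metadata, label_col,
                                 strata_mode = c("none", "cluster_by_species",
                                                 "within_class"),
                                 n_perm = 999, seed = 1L,
                                 species_col = "species",
                                 class_col = "phylo_class",
                                 n_components = NULL) {
  strata_mode <- match.arg(strata_mode)
  md <- check_metadata(profile, metadata)
  labels <- as.character(md[[label_col]])
  if (length(unique(labels)) < 2) stop("need >= 2 labels", call. = FALSE)
  X <- stats::prcomp(profile, center = TRUE, scale. = FALSE)$x
  if (!is.null(n_components)) X <- X[, seq_len(n_components), drop = FALSE]
  d2 <- as.matrix(stats::dist(X))^2
  f_obs <- permanova_f(d2, labels)

  gen <- switch(strata_mode,
    none = function() sample(labels),
    cluster_by_species = {
      species <- as.character(md[[species_col]])
      sp_lab <- tapply(labels, species, function(x) {
        u <- unique(x)
        if (length(u) > 1) {
          warning("label varies within a species cluster; using the first",
                  call. = FALSE)
        }
        u[1]
      })
      sp_names <- names(sp_lab)
      function() {
        new_map <- stats::setNames(sample(as.character(sp_lab)), sp_names)
        unname(new_map[species])
      }
    },
    within_class = {
      cls <- as.character(md[[class_col]])
      for (cl in unique(cls)) {
        if (length(unique(labels[cls == cl])) < 2) {
          warning("stratum '", cl, "' carries a single label; ",
                  "it contributes no permutation variability", call. = FALSE)
        }
      }
      function() {
        out <- labels
        for (cl in unique(cls)) {
          i <- cls == cl
          out[i] <- sample(labels[i])
        }
        out
      }
    }
  )
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    permanova_f(d2, gen())
  }, numeric(1)))
  list(F = f_obs, p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       n_perm = n_perm, strata_mode = strata_mode)
}

#' Repeated-holdout random-forest prediction harness
#'
#' Trains a random forest (default hyperparameters) for `n_iter` iterations.
#' Each iteration splits the data into train and validation sets with
#' `val_frac` of the samples held out, the validation set class-balanced
#' between the two groups, and scores ROC-AUC on the validation set. A
#' different seed (`seed_base + i`) is used per iteration.
#'
#' @param profile Samples x features matrix.
#' @param metadata data.frame with `sample_id` and the binary label column.
#' @param label_col Binary label column.
#' @param n_iter Number of train/validation iterations.
#' @param val_frac Fraction of the data held out for validation.
#' @param seed_base Base seed; iteration i uses `seed_base + i`.
#' @return List with `auc` (per-iteration ROC-AUC), `mean_auc`, and
#'   `mean_roc` (mean true-positive rate over a fixed false-positive grid).
#' @export
rf_group_prediction <- function(profile, metadata, label_col, n_iter = 500,
                                val_frac = 0.4, seed_base = 0L) {
  md <- check_metadata(profile, metadata)
  y <- factor(md[[label_col]])
  if (nlevels(y) != 2) stop("label must be binary", call. = FALSE)
  if (any(table(y) < 2)) stop("each class needs >= 2 samples", call. = FALSE)
  n <- length(y)
  n_val_per_class <- max(1L, round(val_frac * n / 2))
  if (any(table(y) <= n_val_per_class)) {
    stop("classes too small for a balanced validation set of ",
         n_val_per_class, " per class", call. = FALSE)
  }
  fpr_grid <- seq(0, 1, by = 0.01)
  aucs <- numeric(n_iter)
  tpr_sum <- numeric(length(fpr_grid))
  pos <- levels(y)[2]
  for (i in seq_len(n_iter)) {
    sp <- with_seed(seed_base + i, {
      val <- unlist(lapply(levels(y), function(lv) {
        sample(which(y == lv), n_val_per_class)
      }))
      fit <- randomForest::randomForest(profile[-val, , drop = FALSE], y[-val])
      prob <- stats::predict(fit, profile[val, , drop = FALSE], type = "prob")[, pos]
      r <- pROC::roc(response = y[val], predictor = prob, levels = levels(y),
                     direction = "<", quiet = TRUE)
      list(auc = as.numeric(pROC::auc(r)),
           tpr = stats::approx(x = 1 - r$specificities, y = r$sensitivities,
                               xout = fpr_grid, ties = max, rule = 2)$y)
    })
    aucs[i] <- sp$auc
    tpr_sum <- tpr_sum + sp$tpr
  }
  list(auc = aucs, mean_auc = mean(aucs),
       mean_roc = data.frame(fpr = fpr_grid, tpr = tpr_sum / n_iter))
}

#' Agreement between inferred capacity ranks and in vitro growth
#'
#' For every "no growth" entry of the growth matrix, agreement means the
#' clade's inferred capacity ranks lowest or second lowest for that fiber;
#' for every "grows" entry, highest or second highest. Tied scores receive
#' average ranks ("lowest or second lowest" then means rank <= 2) and are
#' flagged. Significance is assessed by independently shuffling each fiber's
#' capacity scores among the clades `n_shuffles` times and counting shuffles
#' with at least the observed agreement (add-one corrected).
#'
#' @param clade_ifdp Clades x fibers capacity matrix.
#' @param growth Clades x fibers character matrix with entries `"grows"`,
#'   `"no_growth"`, `"untested"` (same dimnames as `clade_ifdp`).
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed.
#' @return List with `n_agree_nogrow`, `n_agree_grow`, `p_nogrow`, `p_grow`,
#'   `n_cases_nogrow`, `n_cases_grow`, `ties_flagged`.
#' @export
agreement_permutation_test <- function(clade_ifdp, growth, n_shuffles = 2000,
                                       seed = 1L) {
  stopifnot(is.matrix(clade_ifdp), is.matrix(growth),
            all(dim(clade_ifdp) == dim(growth)))
  if (nrow(clade_ifdp) < 2) stop("need >= 2 clades", call. = FALSE)
  if (!any(growth != "untested")) {
    stop("growth matrix is all untested: nothing to compare", call. = FALSE)
  }
  n_clades <- nrow(clade_ifdp)
  ties <- apply(clade_ifdp, 2, function(x) anyDuplicated(x) > 0)
  if (any(ties)) {
    warning("tied capacity scores in fiber(s): ",
            paste(colnames(clade_ifdp)[ties], collapse = ", "),
            "; average ranks used", call. = FALSE)
  }
  count_agree <- function(scores) {
    r <- apply(scores, 2, rank)  # average ranks for ties; 1 = lowest
    c(nogrow = sum(growth == "no_growth" & r <= 2),
      grow = sum(growth == "grows" & r >= n_clades - 1))
  }
  obs <- count_agree(clade_ifdp)
  perm <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      count_agree(apply(clade_ifdp, 2, sample))
    }, numeric(2))
  })
  list(
    n_agree_nogrow = unname(obs["nogrow"]),
    n_agree_grow = unname(obs["grow"]),
    p_nogrow = (1 + sum(perm["nogrow", ] >= obs["nogrow"])) / (1 + n_shuffles),
    p_grow = (1 + sum(perm["grow", ] >= obs["grow"])) / (1 + n_shuffles),
    n_cases_nogrow = sum(growth == "no_growth"),
    n_cases_grow = sum(growth == "grows"),
    ties_flagged = names(which(ties))
  )
}

#' Country-versus-rest t-statistic matrix
#'
#' For each country and each fiber, a Welch two-sample t-test of that
#' country's capacity against all other countries pooled. P values are
#' corrected across all country x fiber tests (Bonferroni by default) and a
#' significance mask is returned alongside the t-statistic matrix, which can
#' be hierarchically clustered to compare national capacity signatures.
#'
#' @param ifdp Samples x fibers capacity matrix.
#' @param metadata data.frame with `sample_id` and the country column.
#' @param country_col Country column name.
#' @param correction Method for [stats::p.adjust()].
#' @param alpha Significance level for the mask.
#' @return List with matrices `t`, `p`, `p_adjusted`, `significant`
#'   (countries x fibers) and `excluded` (countries with < 2 samples).
#' @export
country_tstat_matrix <- function(ifdp, metadata, country_col,
                                 correction = "bonferroni", alpha = 0.05) {
  md <- check_metadata(ifdp, metadata)
  country <- as.character(md[[country_col]])
  tab <- table(country)
  excluded <- names(tab)[tab < 2]
  if (length(excluded) > 0) {
    warning("excluding country(ies) with < 2 samples: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  countries <- sort(names(tab)[tab >= 2])
  if (length(countries) < 2) stop("need >= 2 countries", call. = FALSE)
  tmat <- pmat <- matrix(NA_real_, length(countries), ncol(ifdp),
                         dimnames = list(countries, colnames(ifdp)))
  for (co in countries) {
    i <- country == co
    for (f in colnames(ifdp)) {
      tt <- stats::t.test(ifdp[i, f], ifdp[!i, f], var.equal = FALSE)
      tmat[co, f] <- unname(tt$statistic)
      pmat[co, f] <- tt$p.value
    }
  }
  padj <- matrix(stats::p.adjust(pmat, method = correction),
                 nrow = nrow(pmat), dimnames = dimnames(pmat))
  list(t = tmat, p = pmat, p_adjusted = padj,
       significant = padj < alpha, excluded = excluded)
}

#' Ordination and hierarchical clustering of profiles
#'
#' PCA (deterministic, via [stats::prcomp()]) or average-linkage hierarchical
#' clustering on Euclidean distances, for embedding profiles or clustering
#' t-statistic matrices.
#'
#' @param x Samples (or countries) x features matrix.
#' @param method `"pca"` or `"hclust"`.
#' @param n_components Number of principal components to return.
#' @return For `"pca"`: list with `scores`, `sdev`, `explained_var`. For
#'   `"hclust"`: an `hclust` object.
#' @export
ordination_and_clustering <- function(x, method = c("pca", "hclust"),
                                      n_components = 2) {
  method <- match.arg(method)
  stopifnot(is.matrix(x))
  if (method == "pca") {
    if (n_components > min(dim(x))) {
      stop("fewer samples/features than requested components", call. = FALSE)
    }
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = pc$x[, seq_len(n_components), drop = FALSE],
         sdev = pc$sdev, explained_var = ev)
  } else {
    stats::hclust(stats::dist(x), method = "average")
  }
}
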