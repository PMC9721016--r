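# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# Brute-force enzyme-fiber interaction: explicit double loop over pairs.
brute_force_interaction <- function(fibers, enzymes) {
  M <- matrix(0L, nrow(enzymes), nrow(fibers),
              dimnames = list(enzymes$ec, fibers$abbreviation))
  for (i in seq_len(nrow(enzymes))) {
    for (j in seq_len(nrow(fibers))) {
      M[i, j] <- as.integer(
        length(intersect(enzymes$bonds[[i]], fibers$bonds[[j]])) > 0)
    }
  }
  M
}

# Random small catalog over a random bond pool.
random_small_catalog <- function(seed) {
  set.seed(seed)
  sugars <- c("Glc", "Fru", "Gal", "Xyl", "Ara", "Man")
  pool <- unique(replicate(12, paste0(
    sample(c("a", "b"), 1), sample(1:6, 1), "-", sample(1:6, 1), ":",
    sample(sugars, 1), "-", sample(sugars, 1))))
  nf <- sample(2:5, 1); ne <- sample(2:6, 1)
  fibers <- data.frame(
    name = paste0("fiber", seq_len(nf)),
    abbreviation = paste0("F", seq_len(nf)),
    solubility = NA_character_, stringsAsFactors = FALSE)
  fibers$bonds <- I(lapply(seq_len(nf), function(i)
    sample(pool, sample(1:3, 1))))
  enzymes <- data.frame(ec = paste0("3.2.1.", seq_len(ne)),
                        stringsAsFactors = FALSE)
  enzymes$bonds <- I(lapply(seq_len(ne), function(i)
    sample(pool, sample(1:3, 1))))
  list(fibers = fibers, enzymes = enzymes)
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  vals <- c(x, y)
  u_of <- function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  u_all <- apply(utils::combn(n, n1), 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  }
  out
}

# Exhaustive agreement-test null for small instances (<= 4 clades, <= 2
# fibers): enumerate every joint per-fiber permutation of the scores.
agreement_exact_p <- function(clade_ifdp, growth) {
  n <- nrow(clade_ifdp); nf <- ncol(clade_ifdp)
  count_agree <- function(scores) {
    r <- apply(scores, 2, rank)
    c(nogrow = sum(growth == "no_growth" & r <= 2),
      grow = sum(growth == "grows" & r >= n - 1))
  }
  obs <- count_agree(clade_ifdp)
  P <- all_perms(seq_len(n))
  combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(P))), nf)))
  counts <- apply(combos, 1, function(sel) {
    m <- clade_ifdp
    for (j in seq_len(nf)) m[, j] <- clade_ifdp[P[sel[j], ], j]
    count_agree(m)
  })
  c(p_nogrow = mean(counts["nogrow", ] >= obs["nogrow"]),
    p_grow = mean(counts["grow", ] >= obs["grow"]))
}
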