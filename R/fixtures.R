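#' Self-consistent toy fixtures with known ground truth
#'
#' Three fixture kinds, each small enough that the expected outputs are
#' analytically known:
#' \describe{
#'   \item{minimal}{2 fibers, 3 ECs, 2 samples; the expected capacity profile
#'     equals the hand-computed profile-by-matrix product (returned as
#'     `expected_ifdp`).}
#'   \item{two_group_cohort}{20 samples in two groups of 10 with one planted
#'     enzyme shift (4x on EC 3.2.1.7, which maps to inulin only), so the
#'     volcano test should flag exactly the planted fiber.}
#'   \item{clades_growth}{a 4-clade x 6-fiber capacity matrix and a growth
#'     matrix with planted full agreement (per fiber, the lowest-ranked clade
#'     marked no-growth and the highest-ranked marked growth), for the
#'     agreement permutation test.}
#' }
#'
#' @param kind One of `"minimal"`, `"two_group_cohort"`, `"clades_growth"`.
#' @param seed Integer seed for the stochastic fixtures.
#' @return A list; components depend on `kind` (see Details).
#' @export
make_toy_fixture <- function(kind = c("minimal", "two_group_cohort",
                                      "clades_growth"), seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
         minimal = fixture_minimal(),
         two_group_cohort = fixture_two_group(seed),
         clades_growth = fixture_clades_growth(seed))
}

make_catalog_df <- function(fibers, enzymes) {
  list(
    fibers = data.frame(
      name = names(fibers), abbreviation = names(fibers),
      solubility = NA_character_,
      bonds = I(unname(fibers)), stringsAsFactors = FALSE),
    enzymes = data.frame(
      ec = names(enzymes), bonds = I(unname(enzymes)),
      stringsAsFactors = FALSE)
  )
}

fixture_minimal <- function() {
  cat <- make_catalog_df(
    fibers = list(Cel = "b1-4:Glc-Glc",
                  Inu = c("b2-1:Fru-Fru", "b1-2:Glc-Fru")),
    enzymes = list(`3.2.1.4` = "b1-4:Glc-Glc",
                   `3.2.1.7` = "b2-1:Fru-Fru",
                   `3.2.1.26` = c("b1-2:Glc-Fru", "b2-1:Fru-Fru"))
  )
  M <- build_interaction_matrix(cat$fibers, cat$enzymes)
  ffp <- matrix(c(2, 3, 0,
                  1, 0, 4), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"),
                                c("3.2.1.4", "3.2.1.7", "3.2.1.26")))
  expected <- matrix(c(2, 3,
                       1, 4), nrow = 2, byrow = TRUE,
                     dimnames = list(c("s1", "s2"), c("Cel", "Inu")))
  list(catalog = cat, M = M, ffp = ffp, expected_ifdp = expected)
}

fixture_two_group <- function(seed) {
  cat <- make_catalog_df(
    fibers = list(Cel = "b1-4:Glc-Glc", Inu = "b2-1:Fru-Fru",
                  Xyl = "b1-4:Xyl-Xyl", Pec = "a1-4:GalA-GalA",
                  Man = "b1-4:Man-Man"),
    enzymes = list(`3.2.1.4` = "b1-4:Glc-Glc", `3.2.1.7` = "b2-1:Fru-Fru",
                   `3.2.1.8` = "b1-4:Xyl-Xyl", `3.2.1.15` = "a1-4:GalA-GalA",
                   `3.2.1.25` = "b1-4:Man-Man",
                   `3.2.1.6` = c("b1-3:Glc-Glc", "b1-4:Glc-Glc"))
  )
  M <- build_interaction_matrix(cat$fibers, cat$enzymes)
  n_per <- 10L
  samples <- sprintf("s%02d", seq_len(2 * n_per))
  ecs <- cat$enzymes$ec
  ffp <- with_seed(seed, {
    base <- matrix(stats::rpois(2 * n_per * length(ecs), lambda = 100),
                   nrow = 2 * n_per,
                   dimnames = list(samples, ecs))
    # planted 4x shift on the inulin-specific enzyme in group B
    base[(n_per + 1):(2 * n_per), "3.2.1.7"] <-
      stats::rpois(n_per, lambda = 400)
    base
  })
  metadata <- data.frame(
    sample_id = samples,
    group = rep(c("A", "B"), each = n_per),
    stringsAsFactors = FALSE
  )
  list(catalog = cat, M = M, ffp = ffp, metadata = metadata,
       planted_fiber = "Inu", planted_group = "B")
}

fixture_clades_growth <- function(seed) {
  clades <- c("A", "B", "C", "D")
  fibers <- c("Inu", "AX", "BG", "XG", "GluM", "Pec")
  ifdp <- with_seed(seed, {
    m <- matrix(0, 4, 6, dimnames = list(clades, fibers))
    for (j in seq_len(6)) m[, j] <- sample(c(1, 2, 3, 4) * 10)
    m
  })
  growth <- matrix("untested", 4, 6, dimnames = list(clades, fibers))
  # plant full agreement: per fiber, a no-growth case at the lowest-ranked
  # clade and a growth case at the highest-ranked clade (6 cases each, so
  # full agreement is significant under the shuffle null: ~0.5^6)
  for (j in 1:6) {
    growth[which.min(ifdp[, j]), j] <- "no_growth"
    growth[which.max(ifdp[, j]), j] <- "grows"
  }
  list(clade_ifdp = ifdp, growth = growth)
}
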