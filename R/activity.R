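#' Transcriptional activity-center scores
#'
#' A gene sits in an activity center when its interaction neighborhood
#' is both strongly co-expressed with it and differentially expressed.
#' For gene `i` with `N` FPI neighbors `d`, the score is
#' `mean_d(CorrFPI(i, d) * R(d)) * max_d(CorrFPI(i, d) * R(d))`,
#' where `R(d) = -log10(p)` is the neighbor's differential-expression
#' significance. Genes with no neighbors score 0.
#'
#' @param corrfpi Edge-wise co-expression tibble from
#'   [compute_corrfpi()].
#' @param de Differential-expression tibble from
#'   [differential_significance()]; must cover every FPI neighbor of the
#'   scored genes.
#' @param genes Genes to score (default: all genes in `de`).
#' @return An `activity_profile` tibble: `gene`, `n_neighbors`, `R`,
#'   `p` (the gene's own significance, `NA` if the gene is not in
#'   `de`), and `activity_score`.
#' @export
activity_scores <- function(corrfpi, de, genes = de$gene) {
  adj <- corrfpi_adjacency(corrfpi)
  rmap <- setNames(de$R, de$gene)
  score <- vapply(genes, function(g) {
    d <- adj[[g]]
    if (is.null(d) || nrow(d) == 0) return(0)
    rn <- rmap[d$partner]
    if (anyNA(rn)) {
      abort(sprintf("neighbor(s) of '%s' missing from differential-expression results: %s",
                    g, paste(head(d$partner[is.na(rn)], 5), collapse = ", ")))
    }
    prod <- d$mi * unname(rn)
    mean(prod) * max(prod)
  }, 0, USE.NAMES = FALSE)
  n_nb <- vapply(genes, function(g) {
    d <- adj[[g]]
    if (is.null(d)) 0L else nrow(d)
  }, 0L, USE.NAMES = FALSE)
  own <- match(genes, de$gene)
  out <- tibble::tibble(gene = genes, n_neighbors = n_nb,
                        R = de$R[own], p = de$p[own],
                        activity_score = score)
  class(out) <- c("activity_profile", class(out))
  out
}

#' Classify principal regulators from an activity profile
#'
#' Genes whose activity score exceeds the mean score are activity
#' centers ("principal regulators"); those that are themselves
#' differentially expressed (`p <= p_thresh`) are transcriptional
#' (`significant_DE_center`), while high-scoring genes that are not DE
#' themselves are candidate post-translational regulators
#' (`posttranslational_center`) — their neighborhood responds while
#' they do not. The mean is taken over genes with at least one FPI
#' neighbor, since isolated genes carry structural zeros.
#'
#' @param profile `activity_profile` from [activity_scores()].
#' @param p_thresh Own-gene significance threshold (default 0.05).
#' @return The profile with an added `class` column in
#'   `{significant_DE_center, posttranslational_center, none}`.
#' @export
classify_regulators <- function(profile, p_thresh = 0.05) {
  connected <- profile$n_neighbors > 0
  ref <- if (any(connected)) mean(profile$activity_score[connected]) else 0
  cls <- rep("none", nrow(profile))
  high <- profile$activity_score > ref
  cls[high & !is.na(profile$p) & profile$p <= p_thresh] <- "significant_DE_center"
  cls[high & (is.na(profile$p) | profile$p > p_thresh)] <- "posttranslational_center"
  dplyr::mutate(profile, class = cls)
}

#' Resampling stability of the activity-score profile
#'
#' Repeatedly recomputes differential-expression significance on
#' stratified subsamples of the two groups, rebuilds the activity-score
#' profile each round, and reports the mean pairwise squared Pearson
#' correlation between round profiles. Values near 1 indicate that the
#' activity centers do not depend on the particular samples drawn.
#'
#' @param expr Expression matrix (genes x samples).
#' @param group1,group2 Sample id vectors defining the contrast.
#' @param corrfpi Edge co-expression tibble (held fixed across rounds).
#' @param n_rounds Number of resampling rounds (>= 2, default 20).
#' @param subsample Fraction of each group drawn per round (default 0.8).
#' @param seed Integer seed.
#' @return Mean pairwise squared correlation, with the per-round score
#'   matrix in attribute `"profiles"`.
#' @export
activity_stability <- function(expr, group1, group2, corrfpi,
                               n_rounds = 20, subsample = 0.8, seed = 1L) {
  if (n_rounds < 2) abort("n_rounds must be >= 2")
  k1 <- floor(subsample * length(group1))
  k2 <- floor(subsample * length(group2))
  if (k1 < 2 || k2 < 2) {
    abort("groups too small to subsample")
  }
  genes <- rownames(expr)
  profiles <- withr::with_seed(seed, {
    vapply(seq_len(n_rounds), function(i) {
      g1 <- sample(group1, k1)
      g2 <- sample(group2, k2)
      de <- differential_significance(expr, g1, g2)
      activity_scores(corrfpi, de, genes = genes)$activity_score
    }, numeric(length(genes)))
  })
  keep <- apply(profiles, 2, sd) > 0
  if (sum(keep) < 2) abort("activity profiles degenerate across rounds")
  cm <- cor(profiles[, keep, drop = FALSE])
  r2 <- mean(cm[upper.tri(cm)]^2)
  attr(r2, "profiles") <- profiles
  r2
}

#' Write an activity profile to TSV
#'
#' @param profile `activity_profile`, optionally with a `class` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity <- function(profile, path) {
  readr::write_tsv(profile, path, progress = FALSE)
  invisible(path)
}
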