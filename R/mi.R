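#' Mutual-information estimator configuration
#'
#' Mutual information between two expression profiles is estimated by
#' discretizing each profile into `n_bins` bins, forming the joint
#' histogram, and summing `p(d,r) * log(p(d,r) / (p(d) p(r)))` over
#' occupied cells. Equal-frequency binning (the default) makes the
#' estimate invariant under strictly monotone transforms of either
#' profile and gives `MI(x, x)` a closed form (the marginal entropy),
#' which is convenient at cohort sizes around 100-150 samples.
#'
#' @param n_bins Number of bins per profile (>= 2). Default 8.
#' @param binning `"equal_frequency"` (ranks split into bins of near
#'   equal size, ties broken by stable rank order) or `"equal_width"`.
#' @param log_base `"natural"` (MI in nats) or `"2"` (bits).
#' @return An object of class `mi_config`.
#' @export
mi_config <- function(n_bins = 8L, binning = c("equal_frequency", "equal_width"),
                      log_base = c("natural", "2")) {
  binning <- match.arg(binning)
  log_base <- match.arg(log_base)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) abort("n_bins must be an integer >= 2")
  structure(list(n_bins = n_bins, binning = binning, log_base = log_base),
            class = "mi_config")
}

log_div <- function(cfg) if (cfg$log_base == "2") log(2) else 1

#' Discretize a profile per an estimator configuration
#'
#' @param x Numeric vector.
#' @param cfg [mi_config()].
#' @return Integer bin indices in `1:n_bins`.
#' @export
discretize_profile <- function(x, cfg = mi_config()) {
  if (anyNA(x) || any(!is.finite(x))) abort("profile contains non-finite values")
  n <- length(x)
  if (cfg$binning == "equal_frequency") {
    r <- rank(x, ties.method = "first")
    as.integer(ceiling(r * cfg$n_bins / n))
  } else {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(1L, n))
    b <- as.integer(cut(x, breaks = seq(rng[1], rng[2], length.out = cfg$n_bins + 1),
                        include.lowest = TRUE))
    b
  }
}

mi_from_bins <- function(dx, dy, n_bins, divisor) {
  n <- length(dx)
  joint <- tabulate(dx + n_bins * (dy - 1L), nbins = n_bins * n_bins)
  px <- tabulate(dx, nbins = n_bins) / n
  py <- tabulate(dy, nbins = n_bins) / n
  occ <- joint > 0L
  p <- joint[occ] / n
  idx <- which(occ) - 1L
  mi <- sum(p * log(p / (px[idx %% n_bins + 1L] * py[idx %/% n_bins + 1L])))
  mi / divisor
}

#' Mutual information between two expression profiles
#'
#' @param x,y Numeric vectors of equal length (>= 8 observations).
#' @param cfg [mi_config()].
#' @return Nonnegative mutual information in nats (or bits per `cfg`).
#'   Profiles with zero variance carry no information and return 0.
#' @export
mutual_information <- function(x, y, cfg = mi_config()) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 8) abort("profiles must have at least 8 observations")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  mi_from_bins(discretize_profile(x, cfg), discretize_profile(y, cfg),
               cfg$n_bins, log_div(cfg))
}

#' Entropy of a discretized profile
#'
#' The entropy of the binned marginal; equals `mutual_information(x, x)`
#' for a profile with nonzero variance.
#'
#' @inheritParams mutual_information
#' @return Entropy in nats (or bits per `cfg`).
#' @export
profile_entropy <- function(x, cfg = mi_config()) {
  if (sd(x) == 0) return(0)
  p <- tabulate(discretize_profile(x, cfg), nbins = cfg$n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log_div(cfg)
}

#' Mutual information for all row pairs of two matrices
#'
#' Computes `MI(X[i, ], Y[j, ])` for every `(i, j)` with one pass of
#' bin-indicator matrix products, which is much faster than looping
#' when thousands of pairs are needed.
#'
#' @param x,y Numeric matrices with the same number of columns
#'   (profiles in rows, samples in columns).
#' @param cfg [mi_config()].
#' @return A `nrow(x)` x `nrow(y)` matrix of MI values.
#' @export
mi_matrix <- function(x, y, cfg = mi_config()) {
  if (ncol(x) != ncol(y)) abort("x and y must have the same samples")
  n <- ncol(x)
  if (n < 8) abort("profiles must have at least 8 observations")
  B <- cfg$n_bins
  dx <- t(apply(x, 1, discretize_profile, cfg = cfg))
  dy <- t(apply(y, 1, discretize_profile, cfg = cfg))
  if (nrow(x) == 1) dx <- matrix(dx, nrow = 1)
  if (nrow(y) == 1) dy <- matrix(dy, nrow = 1)
  px <- t(apply(dx, 1, tabulate, nbins = B)) / n
  py <- t(apply(dy, 1, tabulate, nbins = B)) / n
  if (nrow(x) == 1) px <- matrix(px, nrow = 1)
  if (nrow(y) == 1) py <- matrix(py, nrow = 1)
  mi <- matrix(0, nrow(x), nrow(y), dimnames = list(rownames(x), rownames(y)))
  for (a in seq_len(B)) {
    ia <- matrix(as.numeric(dx == a), nrow(x), n)
    for (b in seq_len(B)) {
      ib <- matrix(as.numeric(dy == b), nrow(y), n)
      pj <- (ia %*% t(ib)) / n
      denom <- px[, a] %o% py[, b]
      term <- pj * log(pj / denom)
      term[pj == 0] <- 0
      mi <- mi + term
    }
  }
  zx <- apply(x, 1, sd) == 0
  zy <- apply(y, 1, sd) == 0
  mi[zx, ] <- 0
  mi[, zy] <- 0
  mi / log_div(cfg)
}

#' Pearson correlation between two profiles
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("profiles must have at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance profile")
  cor(x, y)
}

#' Per-gene differential-expression significance
#'
#' Two-sample t-test per gene between two disjoint sample groups; the
#' significance score is `R = -log10(p)`, so larger `R` means more
#' significant differential expression. Welch's unequal-variance test is
#' the default; `var_equal = TRUE` gives the pooled-variance test.
#' Genes with zero variance in both groups and equal means get `p = 1`,
#' `R = 0`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param group1,group2 Disjoint character vectors of sample ids, each
#'   of length >= 2.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return A tibble with columns `gene`, `t`, `p`, `R`.
#' @export
differential_significance <- function(expr, group1, group2, var_equal = FALSE) {
  if (length(intersect(group1, group2)) > 0) abort("groups must be disjoint")
  missing <- setdiff(c(group1, group2), colnames(expr))
  if (length(missing) > 0) {
    abort(sprintf("group sample(s) not in expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (length(group1) < 2 || length(group2) < 2) {
    abort("each group needs at least 2 samples")
  }
  x1 <- expr[, group1, drop = FALSE]
  x2 <- expr[, group2, drop = FALSE]
  n1 <- length(group1); n2 <- length(group2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * pt(-abs(tstat), df)
  # degenerate genes: no variance anywhere
  flat <- se == 0
  tstat[flat & m1 == m2] <- 0
  p[flat & m1 == m2] <- 1
  p[flat & m1 != m2] <- .Machine$double.xmin
  tstat[flat & m1 != m2] <- sign(m1 - m2)[flat & m1 != m2] * Inf
  p <- pmax(p, .Machine$double.xmin)
  tibble::tibble(gene = rownames(expr), t = unname(tstat), p = unname(p),
                 R = -log10(unname(p)))
}
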