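#' Elastic-net configuration
#'
#' Defaults follow standard practice for expression-on-network
#' regressions: mixing parameter `alpha = 0.5` (midway between ridge
#' and lasso, retaining correlated predictors while still sparsifying),
#' a 100-value lambda path, and ten-fold cross-validation with the
#' penalty chosen at minimum mean squared error.
#'
#' @param alpha Elastic-net mixing in `[0, 1]` (0 = ridge, 1 = lasso).
#' @param n_lambda Length of the lambda path (default 100); the path is
#'   log-spaced from the solver's `lambda_max` down to
#'   `lambda_max * lambda_min_ratio`.
#' @param lambda_min_ratio Smallest lambda as a fraction of
#'   `lambda_max` (default 1e-3).
#' @param n_folds Cross-validation folds (default 10).
#' @param standardize Standardize predictors to unit variance before
#'   fitting (coefficients are reported on the original scale).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.5, n_lambda = 100L, lambda_min_ratio = 1e-3,
                        n_folds = 10L, standardize = TRUE, seed = 1L) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (n_lambda < 2) abort("n_lambda must be >= 2")
  if (n_folds < 2) abort("n_folds must be >= 2")
  structure(list(alpha = alpha, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_folds = as.integer(n_folds),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "enet_config")
}

#' Build the genes-x-miRNAs design matrix from an influence network
#'
#' Column `j` holds the influence score of miRNA `j` on each gene of
#' the universe (0 where the pair is not in the network). miRNAs whose
#' column is entirely zero are dropped with a message.
#'
#' @param net `mirti_network` tibble (or any tibble with `mirna`,
#'   `target` and a score column named `mirti`).
#' @param gene_universe Ordered character vector of gene ids (the
#'   regression observations).
#' @return Numeric matrix (genes x miRNAs) with dimnames.
#' @export
build_design <- function(net, gene_universe) {
  if (length(gene_universe) == 0) abort("empty gene universe")
  mirs <- sort(unique(net$mirna))
  x <- matrix(0, length(gene_universe), length(mirs),
              dimnames = list(gene_universe, mirs))
  keep <- net$target %in% gene_universe
  x[cbind(match(net$target[keep], gene_universe),
          match(net$mirna[keep], mirs))] <- net$mirti[keep]
  zero <- colSums(x != 0) == 0
  if (any(zero)) {
    inform(sprintf("dropping %d all-zero design column(s): %s", sum(zero),
                   paste(head(colnames(x)[zero], 5), collapse = ", ")))
    x <- x[, !zero, drop = FALSE]
  }
  x
}

# seeded fold assignment over the observations (genes)
make_foldid <- function(n, n_folds, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

fit_enet_column <- function(x, y, cfg, foldid) {
  if (sd(y) == 0) {
    # a constant response carries no signal: full shrinkage
    return(list(beta = setNames(numeric(ncol(x)), colnames(x)),
                lambda = NA_real_, cv_mse = 0, nonzero = 0L, path = NULL))
  }
  base <- glmnet::glmnet(x, y, alpha = cfg$alpha,
                         standardize = cfg$standardize, nlambda = 5)
  lmax <- base$lambda[1]
  path <- exp(seq(log(lmax), log(lmax * cfg$lambda_min_ratio),
                  length.out = cfg$n_lambda))
  cv <- glmnet::cv.glmnet(x, y, alpha = cfg$alpha, lambda = path,
                          foldid = foldid, standardize = cfg$standardize)
  i <- which.min(cv$cvm)
  beta <- as.numeric(coef(cv$glmnet.fit, s = cv$lambda[i]))[-1]
  list(beta = setNames(beta, colnames(x)), lambda = cv$lambda[i],
       cv_mse = cv$cvm[i], nonzero = sum(beta != 0), path = cv)
}

#' Per-patient miRNA influence by elastic-net regression
#'
#' Models each patient's gene expression profile as a linear
#' combination of the influence of the miRNAs on their targets: the
#' response is the patient's expression over the gene universe, the
#' predictors are the influence-network design columns, and the fit is
#' an elastic net with the penalty chosen by cross-validated minimum
#' MSE over the lambda path. Each patient is fit independently; the
#' coefficients form the miRNA-patient influence matrix. Fold
#' assignment is over genes (the regression observations) and shared
#' across patients, so results do not depend on patient order.
#'
#' @param design Genes-x-miRNAs matrix from [build_design()].
#' @param expr Expression matrix covering the design's gene rows
#'   (patients in columns).
#' @param cfg [enet_config()].
#' @return An object of class `influence_fit` with elements `beta`
#'   (miRNAs x patients coefficient matrix), `lambda`, `cv_mse`,
#'   `nonzero` (per patient), `alpha`, `config`.
#' @export
fit_patient_influence <- function(design, expr, cfg = enet_config()) {
  missing <- setdiff(rownames(design), rownames(expr))
  if (length(missing) > 0) {
    abort(sprintf("design gene(s) missing from expression: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (nrow(design) < 2 * cfg$n_folds) {
    abort("fewer genes than twice the number of CV folds")
  }
  y_all <- expr[rownames(design), , drop = FALSE]
  foldid <- make_foldid(nrow(design), cfg$n_folds, cfg$seed)
  fits <- lapply(seq_len(ncol(y_all)), function(j) {
    fit_enet_column(design, y_all[, j], cfg, foldid)
  })
  influence_fit(fits, colnames(y_all), colnames(design), cfg)
}

#' miRNA influence on the activity-score profile
#'
#' Same regression contract as [fit_patient_influence()], with the
#' per-gene activity score as the single response. miRNAs with positive
#' coefficients positively explain the transcriptional activity of
#' gene neighborhoods; negative coefficients indicate a depressive
#' association.
#'
#' @param design Genes-x-miRNAs matrix from [build_design()].
#' @param profile `activity_profile` covering the design's gene rows.
#' @param cfg [enet_config()].
#' @return An `influence_fit` with the single column `"activity"`.
#' @export
fit_activity_influence <- function(design, profile, cfg = enet_config()) {
  idx <- match(rownames(design), profile$gene)
  if (anyNA(idx)) {
    abort(sprintf("design gene(s) missing from activity profile: %s",
                  paste(head(rownames(design)[is.na(idx)], 5), collapse = ", ")))
  }
  if (nrow(design) < 2 * cfg$n_folds) {
    abort("fewer genes than twice the number of CV folds")
  }
  y <- profile$activity_score[idx]
  foldid <- make_foldid(nrow(design), cfg$n_folds, cfg$seed)
  fit <- fit_enet_column(design, y, cfg, foldid)
  influence_fit(list(fit), "activity", colnames(design), cfg)
}

influence_fit <- function(fits, columns, mirnas, cfg) {
  beta <- vapply(fits, `[[`, numeric(length(mirnas)), "beta")
  beta <- matrix(beta, nrow = length(mirnas),
                 dimnames = list(mirnas, columns))
  structure(list(
    beta = beta,
    lambda = setNames(vapply(fits, `[[`, 0, "lambda"), columns),
    cv_mse = setNames(vapply(fits, `[[`, 0, "cv_mse"), columns),
    nonzero = setNames(vapply(fits, `[[`, 0L, "nonzero"), columns),
    alpha = cfg$alpha, config = cfg), class = "influence_fit")
}

#' @export
print.influence_fit <- function(x, ...) {
  cat(sprintf("Elastic-net influence fit: %d miRNAs x %d response column(s)\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  alpha = %g; median nonzero coefficients = %g\n",
              x$alpha, stats::median(x$nonzero)))
  invisible(x)
}

#' Tidy an influence fit
#'
#' @param x An `influence_fit`.
#' @param ... Unused.
#' @return Long tibble with columns `mirna`, `column` (patient id or
#'   `"activity"`), `beta`.
#' @method tidy influence_fit
#' @export
tidy.influence_fit <- function(x, ...) {
  tibble::tibble(
    mirna = rep(rownames(x$beta), times = ncol(x$beta)),
    column = rep(colnames(x$beta), each = nrow(x$beta)),
    beta = as.numeric(x$beta))
}

#' Glance at an influence fit
#'
#' @param x An `influence_fit`.
#' @param ... Unused.
#' @return One-row tibble summarising the fit.
#' @method glance influence_fit
#' @export
glance.influence_fit <- function(x, ...) {
  tibble::tibble(n_mirnas = nrow(x$beta), n_columns = ncol(x$beta),
                 alpha = x$alpha,
                 mean_nonzero = mean(x$nonzero),
                 mean_cv_mse = mean(x$cv_mse),
                 median_lambda = stats::median(x$lambda))
}

#' Per-column fit summary
#'
#' @param fit An `influence_fit`.
#' @return Tibble with `column`, `lambda`, `cv_mse`, `nonzero`.
#' @export
influence_summary <- function(fit) {
  tibble::tibble(column = colnames(fit$beta), lambda = unname(fit$lambda),
                 cv_mse = unname(fit$cv_mse), nonzero = unname(fit$nonzero))
}

#' Heatmap of an influence matrix
#'
#' @param object An `influence_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot influence_fit
#' @export
autoplot.influence_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$mirna,
                                   fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "beta") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Write an influence matrix to TSV
#'
#' Writes the coefficient matrix (miRNAs as rows) and a sidecar with
#' per-column lambda and cross-validated MSE.
#'
#' @param fit An `influence_fit`.
#' @param path Output path for the matrix; the sidecar gets the suffix
#'   `.fitinfo.tsv`.
#' @return `path`, invisibly.
#' @export
write_influence <- function(fit, path) {
  df <- tibble::as_tibble(fit$beta, rownames = "mirna")
  readr::write_tsv(df, path, progress = FALSE)
  readr::write_tsv(influence_summary(fit),
                   paste0(path, ".fitinfo.tsv"), progress = FALSE)
  invisible(path)
}
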