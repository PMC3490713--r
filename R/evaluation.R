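#' Two-group risk stratification by hierarchical clustering
#'
#' Agglomerative clustering of samples cut at two clusters. The default
#' pairing — Euclidean distance with Ward linkage — targets compact
#' groups separated by mean shifts, which is how risk signatures
#' manifest in influence and expression features; correlation distance
#' (`1 - Pearson` between sample profiles) with average linkage is
#' available for shape-based grouping. The cluster with the larger
#' mean feature value is labeled `"high"`, the other `"low"`; ties
#' break by sample order.
#'
#' @param features Samples-x-features numeric matrix with sample row
#'   names, or a data frame whose first column holds sample ids.
#' @param method Linkage method (default `"ward.D2"`).
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @return A tibble with columns `sample`, `group` (`"high"`/`"low"`).
#' @export
cluster_two_groups <- function(features, method = "ward.D2",
                               distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  features <- as_feature_matrix(features)
  if (nrow(features) < 4 || ncol(features) < 2) {
    abort("need at least 4 samples and 2 features")
  }
  if (sd(as.numeric(features)) == 0) abort("constant feature matrix")
  if (distance == "correlation") {
    rv <- apply(features, 1, sd)
    if (any(rv == 0)) {
      abort("sample(s) with constant profile cannot be clustered by correlation distance")
    }
    d <- as.dist(1 - cor(t(features)))
  } else {
    d <- stats::dist(features)
  }
  cl <- cutree(hclust(d, method = method), k = 2)
  means <- tapply(rowMeans(features), cl, mean)
  high <- as.integer(names(means)[which.max(means)])
  tibble::tibble(sample = rownames(features),
                 group = unname(ifelse(cl == high, "high", "low")))
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    ids <- as.character(features[[1]])
    m <- as.matrix(features[, -1, drop = FALSE])
    rownames(m) <- ids
    features <- m
  }
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("sample", seq_len(nrow(features)))
  }
  storage.mode(features) <- "double"
  features
}

#' Log-rank test and hazard ratio between two risk groups
#'
#' Standard two-group log-rank test plus a hazard ratio from a
#' single-covariate Cox proportional-hazards fit on the group
#' indicator (high vs low). Swapping the group labels inverts the
#' hazard ratio and leaves the chi-square unchanged. If either group
#' has no events the result is flagged `degenerate`.
#'
#' @param split Tibble with columns `sample`, `group` from
#'   [cluster_two_groups()] (or any high/low assignment).
#' @param ann Annotation tibble with `sample`, `time`, `event`.
#' @return One-row tibble: `n_high`, `n_low`, `chisq`, `p`,
#'   `hazard_ratio`, `hr_low`, `hr_high` (95% CI), `degenerate`.
#' @export
logrank_hr <- function(split, ann) {
  missing <- setdiff(split$sample, ann$sample)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) missing from survival annotations: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  df <- dplyr::inner_join(split, ann, by = "sample")
  df <- df[!is.na(df$time) & !is.na(df$event), , drop = FALSE]
  if (length(unique(df$group)) != 2) abort("need two nonempty groups")
  grp <- factor(df$group, levels = c("low", "high"))
  events <- tapply(df$event, grp, sum)
  degenerate <- any(events == 0)
  sv <- survival::Surv(df$time, df$event)
  sd_ <- survival::survdiff(sv ~ grp)
  chisq <- unname(sd_$chisq)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(sv ~ grp)
  hr <- unname(exp(coef(cx)))
  ci <- exp(stats::confint(cx))
  tibble::tibble(n_high = sum(df$group == "high"),
                 n_low = sum(df$group == "low"),
                 chisq = chisq, p = p, hazard_ratio = hr,
                 hr_low = ci[1], hr_high = ci[2],
                 degenerate = degenerate)
}

#' Cross-validated linear-SVM classification accuracy
#'
#' Stratified k-fold cross-validation of a linear-kernel support vector
#' machine (cost 1). Features are z-scored with the training fold's
#' statistics only; constant features are left unscaled. Returns the
#' mean fold accuracy.
#'
#' @param features Samples-x-features matrix (or data frame with sample
#'   ids in the first column).
#' @param labels Binary labels (factor, character, or logical), one per
#'   sample.
#' @param n_folds Folds (default 5); each class must have at least
#'   `n_folds` members.
#' @param seed Integer seed for fold assignment.
#' @param cost SVM cost parameter (default 1).
#' @return Mean fold accuracy in `[0, 1]`, with per-fold accuracies in
#'   attribute `"folds"`.
#' @export
svm_cv_accuracy <- function(features, labels, n_folds = 5, seed = 1L,
                            cost = 1) {
  features <- as_feature_matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2) abort("labels must be binary")
  if (length(labels) != nrow(features)) {
    abort("one label per sample required")
  }
  if (min(table(labels)) < n_folds) {
    abort("each class needs at least n_folds members")
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  acc <- vapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    mu <- colMeans(features[tr, , drop = FALSE])
    sg <- apply(features[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- scale(features[tr, , drop = FALSE], center = mu, scale = sg)
    xte <- scale(features[!tr, , drop = FALSE], center = mu, scale = sg)
    fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    mean(predict(fit, xte) == labels[!tr])
  }, 0)
  out <- mean(acc)
  attr(out, "folds") <- acc
  out
}

#' Kaplan-Meier curves for a two-group split
#'
#' @param split Tibble with `sample`, `group`.
#' @param ann Annotation tibble with `sample`, `time`, `event`.
#' @return A ggplot object with one step curve per risk group.
#' @export
plot_km <- function(split, ann) {
  df <- dplyr::inner_join(split, ann, by = "sample")
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(sf$strata), sf$strata)
  curve <- tibble::tibble(time = sf$time, surv = sf$surv,
                          group = sub("group=", "", strata))
  curve <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, group = unique(curve$group)), curve)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$surv,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "recurrence-free fraction",
                  colour = "risk group") +
    ggplot2::theme_minimal()
}
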