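toy_design <- function(seed = 7, n = 80, p = 10) {
  withr::with_seed(seed, {
    x <- matrix(abs(rnorm(n * p)), n, p,
                dimnames = list(sprintf("g%03d", 1:n), sprintf("m%02d", 1:p)))
    x[x < 1] <- 0  # sparse, nonnegative, like influence scores
    x
  })
}

test_that("the design matrix places influence scores at target cells", {
  net <- tibble::tibble(mirna = c("m1", "m1", "m2"),
                        target = c("gA", "gC", "gB"),
                        mirti = c(1.5, 2.5, 3.5))
  genes <- c("gA", "gB", "gC", "gD", "gE")
  x <- build_design(net, genes)
  expect_equal(dim(x), c(5L, 2L))
  expect_equal(x["gA", "m1"], 1.5)
  expect_equal(x["gC", "m1"], 2.5)
  expect_equal(x["gB", "m2"], 3.5)
  expect_equal(sum(x != 0), 3)
  # a miRNA with no retained targets loses its column
  net2 <- dplyr::bind_rows(net, tibble::tibble(mirna = "m3", target = "gZ",
                                               mirti = 9))
  expect_message(x2 <- build_design(net2, genes), "all-zero")
  expect_identical(colnames(x2), c("m1", "m2"))
  expect_error(build_design(net, character(0)), "empty")
})

test_that("full shrinkage at the top of the lambda path zeroes everything", {
  x <- toy_design()
  withr::with_seed(1, y <- rnorm(nrow(x)))
  cfg <- enet_config(seed = 3)
  foldid <- mirtinet:::make_foldid(nrow(x), cfg$n_folds, cfg$seed)
  fit <- mirtinet:::fit_enet_column(x, y, cfg, foldid)
  beta_max <- as.numeric(coef(fit$path$glmnet.fit,
                              s = fit$path$lambda[1]))[-1]
  expect_lt(max(abs(beta_max)), 1e-12)
})

test_that("a single planted predictor is recovered with the largest |beta|", {
  x <- toy_design()
  withr::with_seed(2, y <- 3 * x[, "m04"] + rnorm(nrow(x), sd = 0.2))
  expr <- matrix(y, ncol = 1, dimnames = list(rownames(x), "patient1"))
  fit <- fit_patient_influence(x, expr, enet_config(seed = 3))
  expect_equal(names(which.max(abs(fit$beta[, 1]))), "m04")
  expect_gt(fit$beta["m04", 1], 0)
})

test_that("nonzero counts are ordered by alpha and monotone along the path", {
  x <- toy_design(n = 120, p = 15)
  withr::with_seed(4, {
    y <- x[, 1] - 2 * x[, 2] + 0.5 * x[, 3] + rnorm(nrow(x), sd = 0.5)
  })
  expr <- matrix(y, ncol = 1, dimnames = list(rownames(x), "p1"))
  nz <- vapply(c(0, 0.5, 1), function(a) {
    unname(fit_patient_influence(x, expr, enet_config(alpha = a,
                                                      seed = 5))$nonzero)
  }, 0)
  expect_true(nz[3] <= nz[2] && nz[2] <= nz[1])
  # nonzero count along the decreasing-lambda path never decreases
  cfg <- enet_config(seed = 5)
  foldid <- mirtinet:::make_foldid(nrow(x), cfg$n_folds, cfg$seed)
  fit <- mirtinet:::fit_enet_column(x, y, cfg, foldid)
  expect_true(all(diff(as.integer(fit$path$nzero)) >= 0))
})

test_that("fits are deterministic and independent of patient order", {
  x <- toy_design()
  withr::with_seed(6, {
    expr <- matrix(rnorm(nrow(x) * 3), nrow(x), 3,
                   dimnames = list(rownames(x), c("pa", "pb", "pc")))
  })
  cfg <- enet_config(seed = 11)
  f1 <- fit_patient_influence(x, expr, cfg)
  f2 <- fit_patient_influence(x, expr, cfg)
  expect_identical(f1$beta, f2$beta)
  f3 <- fit_patient_influence(x, expr[, c("pc", "pa", "pb")], cfg)
  expect_equal(f3$beta[, colnames(f1$beta)], f1$beta)
  expect_error(fit_patient_influence(x[1:10, ], expr[1:10, ], cfg), "folds")
})

test_that("activity regression honors linearity and degenerate responses", {
  x <- toy_design()
  prof0 <- tibble::tibble(gene = rownames(x), n_neighbors = 1L, R = 0,
                          p = 1, activity_score = 0)
  cfg <- enet_config(seed = 2)
  f0 <- fit_activity_influence(x, prof0, cfg)
  expect_true(all(f0$beta == 0))
  withr::with_seed(8, y <- 2 * x[, "m02"] + rnorm(nrow(x), sd = 0.3))
  yc <- y - mean(y)
  prof1 <- dplyr::mutate(prof0, activity_score = yc)
  prof2 <- dplyr::mutate(prof0, activity_score = -yc)
  f1 <- fit_activity_influence(x, prof1, cfg)
  f2 <- fit_activity_influence(x, prof2, cfg)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-8)
  expect_equal(colnames(f1$beta), "activity")
  expect_gt(f1$beta["m02", 1], 0)
})

test_that("an activity response concentrated on one miRNA's targets selects it", {
  sim <- small_sim(seed = 12, n_genes = 200, n_modules = 6, module_size = 12,
                   n_mirnas = 20, n_driver_mirnas = 4)
  net <- build_mirti(sim$mirna, sim$mrna, sim$fpi, sim$seq)
  x <- suppressMessages(build_design(net, rownames(sim$mrna)))
  driver <- sim$truth$drivers[1]
  # synthetic activity profile: high exactly on that driver's design column
  prof <- tibble::tibble(gene = rownames(x), n_neighbors = 1L, R = 0, p = 1,
                         activity_score = x[, driver] +
                           withr::with_seed(1, rnorm(nrow(x), sd = 0.05)))
  fit <- fit_activity_influence(x, prof, enet_config(seed = 4))
  expect_gt(abs(fit$beta[driver, 1]), 0)
  expect_equal(names(which.max(abs(fit$beta[, 1]))), driver)
})

test_that("tidy, glance and summaries expose the fit", {
  x <- toy_design()
  withr::with_seed(10, {
    expr <- matrix(rnorm(nrow(x) * 2), nrow(x), 2,
                   dimnames = list(rownames(x), c("p1", "p2")))
  })
  fit <- fit_patient_influence(x, expr, enet_config(seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), ncol(x) * 2)
  expect_identical(colnames(td), c("mirna", "column", "beta"))
  gl <- glance(fit)
  expect_equal(gl$n_columns, 2)
  expect_equal(gl$alpha, 0.5)
  sm <- influence_summary(fit)
  expect_identical(sm$column, c("p1", "p2"))
  expect_true(all(sm$lambda > 0))
  expect_s3_class(autoplot(fit), "ggplot")
})
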