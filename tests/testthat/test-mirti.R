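test_that("corrfpi scores FPI edges and zeroes unmeasured endpoints", {
  w <- toy_world()
  cfg <- mi_config(n_bins = 3)
  cf <- compute_corrfpi(w$mrna, w$fpi, cfg)
  expect_equal(nrow(cf), nrow(w$fpi))
  for (i in seq_len(nrow(cf))) {
    expect_equal(cf$mi[i],
                 mutual_information(w$mrna[cf$from[i], ],
                                    w$mrna[cf$to[i], ], cfg))
  }
  # edge with an endpoint absent from expression carries 0
  fpi2 <- dplyr::bind_rows(w$fpi, tibble::tibble(from = "gX", to = "gY"))
  cf2 <- compute_corrfpi(w$mrna, fpi2, cfg)
  expect_equal(cf2$mi[cf2$from == "gX"], 0)
  # duplicated profile on an edge gives the marginal entropy
  mrna3 <- w$mrna
  mrna3["g02", ] <- mrna3["g01", ]
  cf3 <- compute_corrfpi(mrna3, w$fpi, cfg)
  expect_equal(cf3$mi[cf3$from == "g01" & cf3$to == "g02"],
               profile_entropy(mrna3["g01", ], cfg))
})

test_that("corrmir applies the candidate and negative-correlation filters", {
  w <- toy_world()
  seqt <- tibble::tibble(mirna = c("mirA", "mirA", "mirB"),
                         target = c("g01", "g03", "g05"))
  cm <- compute_corrmir(w$mirna, w$mrna, seqt)
  # repressed target: negative correlation, high MI close to entropy
  r1 <- cm[cm$target == "g01", ]
  expect_lt(r1$pearson, 0)
  expect_gt(r1$corrmir, 0.5 * profile_entropy(w$mirna["mirA", ]))
  # positively coupled target is filtered to 0
  r3 <- cm[cm$target == "g03", ]
  expect_gt(r3$pearson, 0)
  expect_equal(r3$corrmir, 0)
  # unaligned samples error
  expect_error(compute_corrmir(w$mirna[, -1], w$mrna, seqt), "aligned")
})

test_that("W sums partner products and vanishes for isolated targets", {
  w <- toy_world()
  cfg <- mi_config()
  pairs <- tibble::tibble(mirna = c("mirA", "mirA", "mirA"),
                          target = c("g01", "g04", "g07"))
  ww <- compute_w(w$mirna, w$mrna, w$fpi, pairs, cfg)
  # g07 has no FPI partners
  expect_equal(ww$w[ww$target == "g07"], 0)
  # g01 has the single partner g02
  expect_equal(ww$w[ww$target == "g01"],
               mutual_information(w$mirna["mirA", ], w$mrna["g02", ], cfg) *
                 mutual_information(w$mrna["g02", ], w$mrna["g01", ], cfg))
  # g04 has partners g02 and g03: brute-force sum of two products
  exp_w <- sum(vapply(c("g02", "g03"), function(k) {
    mutual_information(w$mirna["mirA", ], w$mrna[k, ], cfg) *
      mutual_information(w$mrna[k, ], w$mrna["g04", ], cfg)
  }, 0))
  expect_equal(ww$w[ww$target == "g04"], exp_w)
})

test_that("influence scores annihilate without sequence, repression, or partners", {
  w <- toy_world()
  # exhaustive candidate relation over the 10-gene toy
  seqt <- tidyr::expand_grid(mirna = rownames(w$mirna),
                             target = rownames(w$mrna))
  net <- build_mirti(w$mirna, w$mrna, w$fpi, seqt)
  expect_equal(net$mirti, net$corrmir * net$w * net$max_corrfpi)
  # positive-correlation pairs annihilate
  expect_true(all(net$mirti[!is.na(net$pearson) & net$pearson >= 0] == 0))
  # FPI-isolated targets annihilate (w = 0 and max_corrfpi = 0)
  isolated <- setdiff(rownames(w$mrna),
                      unique(c(w$fpi$from, w$fpi$to)))
  iso_rows <- net[net$target %in% isolated, ]
  expect_true(all(iso_rows$w == 0))
  expect_true(all(iso_rows$max_corrfpi == 0))
  expect_true(all(iso_rows$mirti == 0))
  # pairs outside the candidate relation never appear
  seq_small <- tibble::tibble(mirna = "mirA", target = "g01")
  net2 <- build_mirti(w$mirna, w$mrna, w$fpi, seq_small)
  expect_equal(nrow(net2), 1)
  # the repressed, partnered pair survives with a positive score
  expect_gt(net$mirti[net$mirna == "mirA" & net$target == "g01"], 0)
})

test_that("influence is invariant under monotone transforms of expression", {
  w <- toy_world()
  seqt <- tibble::tibble(mirna = c("mirA", "mirA"), target = c("g01", "g04"))
  n1 <- build_mirti(w$mirna, w$mrna, w$fpi, seqt)
  # strictly increasing transforms leave equal-frequency bins unchanged;
  # Pearson's sign is preserved under positive affine maps
  n2 <- build_mirti(2 * w$mirna + 3, 0.5 * w$mrna - 1, w$fpi, seqt)
  expect_equal(n1$mirti, n2$mirti, tolerance = 1e-12)
})

test_that("top-quartile retention uses interpolated Q3 of positive scores", {
  net <- tibble::tibble(mirna = c("m1", "m1", "m2", "m2"),
                        target = c("a", "b", "c", "d"),
                        pearson = -0.5, corrmir = 1, w = 1,
                        max_corrfpi = 1, mirti = c(1, 2, 3, 4))
  fpi <- tibble::tibble(from = character(), to = character())
  mods <- extract_modules(net, fpi)
  # Q3 of {1,2,3,4} = 3.25; only the score-4 entry survives
  expect_equal(attr(mods, "threshold"), 3.25)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$to, "d")
  # all-equal scores: strict inequality retains nothing
  net2 <- dplyr::mutate(net, mirti = 2)
  expect_equal(nrow(extract_modules(net2, fpi)), 0)
  # all-zero network errors
  net3 <- dplyr::mutate(net, mirti = 0)
  expect_error(extract_modules(net3, fpi), "no positive")
})

test_that("modules are connected components over retained edges", {
  net <- tibble::tibble(
    mirna = c("m1", "m1", "m2", "m2", rep("m3", 12)),
    target = c("a", "b", "c", "d", rep("e", 12)),
    pearson = -0.5, corrmir = 1, w = 1, max_corrfpi = 1,
    mirti = c(10, 9, 8, 7, rep(0.5, 12)))
  fpi <- tibble::tibble(from = c("a", "x"), to = c("b", "y"))
  mods <- extract_modules(net, fpi)
  # two disconnected stars -> 2 modules; the weak entry is dropped
  expect_equal(max(mods$module), 2)
  expect_false("e" %in% mods$to)
  # FPI edge between retained targets a, b joins module 1
  expect_true(any(mods$type == "fpi" & mods$from == "a" & mods$to == "b"))
  # module numbering is by decreasing edge count
  expect_gte(sum(mods$module == 1), sum(mods$module == 2))
})

test_that("randomization preserves degree structure and is seeded", {
  sim <- small_sim(seed = 5, n_genes = 150, n_modules = 4, module_size = 10,
                   n_mirnas = 15, n_driver_mirnas = 3)
  r1 <- randomize_for_null(sim$fpi, sim$seq, seed = 7)
  r2 <- randomize_for_null(sim$fpi, sim$seq, seed = 7)
  expect_identical(r1, r2)
  r3 <- randomize_for_null(sim$fpi, sim$seq, seed = 8)
  expect_false(identical(r1$fpi, r3$fpi))
  deg <- function(net) sort(table(c(net$from, net$to)))
  expect_identical(as.vector(deg(sim$fpi)), as.vector(deg(r1$fpi)))
  # per-miRNA out-degree preserved exactly; per-gene in-degree as multiset
  expect_identical(table(sim$seq$mirna), table(r1$seq$mirna))
  expect_identical(sort(as.vector(table(sim$seq$target))),
                   sort(as.vector(table(r1$seq$target))))
  expect_error(randomize_for_null(sim$fpi[1, ], sim$seq, 1), "too small")
})

test_that("rewiring moves most edges on a 500-edge random graph", {
  g <- withr::with_seed(31, igraph::sample_gnm(200, 500))
  el <- igraph::as_edgelist(g)
  fpi <- tibble::tibble(from = paste0("n", el[, 1]), to = paste0("n", el[, 2]))
  seqt <- tibble::tibble(mirna = rep(sprintf("m%d", 1:10), each = 20),
                         target = paste0("n", rep(1:20, 10)))
  rnd <- randomize_for_null(fpi, seqt, seed = 3)
  key <- function(net) paste(pmin(net$from, net$to), pmax(net$from, net$to))
  jac <- length(intersect(key(fpi), key(rnd$fpi))) /
    length(union(key(fpi), key(rnd$fpi)))
  expect_lt(jac, 0.5)
})
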