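#' Co-expression of interacting proteins (CorrFPI channel)
#'
#' Mutual information between the expression profiles of every pair of
#' genes linked in the functional protein interaction (FPI) network.
#' Edges with an endpoint absent from the expression matrix carry 0:
#' absence of measurement is treated as absence of co-expression
#' evidence, not as an error.
#'
#' @param expr Gene expression matrix (genes x samples).
#' @param fpi Interaction network tibble (`from`, `to`).
#' @param cfg [mi_config()].
#' @return Tibble `from`, `to`, `mi` (one row per FPI edge).
#' @export
compute_corrfpi <- function(expr, fpi, cfg = mi_config()) {
  mi <- numeric(nrow(fpi))
  have <- fpi$from %in% rownames(expr) & fpi$to %in% rownames(expr)
  if (any(have)) {
    bins <- t(apply(expr, 1, discretize_profile, cfg = cfg))
    zero_var <- apply(expr, 1, sd) == 0
    divisor <- log_div(cfg)
    fi <- match(fpi$from[have], rownames(expr))
    ti <- match(fpi$to[have], rownames(expr))
    vals <- vapply(seq_along(fi), function(k) {
      if (zero_var[fi[k]] || zero_var[ti[k]]) return(0)
      mi_from_bins(bins[fi[k], ], bins[ti[k], ], cfg$n_bins, divisor)
    }, 0)
    mi[have] <- vals
  }
  tibble::tibble(from = fpi$from, to = fpi$to, mi = mi)
}

# adjacency lookup: named list gene -> tibble(partner, mi)
corrfpi_adjacency <- function(corrfpi) {
  both <- tibble::tibble(
    gene = c(corrfpi$from, corrfpi$to),
    partner = c(corrfpi$to, corrfpi$from),
    mi = c(corrfpi$mi, corrfpi$mi))
  split(both[, c("partner", "mi")], both$gene)
}

#' miRNA-target co-expression under the repression filter (Corrmir channel)
#'
#' For each candidate pair in the sequence-predicted relation, the
#' mutual information between the miRNA and the target profile, kept
#' only when their Pearson correlation is negative (miRNA repression
#' lowers target expression, so a functional pair should anticorrelate;
#' the filter removes pairs whose high MI stems from positive
#' co-variation). Pairs not in the candidate relation, pairs with
#' nonnegative correlation, and pairs involving a zero-variance or
#' unmeasured profile all score 0.
#'
#' @param mirna miRNA expression matrix (miRNAs x samples).
#' @param mrna Gene expression matrix (genes x samples), sample-aligned
#'   with `mirna`.
#' @param seq_targets Candidate relation tibble (`mirna`, `target`).
#' @param cfg [mi_config()].
#' @return Tibble `mirna`, `target`, `pearson`, `corrmir`.
#' @export
compute_corrmir <- function(mirna, mrna, seq_targets, cfg = mi_config()) {
  check_aligned(mirna, mrna)
  n <- nrow(seq_targets)
  pear <- rep(NA_real_, n)
  cm <- numeric(n)
  have <- seq_targets$mirna %in% rownames(mirna) &
    seq_targets$target %in% rownames(mrna)
  if (any(have)) {
    mi_idx <- match(seq_targets$mirna[have], rownames(mirna))
    t_idx <- match(seq_targets$target[have], rownames(mrna))
    sd_mir <- apply(mirna, 1, sd)
    sd_t <- apply(mrna, 1, sd)
    ok <- sd_mir[mi_idx] > 0 & sd_t[t_idx] > 0
    bm <- t(apply(mirna, 1, discretize_profile, cfg = cfg))
    bt <- t(apply(mrna, 1, discretize_profile, cfg = cfg))
    divisor <- log_div(cfg)
    pv <- rep(NA_real_, sum(have))
    cv <- numeric(sum(have))
    for (k in which(ok)) {
      r <- cor(mirna[mi_idx[k], ], mrna[t_idx[k], ])
      pv[k] <- r
      if (r < 0) {
        cv[k] <- mi_from_bins(bm[mi_idx[k], ], bt[t_idx[k], ],
                              cfg$n_bins, divisor)
      }
    }
    pear[have] <- pv
    cm[have] <- cv
  }
  tibble::tibble(mirna = seq_targets$mirna, target = seq_targets$target,
                 pearson = pear, corrmir = cm)
}

check_aligned <- function(mirna, mrna) {
  if (!identical(colnames(mirna), colnames(mrna))) {
    abort("miRNA and mRNA matrices are not sample-aligned; run align_samples() first")
  }
}

#' Indirect influence of a miRNA on a target through its partners (W channel)
#'
#' `W(miR, t) = sum_k MI(miR, k) * MI(k, t)` over the FPI partners `k`
#' of the target `t`. A target with no partners (or absent from the
#' network) scores 0. A node is not its own partner.
#'
#' @inheritParams compute_corrmir
#' @param fpi Interaction network tibble (`from`, `to`).
#' @param pairs Tibble (`mirna`, `target`) of pairs to score.
#' @return Tibble `mirna`, `target`, `w`.
#' @export
compute_w <- function(mirna, mrna, fpi, pairs, cfg = mi_config()) {
  check_aligned(mirna, mrna)
  corrfpi <- compute_corrfpi(mrna, fpi, cfg)
  w <- w_channel(mirna, mrna, corrfpi_adjacency(corrfpi), pairs, cfg)
  tibble::tibble(mirna = pairs$mirna, target = pairs$target, w = w)
}

w_channel <- function(mirna, mrna, adj, pairs, cfg) {
  # MI(miR, k) for every miRNA x partner-gene combination actually needed
  partner_genes <- unique(unlist(lapply(adj[intersect(unique(pairs$target),
                                                      names(adj))],
                                        function(d) d$partner)))
  partner_genes <- intersect(partner_genes, rownames(mrna))
  mirs <- intersect(unique(pairs$mirna), rownames(mirna))
  mi_mk <- NULL
  if (length(partner_genes) > 0 && length(mirs) > 0) {
    mi_mk <- mi_matrix(mirna[mirs, , drop = FALSE],
                       mrna[partner_genes, , drop = FALSE], cfg)
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    t <- pairs$target[i]; m <- pairs$mirna[i]
    d <- adj[[t]]
    if (is.null(d) || is.null(mi_mk) || !(m %in% rownames(mi_mk))) return(0)
    k <- d$partner[d$partner %in% colnames(mi_mk)]
    if (length(k) == 0) return(0)
    mik <- d$mi[match(k, d$partner)]
    sum(mi_mk[m, k] * mik)
  }, 0)
}

#' Build the miRNA-target influence (miRTI) network
#'
#' For every candidate pair `(miR, t)` in the sequence-predicted
#' relation, the influence score is the product of three evidence
#' channels:
#' `mirti = corrmir * w * max_corrfpi`, where `corrmir` is the
#' miRNA-target mutual information under the negative-correlation
#' filter, `w` is the indirect influence through the target's FPI
#' partners, and `max_corrfpi` is the strongest co-expression between
#' the target and any of its partners. A zero in any channel (no
#' sequence support, nonnegative correlation, or an isolated target)
#' annihilates the score.
#'
#' @inheritParams compute_corrmir
#' @param fpi Interaction network tibble (`from`, `to`).
#' @return A tibble of class `mirti_network` with columns `mirna`,
#'   `target`, `pearson`, `corrmir`, `w`, `max_corrfpi`, `mirti`.
#' @export
build_mirti <- function(mirna, mrna, fpi, seq_targets, cfg = mi_config()) {
  check_aligned(mirna, mrna)
  if (nrow(seq_targets) == 0) abort("no candidate pairs in the target relation")
  corrfpi <- compute_corrfpi(mrna, fpi, cfg)
  adj <- corrfpi_adjacency(corrfpi)
  cm <- compute_corrmir(mirna, mrna, seq_targets, cfg)
  w <- w_channel(mirna, mrna, adj, seq_targets, cfg)
  max_cf <- vapply(seq_targets$target, function(t) {
    d <- adj[[t]]
    if (is.null(d) || nrow(d) == 0) 0 else max(d$mi)
  }, 0, USE.NAMES = FALSE)
  out <- tibble::tibble(
    mirna = seq_targets$mirna, target = seq_targets$target,
    pearson = cm$pearson, corrmir = cm$corrmir, w = w,
    max_corrfpi = max_cf, mirti = cm$corrmir * w * max_cf)
  class(out) <- c("mirti_network", class(out))
  out
}

#' Extract top-quartile miRNA-target modules
#'
#' Retains influence entries whose score strictly exceeds the upper
#' quartile (75th percentile, linear interpolation) of the strictly
#' positive scores — zeros are structural (annihilated pairs), so they
#' are excluded from the quartile population. Modules are the connected
#' components of the graph formed by the retained miRNA-target edges
#' plus the FPI edges among retained targets.
#'
#' @param net `mirti_network` from [build_mirti()].
#' @param fpi Interaction network tibble (`from`, `to`).
#' @return A tibble with columns `module`, `type`
#'   (`"mirna_target"` or `"fpi"`), `from`, `to`, `mirti` (`NA` for FPI
#'   rows). The retention threshold is stored in attribute
#'   `"threshold"`. Modules are numbered by decreasing edge count, ties
#'   broken by smallest node id.
#' @export
extract_modules <- function(net, fpi) {
  pos <- net$mirti[net$mirti > 0]
  if (length(pos) == 0) abort("no positive influence scores")
  thr <- unname(quantile(pos, 0.75, type = 7))
  keep <- net[net$mirti > thr, , drop = FALSE]
  if (nrow(keep) == 0) {
    out <- tibble::tibble(module = integer(), type = character(),
                          from = character(), to = character(),
                          mirti = numeric())
    attr(out, "threshold") <- thr
    return(out)
  }
  targets <- unique(keep$target)
  fpi_keep <- fpi[fpi$from %in% targets & fpi$to %in% targets, , drop = FALSE]
  edges <- tibble::tibble(
    type = c(rep("mirna_target", nrow(keep)), rep("fpi", nrow(fpi_keep))),
    from = c(keep$mirna, fpi_keep$from),
    to = c(keep$target, fpi_keep$to),
    mirti = c(keep$mirti, rep(NA_real_, nrow(fpi_keep))))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  # deterministic module numbering: decreasing component edge count,
  # ties by smallest member id
  edge_comp <- memb[edges$from]
  sizes <- table(edge_comp)
  min_node <- vapply(split(names(memb), memb), min, "")
  ord <- order(-as.vector(sizes[as.character(seq_len(comp$no))]),
               min_node[as.character(seq_len(comp$no))])
  renum <- match(seq_len(comp$no), ord)
  out <- dplyr::arrange(
    tibble::tibble(module = renum[edge_comp],
                   type = edges$type, from = edges$from, to = edges$to,
                   mirti = edges$mirti),
    .data$module, .data$type, .data$from, .data$to)
  attr(out, "threshold") <- thr
  out
}

#' Degree-preserving randomization of the FPI and target networks
#'
#' Builds a null model that keeps the degree structure of both networks
#' while destroying the joint structure linking them, so that any trend
#' surviving randomization is attributable to degree sequences alone.
#' The FPI graph is rewired by double-edge swaps (every protein keeps
#' its degree). The bipartite target relation is rewired by
#' checkerboard swaps and its gene side is then relabeled by a random
#' permutation: each miRNA keeps its number of targets and the
#' distribution of per-gene targeting counts is preserved as a
#' multiset, but which protein carries which targeting load is
#' randomized — without this decoupling a degree-coupled targeting
#' trend would survive by construction. At least 10 swap attempts per
#' edge; reproducible from the seed.
#'
#' @param fpi Interaction network tibble (`from`, `to`).
#' @param seq_targets Target relation tibble (`mirna`, `target`).
#' @param seed Integer seed.
#' @return A list with rewired `fpi` and `seq` tibbles.
#' @export
randomize_for_null <- function(fpi, seq_targets, seed = 1L) {
  if (nrow(fpi) < 2 || nrow(seq_targets) < 2) {
    abort("networks too small to rewire")
  }
  withr::with_seed(seed, {
    g <- igraph::graph_from_data_frame(fpi[, c("from", "to")],
                                       directed = FALSE)
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * nrow(fpi)))
    el <- igraph::as_edgelist(g2)
    fpi2 <- as_network(el[, 1], el[, 2])
    seq2 <- bipartite_swap(seq_targets, n_attempts = 10 * nrow(seq_targets))
    universe <- unique(c(fpi$from, fpi$to, seq_targets$target))
    relabel <- setNames(sample(universe), universe)
    seq2$target <- unname(relabel[seq2$target])
    seq2 <- dplyr::arrange(seq2, .data$mirna, .data$target)
  })
  list(fpi = fpi2, seq = seq2)
}

bipartite_swap <- function(pairs, n_attempts) {
  m <- pairs$mirna
  g <- pairs$target
  mirs <- unique(m); genes <- unique(g)
  mm <- matrix(FALSE, length(mirs), length(genes),
               dimnames = list(mirs, genes))
  mi <- match(m, mirs); gi <- match(g, genes)
  mm[cbind(mi, gi)] <- TRUE
  np <- length(mi)
  i1 <- sample.int(np, n_attempts, replace = TRUE)
  i2 <- sample.int(np, n_attempts, replace = TRUE)
  for (k in seq_len(n_attempts)) {
    a <- i1[k]; b <- i2[k]
    if (a == b) next
    ma <- mi[a]; mb <- mi[b]; ga <- gi[a]; gb <- gi[b]
    if (ma == mb || ga == gb) next
    if (mm[ma, gb] || mm[mb, ga]) next
    mm[ma, ga] <- FALSE; mm[mb, gb] <- FALSE
    mm[ma, gb] <- TRUE; mm[mb, ga] <- TRUE
    gi[a] <- gb; gi[b] <- ga
  }
  dplyr::arrange(tibble::tibble(mirna = mirs[mi], target = genes[gi]),
                 .data$mirna, .data$target)
}

#' Write an influence network to TSV
#'
#' @param net `mirti_network` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirti <- function(net, path) {
  readr::write_tsv(net[, c("mirna", "target", "corrmir", "w",
                           "max_corrfpi", "mirti")], path, progress = FALSE)
  invisible(path)
}
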