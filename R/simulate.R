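#' Synthetic-cohort configuration
#'
#' Parameters of the planted-structure generator. The defaults emulate
#' a matched miRNA/mRNA tumor cohort at desk scale: 600 genes organised
#' into 12 co-expression modules of 15 genes each embedded in a
#' scale-free interaction background, 50 miRNAs of which 5 are
#' "drivers" that each repress one module's genes, 100 samples split
#' into 30 normal / 60 primary / 10 metastatic, and exponential
#' recurrence times tied to a planted high/low risk group with hazard
#' ratio 2.8.
#'
#' @param n_genes,n_mirnas Universe sizes (defaults 600, 50).
#' @param n_samples Named integer vector
#'   `c(normal = 30, primary = 60, metastatic = 10)`.
#' @param n_modules,module_size Co-expression modules (defaults 12, 15);
#'   `n_modules * module_size` must not exceed `n_genes`.
#' @param module_edge_prob Within-module interaction probability
#'   (default 0.6).
#' @param n_driver_mirnas Number of planted driver miRNAs (default 5);
#'   driver `d` represses the genes of module `d`.
#' @param repression_effect Expression units of target decrease per unit
#'   of driver miRNA expression (default 1.0).
#' @param noise_sd Gene-level Gaussian noise SD (default 0.5).
#' @param latent_weight Loading of the shared module factor on member
#'   genes (default 0.5), creating neighbor co-expression.
#' @param degree_coupling Exponent `kappa` coupling decoy targeting
#'   probability to protein degree (default 1; 0 removes the coupling).
#' @param targets_per_mirna Expected decoy targets per miRNA
#'   (default 12). Decoys have no expression linkage.
#' @param class_effect Driver miRNA mean shift per sample class
#'   (defaults 0 / 0.8 / 1.2 for normal / primary / metastatic).
#' @param risk_effect Additional driver shift in high-risk samples
#'   (default 2).
#' @param baseline_hazard Low-risk exponential event hazard per month
#'   (default 0.008, median ~87 months).
#' @param hazard_ratio High- vs low-risk hazard ratio (default 2.8).
#' @param censor_max Administrative censoring, uniform on
#'   `[0, censor_max]` months (default 120; yields roughly half the
#'   samples censored at the default hazards).
#' @param seed Integer seed; every draw derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600L, n_mirnas = 50L,
                       n_samples = c(normal = 30L, primary = 60L,
                                     metastatic = 10L),
                       n_modules = 12L, module_size = 15L,
                       module_edge_prob = 0.6,
                       n_driver_mirnas = 5L, repression_effect = 1.0,
                       noise_sd = 0.5, latent_weight = 0.5,
                       degree_coupling = 1.0, targets_per_mirna = 12,
                       class_effect = c(normal = 0, primary = 0.8,
                                        metastatic = 1.2),
                       risk_effect = 2.0,
                       baseline_hazard = 0.008, hazard_ratio = 2.8,
                       censor_max = 120, seed = 1L) {
  if (n_modules * module_size > n_genes) {
    abort("n_modules * module_size exceeds n_genes")
  }
  if (n_driver_mirnas > min(n_modules, n_mirnas)) {
    abort("n_driver_mirnas must not exceed n_modules or n_mirnas")
  }
  if (any(n_samples < 0) || sum(n_samples) < 8) {
    abort("need at least 8 samples in total")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a matched miRNA/mRNA cohort with planted structure
#'
#' Generates every input the pipeline consumes, with known ground
#' truth:
#' * an interaction network that is the union of dense intra-module
#'   graphs and a sparse scale-free (preferential-attachment)
#'   background;
#' * module genes sharing a latent factor, so network neighbors are
#'   co-expressed;
#' * driver miRNAs that are differentially expressed across sample
#'   classes and elevated in the planted high-risk group, each
#'   repressing one module's genes
#'   (`target = -repression_effect * miR + latent + noise`);
#' * a candidate target relation containing all planted functional
#'   pairs plus expression-decoupled decoys whose probability scales
#'   with protein degree to the power `degree_coupling`;
#' * exponential recurrence times with the planted group hazard ratio
#'   and uniform administrative censoring.
#'
#' @param cfg [sim_config()].
#' @return A list of class `mirti_simulation`: `mrna`, `mirna`
#'   (matrices), `fpi`, `seq` (tibbles), `ann` (sample annotations),
#'   and `truth` (list: `drivers`, `pairs` with planted/decoy type,
#'   `modules`, `risk`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  mirs <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  n_total <- sum(cfg$n_samples)
  samples <- sprintf("S%03d", seq_len(n_total))
  class <- rep(names(cfg$n_samples), cfg$n_samples)

  # module membership: first n_modules * module_size genes, in blocks
  module_of <- rep(NA_integer_, cfg$n_genes)
  module_of[seq_len(cfg$n_modules * cfg$module_size)] <-
    rep(seq_len(cfg$n_modules), each = cfg$module_size)

  # interaction network: dense intra-module + scale-free background
  edges_from <- character(0); edges_to <- character(0)
  for (m in seq_len(cfg$n_modules)) {
    members <- which(module_of == m)
    pairs <- utils::combn(members, 2)
    pick <- runif(ncol(pairs)) < cfg$module_edge_prob
    edges_from <- c(edges_from, genes[pairs[1, pick]])
    edges_to <- c(edges_to, genes[pairs[2, pick]])
  }
  bg <- igraph::sample_pa(cfg$n_genes, m = 2, directed = FALSE)
  bel <- igraph::as_edgelist(bg)
  edges_from <- c(edges_from, genes[as.integer(bel[, 1])])
  edges_to <- c(edges_to, genes[as.integer(bel[, 2])])
  fpi <- as_network(edges_from, edges_to)

  # planted risk group: normals low, metastatic high, primaries half/half
  risk <- ifelse(class == "metastatic", "high", "low")
  prim <- which(class == "primary")
  n_high <- floor(length(prim) / 2)
  if (n_high > 0) risk[sample(prim, n_high)] <- "high"

  # miRNA expression: drivers shifted by class and risk, rest pure noise
  mirna <- matrix(rnorm(cfg$n_mirnas * n_total), cfg$n_mirnas, n_total,
                  dimnames = list(mirs, samples))
  drivers <- mirs[seq_len(cfg$n_driver_mirnas)]
  for (d in seq_len(cfg$n_driver_mirnas)) {
    mu <- cfg$class_effect[class] + cfg$risk_effect * (risk == "high")
    mirna[d, ] <- mirna[d, ] + mu
  }

  # mRNA expression: module latent factors, driver repression, noise
  latent <- matrix(rnorm(cfg$n_modules * n_total), cfg$n_modules, n_total)
  mrna <- matrix(rnorm(cfg$n_genes * n_total), cfg$n_genes, n_total,
                 dimnames = list(genes, samples))
  for (g in seq_len(cfg$n_genes)) {
    m <- module_of[g]
    if (is.na(m)) next
    base <- cfg$latent_weight * latent[m, ] + cfg$noise_sd * rnorm(n_total)
    if (m <= cfg$n_driver_mirnas) {
      base <- base - cfg$repression_effect * mirna[m, ]
    } else {
      base <- base + (1 - cfg$latent_weight) * latent[m, ]
    }
    mrna[g, ] <- base
  }

  # candidate relation: planted functional pairs + degree-coupled decoys
  planted <- tibble::tibble(
    mirna = rep(drivers, each = cfg$module_size),
    target = unlist(lapply(seq_len(cfg$n_driver_mirnas),
                           function(m) genes[which(module_of == m)])))
  deg <- igraph::degree(igraph::graph_from_data_frame(
    fpi[, c("from", "to")], directed = FALSE, vertices = genes))
  wdeg <- deg[genes]^cfg$degree_coupling
  p_g <- pmin(1, cfg$targets_per_mirna * wdeg / sum(wdeg))
  dec_m <- character(0); dec_t <- character(0)
  for (i in seq_len(cfg$n_mirnas)) {
    hit <- runif(cfg$n_genes) < p_g
    dec_m <- c(dec_m, rep(mirs[i], sum(hit)))
    dec_t <- c(dec_t, genes[hit])
  }
  decoys <- dplyr::anti_join(
    tibble::tibble(mirna = dec_m, target = dec_t), planted,
    by = c("mirna", "target"))
  seq_targets <- dplyr::arrange(dplyr::bind_rows(planted, decoys),
                                .data$mirna, .data$target)

  surv <- simulate_survival(risk, baseline_hazard = cfg$baseline_hazard,
                            hazard_ratio = cfg$hazard_ratio,
                            censor_max = cfg$censor_max, seed = NULL)
  ann <- tibble::tibble(sample = samples, class = class,
                        time = surv$time, event = surv$event)

  truth <- list(
    drivers = drivers,
    pairs = dplyr::bind_rows(
      dplyr::mutate(planted, type = "planted"),
      dplyr::mutate(decoys, type = "decoy")),
    modules = tibble::tibble(gene = genes, module = module_of),
    risk = tibble::tibble(sample = samples, risk = risk))
  structure(list(mrna = mrna, mirna = mirna, fpi = fpi,
                 seq = seq_targets, ann = ann, truth = truth,
                 config = cfg),
            class = "mirti_simulation")
}

#' Simulate exponential survival for a risk split
#'
#' Event times are exponential with the baseline hazard for the low
#' group and `baseline_hazard * hazard_ratio` for the high group;
#' censoring is uniform administrative on `[0, censor_max]`.
#'
#' @param group Character vector of `"high"`/`"low"` per sample.
#' @param baseline_hazard Low-group hazard per month.
#' @param hazard_ratio High- vs low-group hazard ratio.
#' @param censor_max Upper bound of the uniform censoring time.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Tibble with `time` (months) and `event` (1 observed,
#'   0 censored).
#' @export
simulate_survival <- function(group, baseline_hazard = 0.008,
                              hazard_ratio = 2.8, censor_max = 120,
                              seed = 1L) {
  draw <- function() {
    rate <- baseline_hazard * ifelse(group == "high", hazard_ratio, 1)
    t_event <- rexp(length(group), rate = rate)
    t_cens <- runif(length(group), 0, censor_max)
    tibble::tibble(time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.mirti_simulation <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples, %d miRNAs\n",
              nrow(x$mrna), ncol(x$mrna), nrow(x$mirna)))
  cat(sprintf("  %d interaction edges; %d candidate pairs (%d planted)\n",
              nrow(x$fpi), nrow(x$seq),
              sum(x$truth$pairs$type == "planted")))
  invisible(x)
}

#' Write a simulated cohort to a fixture directory
#'
#' Writes the seven files the command-line pipeline consumes:
#' `mrna.tsv`, `mirna.tsv`, `fpi.tsv`, `seq.tsv`, `samples.tsv`,
#' `truth.tsv` (ground truth: planted/decoy pairs, drivers, module
#' membership, risk groups) and `config.tsv`.
#'
#' @param sim A `mirti_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create fixture directory '%s'", dir))
  }
  write_expression(sim$mrna, file.path(dir, "mrna.tsv"))
  write_expression(sim$mirna, file.path(dir, "mirna.tsv"))
  write_network(sim$fpi, file.path(dir, "fpi.tsv"))
  write_targets(sim$seq, file.path(dir, "seq.tsv"))
  write_annotations(sim$ann, file.path(dir, "samples.tsv"))
  truth <- dplyr::bind_rows(
    tibble::tibble(item = paste(sim$truth$pairs$mirna,
                                sim$truth$pairs$target, sep = ","),
                   type = sim$truth$pairs$type),
    tibble::tibble(item = sim$truth$drivers, type = "driver"),
    tibble::tibble(item = sim$truth$modules$gene[!is.na(sim$truth$modules$module)],
                   type = paste0("module_",
                                 sim$truth$modules$module[!is.na(sim$truth$modules$module)])),
    tibble::tibble(item = sim$truth$risk$sample,
                   type = paste0("risk_", sim$truth$risk$risk)))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), col_names = FALSE,
                   progress = FALSE)
  cfgv <- sim$config
  cfg_df <- tibble::tibble(
    key = names(unlist(cfgv[setdiff(names(cfgv), "class_effect")])),
    value = as.character(unlist(cfgv[setdiff(names(cfgv), "class_effect")])))
  readr::write_tsv(cfg_df, file.path(dir, "config.tsv"), col_names = FALSE,
                   progress = FALSE)
  invisible(dir)
}
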