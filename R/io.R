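#' Read an expression matrix from TSV
#'
#' Reads a genes-x-samples (or miRNAs-x-samples) table whose header row
#' holds sample names and whose first column holds row identifiers.
#' Expression is assumed to be on a continuous (typically log) scale.
#'
#' Missing cells are imputed with the row mean; rows with more than
#' `max_missing` missing values are dropped with a warning. Identifier
#' matching throughout the package is exact, case-sensitive string
#' equality.
#'
#' @param path Path to a TSV file. Header: `id<TAB>sample1<TAB>...`.
#' @param impute `"row_mean"` (default) or `"none"`; with `"none"` any
#'   missing cell is an error.
#' @param max_missing Maximum tolerated fraction of missing values per
#'   row before the row is dropped (default 0.2).
#' @return A numeric matrix with row names (gene/miRNA ids) and column
#'   names (sample ids).
#' @export
read_expression <- function(path, impute = c("row_mean", "none"),
                            max_missing = 0.2) {
  impute <- match.arg(impute)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  if (ncol(raw) < 2) {
    abort(sprintf("expression file '%s' needs an id column and at least one sample", path))
  }
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate row id(s) in '%s': %s", path,
                  paste(head(dup, 5), collapse = ", ")))
  }
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id(s) in '%s': %s", path,
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell in '%s' at row '%s', column '%s': '%s'",
                  path, ids[bad[1, 1]], samples[bad[1, 2]],
                  vals[bad[1, 1], bad[1, 2]]))
  }
  dimnames(num) <- list(ids, samples)
  impute_expression(num, impute = impute, max_missing = max_missing)
}

impute_expression <- function(mat, impute = "row_mean", max_missing = 0.2) {
  miss <- rowMeans(is.na(mat))
  if (any(miss > 0) && impute == "none") {
    abort("missing expression values present and impute = 'none'")
  }
  if (any(miss > max_missing)) {
    drop <- rownames(mat)[miss > max_missing]
    warn(sprintf("dropping %d row(s) with > %.0f%% missing values: %s",
                 length(drop), 100 * max_missing,
                 paste(head(drop, 5), collapse = ", ")))
    mat <- mat[miss <= max_missing, , drop = FALSE]
  }
  if (anyNA(mat)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- rm[idx[, 1]]
  }
  if (anyNA(mat) || any(!is.finite(mat))) {
    abort("expression matrix contains non-finite values after imputation")
  }
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an undirected interaction network from a two-column TSV
#'
#' Edges are deduplicated treating `(a, b)` and `(b, a)` as the same
#' edge; self-loops are dropped with a message.
#'
#' @param path Headerless two-column TSV of gene pairs.
#' @return A tibble with columns `from`, `to` (one row per undirected
#'   edge, endpoints sorted lexicographically).
#' @export
read_network <- function(path) {
  tab <- read_two_column(path, what = "network")
  as_network(tab[[1]], tab[[2]])
}

as_network <- function(from, to) {
  from <- as.character(from)
  to <- as.character(to)
  loops <- from == to
  if (any(loops)) {
    inform(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  tibble::tibble(from = a[keep], to = b[keep])
}

#' Write a network edge list to TSV
#'
#' @param net Tibble with columns `from`, `to`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  readr::write_tsv(net[, c("from", "to")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read a sequence-predicted miRNA-target relation
#'
#' The relation is binary: a (miRNA, gene) pair is either present
#' (a candidate target predicted from seed-sequence complementarity)
#' or absent. Duplicate lines are collapsed. Unions of several
#' prediction sources can be formed with [union_targets()].
#'
#' @param path Headerless two-column TSV: miRNA id, gene id.
#' @return A tibble with columns `mirna`, `target`.
#' @export
read_targets <- function(path) {
  tab <- read_two_column(path, what = "targets", allow_empty = TRUE)
  if (nrow(tab) == 0) {
    return(tibble::tibble(mirna = character(), target = character()))
  }
  dplyr::distinct(tibble::tibble(mirna = as.character(tab[[1]]),
                                 target = as.character(tab[[2]])))
}

#' Union of miRNA-target relations
#'
#' @param ... Tibbles with columns `mirna`, `target`.
#' @return Deduplicated union as a tibble.
#' @export
union_targets <- function(...) {
  dplyr::distinct(dplyr::bind_rows(...))
}

#' Write a miRNA-target relation to TSV
#'
#' @param targets Tibble with columns `mirna`, `target`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  readr::write_tsv(targets[, c("mirna", "target")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

read_two_column <- function(path, what, allow_empty = FALSE) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    if (allow_empty) return(tibble::tibble(V1 = character(), V2 = character()))
    abort(sprintf("empty %s file: '%s'", what, path))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2)) {
    bad <- which(nfield != 2)[1]
    abort(sprintf("malformed %s line %d in '%s': expected 2 tab-separated fields, got %d",
                  what, bad, path, nfield[bad]))
  }
  tibble::tibble(V1 = vapply(parts, `[[`, "", 1),
                 V2 = vapply(parts, `[[`, "", 2))
}

#' Read sample annotations (class labels and survival)
#'
#' @param path TSV with header `sample<TAB>class<TAB>time<TAB>event`.
#'   `class` is one of `normal`, `primary`, `metastatic`; `time` is
#'   follow-up in months; `event` is 1 for an observed event (e.g.
#'   biochemical recurrence), 0 for censoring.
#' @return A tibble with those four columns.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", class = "c", time = "d", event = "i"), progress = FALSE)
  req <- c("sample", "class", "time", "event")
  if (!all(req %in% colnames(ann))) {
    abort(sprintf("annotation file '%s' must have columns %s",
                  path, paste(req, collapse = ", ")))
  }
  if (anyDuplicated(ann$sample)) {
    abort("duplicate sample ids in annotation file")
  }
  bad_class <- setdiff(unique(ann$class), c("normal", "primary", "metastatic"))
  if (length(bad_class) > 0) {
    abort(sprintf("unknown class label(s): %s", paste(bad_class, collapse = ", ")))
  }
  if (any(ann$time < 0, na.rm = TRUE)) abort("negative survival time")
  if (!all(ann$event %in% c(0L, 1L, NA))) abort("event must be 0 or 1")
  ann[, req]
}

#' Write sample annotations to TSV
#'
#' @param ann Tibble as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  readr::write_tsv(ann[, c("sample", "class", "time", "event")], path,
                   progress = FALSE)
  invisible(path)
}

#' Restrict paired matrices and annotations to shared samples
#'
#' mRNA and miRNA profiling of the same cohort rarely covers identical
#' sample sets; all downstream statistics require matched, identically
#' ordered samples. Restricts both matrices and the annotation table to
#' the intersection of their sample ids, in the mRNA matrix's order.
#'
#' @param mrna,mirna Expression matrices (columns are samples).
#' @param ann Sample annotation tibble, or `NULL`.
#' @return A list with elements `mrna`, `mirna`, `ann`.
#' @export
align_samples <- function(mrna, mirna, ann = NULL) {
  shared <- intersect(colnames(mrna), colnames(mirna))
  if (!is.null(ann)) shared <- intersect(shared, ann$sample)
  if (length(shared) == 0) {
    abort("no samples shared between the inputs")
  }
  out_ann <- NULL
  if (!is.null(ann)) {
    out_ann <- ann[match(shared, ann$sample), , drop = FALSE]
  }
  list(mrna = mrna[, shared, drop = FALSE],
       mirna = mirna[, shared, drop = FALSE],
       ann = out_ann)
}
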