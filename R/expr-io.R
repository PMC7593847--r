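#' Expression matrix for one tissue
#'
#' Light container for a probe-by-sample matrix of log-scale intensities.
#' Probe and sample IDs are carried as dimnames and must be unique; all
#' values must be finite.
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   dimnames set.
#' @param tissue tissue label, `"tumor"` or `"adjacent"`.
#' @return an object of class `expr_matrix` with elements `values` and
#'   `tissue`.
#' @export
expression_matrix <- function(values, tissue = c("tumor", "adjacent")) {
  tissue <- match.arg(tissue)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry probe IDs (rownames) and sample IDs (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated probe ID: ",
         rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ID: ",
         colnames(values)[duplicated(colnames(values))][1])
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  structure(list(values = values, tissue = tissue), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s tissue: %d probes x %d samples\n",
              x$tissue, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a probe-by-sample expression table
#'
#' Parses the tab-delimited dialect written by [write_expression()]: a header
#' row `probe_id<TAB>sample1<TAB>...`, then one row per probe. Duplicate
#' probes, ragged rows and non-numeric cells are reported with the offending
#' probe/line.
#'
#' @param path path to the TSV file.
#' @param tissue tissue label to attach.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, tissue = c("tumor", "adjacent")) {
  tissue <- match.arg(tissue)
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  n <- length(sample_ids)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != n + 1)) {
    bad <- which(lens != n + 1)[1]
    stop(sprintf("ragged row at line %d of %s: expected %d fields, found %d",
                 bad + 1L, path, n + 1L, lens[bad]))
  }
  probe_ids <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(probe_ids)) {
    stop(sprintf("duplicated probe ID '%s' (line %d of %s)",
                 probe_ids[duplicated(probe_ids)][1],
                 which(duplicated(probe_ids))[1] + 1L, path))
  }
  cells <- unlist(lapply(rows, `[`, -1L), use.names = FALSE)
  values <- suppressWarnings(as.numeric(cells))
  if (anyNA(values)) {
    bad <- which(is.na(values))[1]
    stop(sprintf("non-numeric cell '%s' at line %d of %s",
                 cells[bad], (bad - 1L) %/% n + 2L, path))
  }
  values <- matrix(values, nrow = length(probe_ids), ncol = n, byrow = TRUE,
                   dimnames = list(probe_ids, sample_ids))
  expression_matrix(values, tissue)
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces the doubles exactly.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' Two tab-separated columns with header: `sample_id` and `phenotype`
#' (0 = phenotype-negative, 1 = phenotype-positive, e.g. perineural
#' invasion present).
#'
#' @param path file path.
#' @return `read_annotation`: a data frame with columns `sample_id`,
#'   `phenotype`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(ann)))
    stop("annotation must have columns sample_id and phenotype")
  if (!all(ann$phenotype %in% c(0L, 1L)))
    stop("phenotype must be coded 0/1")
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample ID in annotation: ",
         ann$sample_id[duplicated(ann$sample_id)][1])
  ann[c("sample_id", "phenotype")]
}

#' @rdname read_annotation
#' @param ann annotation data frame.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combine paired tumor and adjacent profiles into one feature matrix
#'
#' For every patient the tumor and adjacent expression vectors are
#' concatenated, so a cohort profiled with `d` probes per tissue yields
#' `2 * d` features per patient. Features are tissue-tagged
#' (`"tumor:<probe>"`, `"adjacent:<probe>"`) so downstream reporting can
#' attribute selected features to a tissue. This is the single point where
#' orientation flips from probes-by-samples (storage) to patients-by-features
#' (analysis).
#'
#' @param tumor,adjacent [expression_matrix()] objects over the same patients
#'   (pairing by identical sample ID).
#' @param annotation data frame mapping `sample_id` to `phenotype` (0/1);
#'   must cover all patients and contain both classes.
#' @return an object of class `combined_matrix`: list with `x` (patients x
#'   features numeric matrix) and `labels` (named 0/1 integer vector).
#' @export
combine_tissues <- function(tumor, adjacent, annotation) {
  stopifnot(inherits(tumor, "expr_matrix"), inherits(adjacent, "expr_matrix"))
  pt <- colnames(tumor$values)
  pa <- colnames(adjacent$values)
  missing_adj <- setdiff(pt, pa)
  missing_tum <- setdiff(pa, pt)
  if (length(missing_adj) || length(missing_tum)) {
    stop("unpaired patients: ",
         paste(c(
           if (length(missing_adj))
             paste0(missing_adj, " (no adjacent sample)"),
           if (length(missing_tum))
             paste0(missing_tum, " (no tumor sample)")),
           collapse = ", "))
  }
  x <- cbind(t(tumor$values), t(adjacent$values[, pt, drop = FALSE]))
  colnames(x) <- c(paste0("tumor:", rownames(tumor$values)),
                   paste0("adjacent:", rownames(adjacent$values)))
  idx <- match(pt, annotation$sample_id)
  if (anyNA(idx))
    stop("annotation missing samples: ", paste(pt[is.na(idx)], collapse = ", "))
  labels <- as.integer(annotation$phenotype[idx])
  names(labels) <- pt
  if (length(unique(labels)) < 2)
    stop("both phenotype classes must be present")
  structure(list(x = x, labels = labels), class = "combined_matrix")
}

#' @export
print.combined_matrix <- function(x, ...) {
  cat(sprintf("<combined_matrix> %d patients x %d features (%d pos / %d neg)\n",
              nrow(x$x), ncol(x$x), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

# Internal: tissue block of a tissue-tagged feature ID.
feature_tissue <- function(feature_id) sub(":.*$", "", feature_id)
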