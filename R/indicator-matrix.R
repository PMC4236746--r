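#' Binary gene-by-case indicator matrix
#'
#' An indicator matrix records, for one omics study, whether each gene is
#' significantly altered ("active", coded 1) in each case. Rows are genes,
#' columns are cases; every cell is 0 or 1. Discretization of raw omics
#' measurements into this form is the caller's responsibility.
#'
#' @param values Integer/numeric matrix of 0/1 values with unique row names
#'   (gene IDs). Missing column names are auto-filled as `case_1..case_n`.
#' @param name Label for the matrix (e.g. `"M1"`), used in formulas.
#' @return An object of class `kp_matrix` with fields `name` and `values`.
#' @export
kp_indicator_matrix <- function(values, name) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (ncol(values) < 1L) stop("indicator matrix must have at least one case column", call. = FALSE)
  if (is.null(rownames(values))) stop("indicator matrix must have gene IDs as row names", call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ID in indicator matrix: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values == 0L | values == 1L)) {
    stop("indicator matrix cells must all be 0 or 1", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("case_", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate case ID in indicator matrix", call. = FALSE)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, values = values), class = "kp_matrix")
}

#' @export
print.kp_matrix <- function(x, ...) {
  cat("<indicator matrix '", x$name, "': ", nrow(x$values), " genes x ",
      ncol(x$values), " cases, ", sum(x$values), " active cells>\n", sep = "")
  invisible(x)
}

#' @rdname kp_indicator_matrix
#' @param m A `kp_matrix`.
#' @export
kp_n_cases <- function(m) ncol(m$values)

#' Read an indicator matrix from a TSV file
#'
#' Expects tab-separated lines with the gene ID in the first column and one
#' 0/1 indicator per case in the remaining columns. All rows must have the
#' same number of columns; duplicate gene IDs are rejected because they would
#' make a gene's activity ambiguous.
#'
#' @param path Path to the TSV file.
#' @param name Label for the matrix (used in formulas), e.g. `"M1"`.
#' @param header If `TRUE` the first line holds column labels: an ID-column
#'   label followed by one case ID per case. If `FALSE` (default) cases are
#'   auto-named `case_1..case_n`.
#' @param missing_token Optional string that, when found in a cell, is read as
#'   0 (non-active). By default parsing is strict: only "0" and "1" are valid.
#' @return A [kp_indicator_matrix()] object.
#' @export
kp_read_indicator_matrix <- function(path, name, header = FALSE, missing_token = NULL) {
  lines <- kp_read_lines(path)
  if (length(lines) == 0L) stop("empty indicator matrix file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  case_ids <- NULL
  if (header) {
    hdr <- fields[[1L]]
    if (length(hdr) < 2L) stop(path, " line 1: header must name the ID column and at least one case", call. = FALSE)
    case_ids <- hdr[-1L]
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("indicator matrix file has a header but no data rows: ", path, call. = FALSE)
  }
  ncol_expected <- length(fields[[1L]])
  if (ncol_expected < 2L) {
    stop(path, " line ", 1L + header, ": expected a gene ID and at least one case column", call. = FALSE)
  }
  n_cases <- ncol_expected - 1L
  if (!is.null(case_ids) && length(case_ids) != n_cases) {
    stop(path, ": header names ", length(case_ids), " cases but rows have ", n_cases, call. = FALSE)
  }
  genes <- character(length(fields))
  values <- matrix(0L, nrow = length(fields), ncol = n_cases)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    lineno <- i + as.integer(header)
    if (length(f) != ncol_expected) {
      stop(path, " line ", lineno, ": ragged row (expected ", ncol_expected,
           " columns, found ", length(f), ")", call. = FALSE)
    }
    genes[i] <- f[1L]
    cells <- f[-1L]
    if (!is.null(missing_token)) cells[cells == missing_token] <- "0"
    bad <- which(cells != "0" & cells != "1")
    if (length(bad)) {
      stop(path, " line ", lineno, ": value '", cells[bad[1L]],
           "' is not 0/1 (column ", bad[1L] + 1L, ")", call. = FALSE)
    }
    values[i, ] <- as.integer(cells)
  }
  if (anyDuplicated(genes)) {
    stop(path, ": duplicate gene ID '", genes[duplicated(genes)][1L], "'", call. = FALSE)
  }
  rownames(values) <- genes
  colnames(values) <- if (is.null(case_ids)) paste0("case_", seq_len(n_cases)) else case_ids
  kp_indicator_matrix(values, name)
}

#' Write an indicator matrix to a TSV file
#'
#' @param m A [kp_indicator_matrix()] object.
#' @param path Output path.
#' @param header Write a header line (`id` followed by case IDs)?
#' @return `path`, invisibly.
#' @export
kp_write_indicator_matrix <- function(m, path, header = FALSE) {
  stopifnot(inherits(m, "kp_matrix"))
  body <- paste0(rownames(m$values), "\t",
                 apply(m$values, 1L, paste, collapse = "\t"))
  if (header) body <- c(paste(c("id", colnames(m$values)), collapse = "\t"), body)
  kp_write_lines(body, path)
  invisible(path)
}

#' Number of non-active cases for genes in a matrix
#'
#' Counts the 0-entries in each gene's row. Genes absent from the matrix count
#' every case as non-active, so they are inactive under any threshold
#' `L < n_cases`; this conservative convention avoids inventing signal for
#' unmeasured genes.
#'
#' @param m A [kp_indicator_matrix()] object.
#' @param genes Character vector of gene IDs.
#' @return Named integer vector of non-active case counts.
#' @export
kp_count_inactive <- function(m, genes) {
  stopifnot(inherits(m, "kp_matrix"))
  n <- kp_n_cases(m)
  counts <- rep.int(n, length(genes))
  idx <- match(genes, rownames(m$values))
  hit <- !is.na(idx)
  if (any(hit)) counts[hit] <- n - as.integer(rowSums(m$values[idx[hit], , drop = FALSE]))
  names(counts) <- genes
  counts
}

#' Per-matrix activity of genes under a case-exception threshold
#'
#' A gene is active for a matrix when its row contains at most `l` non-active
#' cases.
#'
#' @param m A [kp_indicator_matrix()] object.
#' @param l A [kp_l()] specification or an integer count, resolved against the
#'   matrix's case count.
#' @param genes Character vector of gene IDs (the activity universe, usually
#'   the network's node set).
#' @return Named logical vector over `genes`.
#' @export
kp_matrix_activity <- function(m, l, genes) {
  L <- kp_resolve_l(l, kp_n_cases(m))
  kp_count_inactive(m, genes) <= L
}

#' Combine two indicator matrices cell by cell
#'
#' For two studies over the *same cases* (same case IDs, same order), builds a
#' single matrix whose cell (g, c) is `op` applied to the two input cells.
#' Genes present in only one matrix contribute an all-zero row for the other.
#' Studies with differing case lists cannot be combined this way; use
#' per-matrix thresholds and a formula instead.
#'
#' @param m1,m2 [kp_indicator_matrix()] objects with identical case lists.
#' @param op One of `"AND"`, `"OR"`, `"XOR"`.
#' @param name Name for the combined matrix.
#' @return A combined `kp_matrix`.
#' @export
kp_cellwise_combine <- function(m1, m2, op = c("AND", "OR", "XOR"),
                                name = paste0(m1$name, "_", op[1L], "_", m2$name)) {
  op <- match.arg(op)
  stopifnot(inherits(m1, "kp_matrix"), inherits(m2, "kp_matrix"))
  if (!identical(colnames(m1$values), colnames(m2$values))) {
    stop("case lists differ between '", m1$name, "' and '", m2$name,
         "'; cell-wise combination requires the same cohort - use per-matrix ",
         "L thresholds with a formula for unconnected data sets", call. = FALSE)
  }
  genes <- sort(unique(c(rownames(m1$values), rownames(m2$values))), method = "radix")
  a <- matrix(0L, length(genes), ncol(m1$values), dimnames = list(genes, colnames(m1$values)))
  b <- a
  a[rownames(m1$values), ] <- m1$values
  b[rownames(m2$values), ] <- m2$values
  combined <- switch(op,
    AND = a & b,
    OR  = a | b,
    XOR = xor(a == 1L, b == 1L))
  kp_indicator_matrix(combined + 0L, name)
}
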