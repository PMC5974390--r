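# Typed matrix containers and CSV/TSV readers for all tabular inputs.
#
# Two lightweight S3 classes wrap base matrices:
#   response_matrix  - drugs x cell lines, log-IC50, NAs allowed
#   side_info_matrix - entities x features, dense, no NAs; kind attribute
# Drug/cell/feature identifiers live in dimnames, so every base matrix
# operation keeps working.

.matrix_kinds <- c("response", "drug_target", "pathway_score",
                   "gene_expression", "mutation_cnv")

.check_unique <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate %s identifiers: %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' Construct a drug-response matrix
#'
#' A drugs x cell lines matrix of log-IC50 values (lower = more sensitive).
#' Missing entries are allowed and recorded; identifiers must be unique.
#'
#' @param values numeric matrix with unique rownames (drug ids) and
#'   colnames (cell line ids); `NA` marks an unobserved drug/cell pair.
#' @return a `response_matrix`: the input matrix with an
#'   `observed_fraction` attribute.
#' @export
response_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("response matrix needs drug rownames and cell-line colnames",
         call. = FALSE)
  .check_unique(rownames(values), "drug")
  .check_unique(colnames(values), "cell line")
  structure(values,
            observed_fraction = mean(!is.na(values)),
            class = c("response_matrix", "matrix", "array"))
}

#' Construct a side-information matrix
#'
#' Entities on rows (drugs or cell lines), features on columns (protein
#' targets, pathway scores, genes).  No missing values are allowed; a
#' `drug_target` matrix must be binary 0/1.
#'
#' @param values numeric matrix with unique row and column names.
#' @param kind one of `"drug_target"`, `"pathway_score"`,
#'   `"gene_expression"`, `"mutation_cnv"`.
#' @return a `side_info_matrix` with a `kind` attribute.
#' @export
side_info_matrix <- function(values, kind) {
  kind <- match.arg(kind, setdiff(.matrix_kinds, "response"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("side-information matrix needs entity rownames and feature colnames",
         call. = FALSE)
  .check_unique(rownames(values), "entity")
  .check_unique(colnames(values), "feature")
  if (anyNA(values))
    stop("side-information matrix must not contain missing values",
         call. = FALSE)
  if (kind == "drug_target" && !all(values %in% c(0, 1)))
    stop("drug_target side information must be binary 0/1", call. = FALSE)
  structure(values, kind = kind,
            class = c("side_info_matrix", "matrix", "array"))
}

#' Tissue annotation table
#'
#' @param cell_ids character vector of cell-line identifiers (unique).
#' @param tissues character vector of non-empty tissue labels, same length.
#' @return a `tissue_annotation` data frame with columns `cell_id`, `tissue`.
#' @export
tissue_annotation <- function(cell_ids, tissues) {
  cell_ids <- as.character(cell_ids)
  tissues <- as.character(tissues)
  stopifnot(length(cell_ids) == length(tissues))
  .check_unique(cell_ids, "cell line")
  if (any(!nzchar(tissues)) || anyNA(tissues))
    stop("tissue labels must be non-empty", call. = FALSE)
  structure(data.frame(cell_id = cell_ids, tissue = tissues,
                       stringsAsFactors = FALSE),
            class = c("tissue_annotation", "data.frame"))
}

.infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a response or side-information matrix from CSV/TSV
#'
#' First row holds column identifiers, first column row identifiers.
#' Empty cells and the sentinels `NA`/`NaN` (case-insensitive) are read as
#' missing, which only a response matrix may contain.
#'
#' @param path file path; delimiter inferred from the extension (`.tsv`,
#'   `.txt` = tab, otherwise comma) unless `sep` is given.
#' @param kind `"response"` or a side-information kind (see
#'   [side_info_matrix()]).
#' @param sep optional delimiter override.
#' @param transpose read entities from columns instead of rows.
#' @param log_transform apply `log()` to a response matrix after reading
#'   (off by default; values are otherwise used as given).
#' @return [response_matrix()] or [side_info_matrix()].
#' @export
read_matrix <- function(path, kind, sep = NULL, transpose = FALSE,
                        log_transform = FALSE) {
  kind <- match.arg(kind, .matrix_kinds)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = .infer_sep(path, sep), check.names = FALSE,
                  row.names = NULL, stringsAsFactors = FALSE,
                  colClasses = "character")
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  na_like <- body == "" | tolower(body) %in% c("na", "nan")
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !na_like, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at row %d ('%s'), column '%s' in %s",
                 bad[1, 1], ids[bad[1, 1]], colnames(body)[bad[1, 2]], path),
         call. = FALSE)
  num[na_like] <- NA_real_
  dimnames(num) <- list(ids, colnames(body))
  if (transpose) num <- t(num)
  if (kind == "response") {
    if (log_transform) num <- log(num)
    response_matrix(num)
  } else {
    side_info_matrix(num, kind)
  }
}

#' Write a matrix to CSV/TSV (inverse of [read_matrix()])
#'
#' @param x matrix with dimnames; `NA` written as empty cell.
#' @param path destination; delimiter inferred from extension.
#' @param sep optional delimiter override.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  # %.17g keeps doubles exact under read/write round trips
  ch <- array(sprintf("%.17g", x), dim = dim(x), dimnames = dimnames(x))
  ch[is.na(unclass(x))] <- ""
  df <- data.frame(id = rownames(x), as.data.frame(ch, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = .infer_sep(path, sep), row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}

#' Read a tissue annotation (two-column CSV: cell_id, tissue)
#'
#' @param path CSV/TSV path with a header row.
#' @param sep optional delimiter override.
#' @return [tissue_annotation()].
#' @export
read_tissue_annotation <- function(path, sep = NULL) {
  df <- read.csv(path, sep = .infer_sep(path, sep), stringsAsFactors = FALSE)
  tissue_annotation(df[[1]], df[[2]])
}

#' Align a response matrix with its two side-information matrices
#'
#' Restricts all three matrices to the intersection of drug identifiers
#' (response rows vs drug side info) and of cell identifiers (response
#' columns vs cell side info), in the response matrix's order.
#'
#' @param response [response_matrix()].
#' @param drug_side,cell_side [side_info_matrix()] or `NULL`.
#' @return list with elements `response`, `drug_side`, `cell_side`,
#'   `dropped` (list of dropped drug/cell ids per input).
#' @export
align_inputs <- function(response, drug_side = NULL, cell_side = NULL) {
  drugs <- rownames(response)
  cells <- colnames(response)
  dropped <- list(drugs = character(), cells = character())
  if (!is.null(drug_side)) {
    keep <- intersect(drugs, rownames(drug_side))
    if (length(keep) == 0) stop("no drugs in common between response and drug side information", call. = FALSE)
    dropped$drugs <- union(setdiff(drugs, keep), setdiff(rownames(drug_side), keep))
    drugs <- drugs[drugs %in% keep]
  }
  if (!is.null(cell_side)) {
    keep <- intersect(cells, rownames(cell_side))
    if (length(keep) == 0) stop("no cell lines in common between response and cell side information", call. = FALSE)
    dropped$cells <- union(setdiff(cells, keep), setdiff(rownames(cell_side), keep))
    cells <- cells[cells %in% keep]
  }
  out <- list(
    response = response_matrix(unclass(response)[drugs, cells, drop = FALSE]),
    drug_side = if (!is.null(drug_side))
      side_info_matrix(unclass(drug_side)[drugs, , drop = FALSE],
                       attr(drug_side, "kind")),
    cell_side = if (!is.null(cell_side))
      side_info_matrix(unclass(cell_side)[cells, , drop = FALSE],
                       attr(cell_side, "kind")),
    dropped = dropped)
  out
}

#' Restrict a screen to one tissue
#'
#' Keeps the cell lines annotated to `tissue` that are present in both the
#' response matrix and the cell side information.  Mirrors the tissue-level
#' analysis rule of keeping only tissues with at least `min_cells` samples:
#' smaller tissues yield a typed "too small" result, not an error.
#'
#' @param response [response_matrix()].
#' @param cell_side [side_info_matrix()] or `NULL`.
#' @param ann [tissue_annotation()].
#' @param tissue tissue label present in `ann`.
#' @param min_cells minimum number of cell lines (default 20).
#' @return list `(response, cell_side, tissue, n_cells, too_small)`;
#'   matrices are `NULL` when `too_small` is `TRUE`.
#' @export
subset_by_tissue <- function(response, cell_side, ann, tissue,
                             min_cells = 20) {
  stopifnot(min_cells >= 1)
  if (!tissue %in% ann$tissue)
    stop(sprintf("unknown tissue '%s'; available: %s", tissue,
                 paste(sort(unique(ann$tissue)), collapse = ", ")),
         call. = FALSE)
  cells <- ann$cell_id[ann$tissue == tissue]
  cells <- intersect(colnames(response), cells)
  if (!is.null(cell_side)) cells <- intersect(cells, rownames(cell_side))
  if (length(cells) < min_cells)
    return(list(response = NULL, cell_side = NULL, tissue = tissue,
                n_cells = length(cells), too_small = TRUE))
  list(
    response = response_matrix(unclass(response)[, cells, drop = FALSE]),
    cell_side = if (!is.null(cell_side))
      side_info_matrix(unclass(cell_side)[cells, , drop = FALSE],
                       attr(cell_side, "kind")),
    tissue = tissue, n_cells = length(cells), too_small = FALSE)
}
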