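#' Paired expression study container
#'
#' Bundles a log2 expression matrix (features x samples) with the
#' tumour/normal pairing map of a matched-tissue design. Every sample must
#' belong to exactly one pair; the pairing is a bijection from tumour to
#' normal sample ids.
#'
#' @param matrix Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids), log2 scale, no missing
#'   values.
#' @param pairing Named character vector or two-column data frame mapping
#'   each tumour sample id to its matched normal sample id.
#' @return An object of class `paired_study` with elements `matrix`,
#'   `feature_ids`, `sample_ids` and `pairing` (named character vector,
#'   names = tumour ids).
#' @export
paired_study <- function(matrix, pairing) {
  if (is.data.frame(pairing)) {
    stopifnot(ncol(pairing) >= 2)
    pairing <- stats::setNames(as.character(pairing[[2]]), as.character(pairing[[1]]))
  }
  if (is.null(names(pairing))) {
    stop("`pairing` must map tumour sample ids (names) to normal sample ids")
  }
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix (features x samples)")
  }
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix needs feature rownames and sample colnames")
  }
  tum <- names(pairing)
  nor <- unname(pairing)
  if (anyDuplicated(tum) || anyDuplicated(nor)) {
    stop("pairing is not a bijection: duplicated sample ids")
  }
  if (length(intersect(tum, nor)) > 0) {
    stop("a sample id appears as both tumour and normal")
  }
  all_ids <- c(tum, nor)
  missing <- setdiff(all_ids, colnames(matrix))
  if (length(missing) > 0) {
    stop("paired samples absent from matrix: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(colnames(matrix), all_ids)
  if (length(extra) > 0) {
    stop("samples in matrix but not in any pair: ", paste(extra, collapse = ", "))
  }
  if (ncol(matrix) != 2L * length(tum)) {
    stop("number of columns must equal 2 x number of pairs")
  }
  structure(
    list(
      matrix = matrix,
      feature_ids = rownames(matrix),
      sample_ids = colnames(matrix),
      pairing = pairing
    ),
    class = "paired_study"
  )
}

#' @export
print.paired_study <- function(x, ...) {
  cat(sprintf(
    "paired_study: %d features, %d pairs (%d samples)\n",
    nrow(x$matrix), length(x$pairing), ncol(x$matrix)
  ))
  invisible(x)
}

#' Number of tumour/normal pairs in a study
#' @param study A `paired_study`.
#' @return Integer number of subject pairs.
#' @export
n_pairs <- function(study) length(study$pairing)

#' Tissue label of each sample column
#' @param study A `paired_study`.
#' @return Character vector (`"tumor"`/`"normal"`) aligned with
#'   `colnames(study$matrix)`.
#' @export
tissue_labels <- function(study) {
  ifelse(study$sample_ids %in% names(study$pairing), "tumor", "normal")
}

# tumour and normal submatrices with columns aligned pair-by-pair
paired_submatrices <- function(study) {
  list(
    tumor = study$matrix[, names(study$pairing), drop = FALSE],
    normal = study$matrix[, unname(study$pairing), drop = FALSE]
  )
}

#' Write / read the tab-delimited expression matrix
#'
#' Row 1 holds the sample ids, column 1 the feature ids.
#'
#' @param study A `paired_study` (or a plain matrix for `write_`).
#' @param path File path.
#' @name expression_io
#' @return `read_expression_matrix` returns a numeric matrix with dimnames.
#' @export
write_expression_matrix <- function(study, path) {
  m <- if (inherits(study, "paired_study")) study$matrix else study
  df <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read the two-column pairing table (tumor_id, normal_id)
#' @param pairing Named character vector (names = tumour ids) or
#'   `paired_study`.
#' @param path File path.
#' @name pairing_io
#' @return `read_pairing` returns a named character vector.
#' @export
write_pairing <- function(pairing, path) {
  if (inherits(pairing, "paired_study")) pairing <- pairing$pairing
  utils::write.table(
    data.frame(tumor_id = names(pairing), normal_id = unname(pairing)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname pairing_io
#' @export
read_pairing <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df$normal_id), as.character(df$tumor_id))
}
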