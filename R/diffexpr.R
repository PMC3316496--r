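#' Per-feature paired t-test
#'
#' Tests, for every feature, whether the mean of the within-pair
#' tumour - normal log2 differences is zero, against the t distribution
#' with `n_pairs - 1` degrees of freedom (two-sided).
#'
#' Features whose paired differences have zero variance are flagged rather
#' than silently reported: if in addition the mean difference is zero
#' (tumour column identical to normal column) the record is `t = 0, p = 1`;
#' a constant nonzero difference yields `t = NA, p = NA` with
#' `zero_variance = TRUE`.
#'
#' @param study A [paired_study()] with at least 2 pairs.
#' @return Data frame: `feature_id`, `t_stat`, `p_value`, `zero_variance`.
#' @export
paired_t_test <- function(study) {
  stopifnot(inherits(study, "paired_study"))
  n <- n_pairs(study)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  sub <- paired_submatrices(study)
  d <- sub$tumor - sub$normal
  mu <- rowMeans(d)
  sdd <- apply(d, 1, stats::sd)
  zero_var <- sdd == 0
  t_stat <- mu / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  # identical columns: define t = 0, p = 1; constant nonzero shift: undefined
  ident <- zero_var & mu == 0
  t_stat[ident] <- 0
  p[ident] <- 1
  t_stat[zero_var & !ident] <- NA_real_
  p[zero_var & !ident] <- NA_real_
  data.frame(
    feature_id = study$feature_ids, t_stat = t_stat, p_value = p,
    zero_variance = zero_var & !ident, row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at
#' 1, returned in the input order. `NA` inputs propagate to `NA` outputs and
#' do not count towards `m`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Tumour/normal expression ratio of one feature
#'
#' Geometric-mean ratio by default: `2^mean(log2 tumour - log2 normal)` over
#' pairs, matching a log-scale (RMA-style) input matrix. The arithmetic
#' alternative is the ratio of linear-scale means.
#'
#' @param study A [paired_study()].
#' @param feature_id Feature to evaluate.
#' @param scale `"geometric"` (default) or `"arithmetic"`.
#' @return Positive scalar ratio (tumour vs normal).
#' @export
expression_ratio <- function(study, feature_id,
                             scale = c("geometric", "arithmetic")) {
  scale <- match.arg(scale)
  stopifnot(inherits(study, "paired_study"))
  if (!feature_id %in% study$feature_ids) {
    stop("unknown feature: ", feature_id)
  }
  sub <- paired_submatrices(study)
  t_vals <- sub$tumor[feature_id, ]
  n_vals <- sub$normal[feature_id, ]
  if (scale == "geometric") {
    2^mean(t_vals - n_vals)
  } else {
    mean(2^t_vals) / mean(2^n_vals)
  }
}

#' Signed fold-change from a linear-scale ratio
#'
#' Down-regulation is reported as a negative fold-change: ratios `>= 1` map
#' to themselves, ratios `< 1` to `-1/ratio`, so `|fold_change| >= 1`
#' always and `signed_fold_change(1/r) = -signed_fold_change(r)`.
#'
#' @param ratio Positive numeric vector of tumour/normal ratios.
#' @return Signed fold changes.
#' @export
signed_fold_change <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio <= 0)) {
    stop("ratio must be strictly positive")
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Full differential-expression table
#'
#' Runs [paired_t_test()], adjusts p-values with [bh_fdr()], and attaches
#' the tumour/normal ratio and signed fold-change of every feature —
#' the per-feature record of a paired microarray comparison.
#'
#' @inheritParams expression_ratio
#' @return Data frame: `feature_id`, `t_stat`, `p_value`, `q_value`,
#'   `ratio`, `fold_change`, `zero_variance`.
#' @export
differential_table <- function(study, scale = c("geometric", "arithmetic")) {
  scale <- match.arg(scale)
  tt <- paired_t_test(study)
  sub <- paired_submatrices(study)
  ratio <- if (scale == "geometric") {
    2^rowMeans(sub$tumor - sub$normal)
  } else {
    rowMeans(2^sub$tumor) / rowMeans(2^sub$normal)
  }
  tt$q_value <- bh_fdr(tt$p_value)
  tt$ratio <- unname(ratio)
  tt$fold_change <- signed_fold_change(tt$ratio)
  tt[, c(
    "feature_id", "t_stat", "p_value", "q_value", "ratio",
    "fold_change", "zero_variance"
  )]
}

#' Order features by differential-expression evidence
#'
#' Ascending p-value; ties broken by descending `|fold_change|`, then
#' lexicographic feature id. Flagged (NA p) records sort last.
#'
#' @param de_table Output of [differential_table()].
#' @return Character vector of feature ids.
#' @export
rank_by_pvalue <- function(de_table) {
  if (nrow(de_table) == 0) return(character(0))
  ord <- order(de_table$p_value, -abs(de_table$fold_change),
    de_table$feature_id,
    na.last = TRUE
  )
  de_table$feature_id[ord]
}

#' Write / read the differential table as TSV
#' @param de_table Output of [differential_table()].
#' @param path File path.
#' @name differential_io
#' @export
write_differential_table <- function(de_table, path) {
  utils::write.table(de_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname differential_io
#' @export
read_differential_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
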