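#' Merge the t-test and random-forest rankings into a signature
#'
#' The tissue-specific signature is the intersection of the features that
#' pass the differential-expression threshold (`p_value < p_threshold`) with
#' those that pass the importance threshold (`mda > mda_threshold`), ordered
#' by ascending p-value. Both thresholds are study choices and must be given
#' explicitly.
#'
#' @param de_table Output of [differential_table()].
#' @param imp_table Output of [conditional_mda()]; must cover the same
#'   feature universe.
#' @param p_threshold Paired t-test p-value cut (exclusive), in (0, 1).
#' @param mda_threshold Minimum MDA (exclusive).
#' @return A `mir_signature` data frame with columns `feature_id`,
#'   `p_value`, `q_value`, `fold_change`, `mda`, and attributes
#'   `p_threshold` / `mda_threshold`.
#' @export
merge_rankings <- function(de_table, imp_table, p_threshold, mda_threshold) {
  stopifnot(
    is.numeric(p_threshold), p_threshold > 0, p_threshold < 1,
    is.numeric(mda_threshold)
  )
  only_de <- setdiff(de_table$feature_id, imp_table$feature_id)
  only_imp <- setdiff(imp_table$feature_id, de_table$feature_id)
  if (length(only_de) > 0 || length(only_imp) > 0) {
    stop(
      "feature universes differ between the two tables; ",
      "only in differential table: [", paste(only_de, collapse = ", "), "]; ",
      "only in importance table: [", paste(only_imp, collapse = ", "), "]"
    )
  }
  mda <- imp_table$mda[match(de_table$feature_id, imp_table$feature_id)]
  keep <- !is.na(de_table$p_value) &
    de_table$p_value < p_threshold & mda > mda_threshold
  sig <- data.frame(
    feature_id = de_table$feature_id[keep],
    p_value = de_table$p_value[keep],
    q_value = de_table$q_value[keep],
    fold_change = de_table$fold_change[keep],
    mda = mda[keep]
  )
  sig <- sig[order(sig$p_value, sig$feature_id), , drop = FALSE]
  rownames(sig) <- NULL
  if (nrow(sig) == 0) {
    warning("signature is empty under the given thresholds")
  }
  structure(sig,
    p_threshold = p_threshold, mda_threshold = mda_threshold,
    class = c("mir_signature", "data.frame")
  )
}

#' Write / read a signature table (TSV with provenance columns)
#' @param signature A `mir_signature`.
#' @param path File path.
#' @name signature_io
#' @export
write_signature <- function(signature, path) {
  utils::write.table(as.data.frame(signature), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname signature_io
#' @param p_threshold,mda_threshold Thresholds to re-attach when reading.
#' @export
read_signature <- function(path, p_threshold = NA_real_, mda_threshold = NA_real_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df,
    p_threshold = p_threshold, mda_threshold = mda_threshold,
    class = c("mir_signature", "data.frame")
  )
}
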