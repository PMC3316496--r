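#' Per-subject 2^-ddCt relative quantification
#'
#' Comparative-Ct quantification of a target against the reference control:
#' per subject, `dCt_tissue = Ct_target - Ct_reference`,
#' `ddCt = dCt_tumor - dCt_normal`, `RQ = 2^-ddCt`. Subjects missing any of
#' the four measurements are excluded with a warning. Adding a constant to
#' all of a subject's Ct values (an instrument offset) leaves RQ unchanged.
#'
#' @param table A `ct_table` (see [generate_ct_table()] /
#'   [read_ct_table()]).
#' @param target Target assay name.
#' @param reference Reference assay; defaults to the table's
#'   `reference_target` attribute.
#' @return Data frame `(subject, ddct, rq)`, one row per complete subject.
#' @export
relative_quantification <- function(table, target, reference = NULL) {
  reference <- reference %||% attr(table, "reference_target")
  if (is.null(reference)) stop("no reference target given")
  df <- as.data.frame(table)
  ct_of <- function(subj, tis, tgt) {
    v <- df$ct[df$subject == subj & df$tissue == tis & df$target == tgt]
    if (length(v) == 1) v else NA_real_
  }
  subjects <- unique(df$subject)
  rows <- lapply(subjects, function(s) {
    ct <- c(
      tt = ct_of(s, "tumor", target), tr = ct_of(s, "tumor", reference),
      nt = ct_of(s, "normal", target), nr = ct_of(s, "normal", reference)
    )
    if (anyNA(ct)) {
      return(NULL)
    }
    ddct <- (ct[["tt"]] - ct[["tr"]]) - (ct[["nt"]] - ct[["nr"]])
    data.frame(subject = s, ddct = ddct, rq = 2^(-ddct))
  })
  dropped <- subjects[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0) {
    warning(
      "subjects excluded (incomplete Ct records): ",
      paste(dropped, collapse = ", ")
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(subject = character(), ddct = numeric(), rq = numeric())
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test of relative quantities against 1
#'
#' Tests whether the RQ values depart from the null value 1, applied on the
#' symmetric log2 scale (`log2(RQ)` against 0). Values exactly equal to 1
#' (zero differences) are dropped first; at least 5 nonzero differences are
#' required. Exact two-sided p-values for 25 or fewer differences, normal
#' approximation with continuity correction above.
#'
#' @param rq_values Positive numeric vector of per-subject RQs.
#' @return List with `statistic` (sum of positive ranks `V`), `p_value`,
#'   `n_used`.
#' @export
wilcoxon_vs_unity <- function(rq_values) {
  if (any(rq_values <= 0)) stop("RQ values must be positive")
  x <- log2(rq_values)
  x <- x[x != 0]
  if (length(x) == 0) stop("all RQ values equal 1: test undefined")
  if (length(x) < 5) {
    stop("need at least 5 RQ values different from 1 (have ", length(x), ")")
  }
  exact <- length(x) <= 25 && !any(duplicated(abs(x)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, mu = 0, exact = exact, correct = TRUE)
  )
  list(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_used = length(x)
  )
}

#' Monte-Carlo power of the qPCR validation design
#'
#' Simulates validation cohorts with [generate_ct_table()] at the given
#' planted fold change and Ct noise, applies [relative_quantification()]
#' and [wilcoxon_vs_unity()], and estimates the probability of rejecting at
#' `alpha`. The binomial standard error of the estimate is attached as the
#' `se` attribute.
#'
#' @param n_subjects Cohort size per replicate.
#' @param fold_change Planted signed fold change (`1` gives the size of the
#'   test under the null).
#' @param ct_sd Ct measurement noise SD (cycles).
#' @param alpha Two-sided significance level, in (0, 1).
#' @param n_reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @return Power estimate in `[0, 1]` with attribute `se`.
#' @export
power_simulation <- function(n_subjects, fold_change, ct_sd, alpha = 0.05,
                             n_reps = 1000, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_reps < 100) stop("n_reps must be at least 100")
  reject <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    tab <- generate_ct_table(
      n_subjects, fold_change, ct_sd,
      seed = seed + 7L * r
    )
    rq <- relative_quantification(tab, "miR-target")
    p <- tryCatch(wilcoxon_vs_unity(rq$rq)$p_value, error = function(e) NA_real_)
    reject[r] <- !is.na(p) && p < alpha
  }
  pow <- mean(reject)
  structure(pow, se = sqrt(pow * (1 - pow) / n_reps))
}

#' Per-target validation report (Table-style summary)
#'
#' Median and mean RQ with quartiles and the Wilcoxon p-value for each
#' requested target — the usual reporting shape of qPCR validation tables.
#'
#' @param table A `ct_table`.
#' @param targets Character vector of target assays (default: every
#'   non-reference target present).
#' @param reference Reference assay (defaults to the table attribute).
#' @return Data frame with one row per target: `target`, `n`, `median_rq`,
#'   `mean_rq`, `q1_rq`, `q3_rq`, `p_value`.
#' @export
qpcr_report <- function(table, targets = NULL, reference = NULL) {
  reference <- reference %||% attr(table, "reference_target")
  df <- as.data.frame(table)
  if (is.null(targets)) targets <- setdiff(unique(df$target), reference)
  rows <- lapply(targets, function(tg) {
    rq <- relative_quantification(table, tg, reference)$rq
    wt <- tryCatch(wilcoxon_vs_unity(rq), error = function(e) NULL)
    q <- stats::quantile(rq, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(
      target = tg, n = length(rq), median_rq = q[2], mean_rq = mean(rq),
      q1_rq = q[1], q3_rq = q[3],
      p_value = if (is.null(wt)) NA_real_ else wt$p_value
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the qPCR report as TSV
#' @param report Output of [qpcr_report()].
#' @param path File path.
#' @export
write_qpcr_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
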