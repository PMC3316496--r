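#' Configuration for the paired-cohort generator
#'
#' Describes a synthetic matched tumour/normal cohort on the log2 scale:
#' a subject-level random effect shared by both tissues of a pair, planted
#' tissue effects (signed fold-changes) on selected features, optional
#' correlated feature modules driven by a shared latent factor, and i.i.d.
#' Gaussian within-pair noise.
#'
#' @param n_pairs Number of subjects (each contributes one tumour and one
#'   matched normal sample).
#' @param n_features Number of features (miRNAs).
#' @param baseline_mean Mean log2 expression.
#' @param baseline_sd Between-subject SD (log2 units); the subject effect is
#'   shared by the two tissues of a pair.
#' @param noise_sd Within-pair noise SD (log2 units).
#' @param de_plan Data frame (or list coercible to one) with columns
#'   `feature` (1-based index) and `fold_change` (signed linear convention:
#'   +2 doubles tumour expression, -2 halves it; `|fold_change| >= 1`).
#' @param module_plan List of modules, each `list(features = <indices>,
#'   rho = <target correlation in (-1,1)>)`. Module members share a latent
#'   per-sample factor with loading `sqrt(rho)`; their marginal variance is
#'   kept at `baseline_sd^2 + noise_sd^2`.
#' @param seed Integer seed; fixes every generated value.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pairs, n_features,
                             baseline_mean = 7, baseline_sd = 1,
                             noise_sd = 0.25,
                             de_plan = NULL, module_plan = list(),
                             seed = 1L) {
  stopifnot(
    n_pairs >= 1, n_features >= 1,
    baseline_sd > 0, noise_sd >= 0,
    is.numeric(seed), length(seed) == 1
  )
  if (is.null(de_plan)) {
    de_plan <- data.frame(feature = integer(), fold_change = numeric())
  }
  de_plan <- as.data.frame(de_plan)
  if (nrow(de_plan) > 0) {
    stopifnot(all(c("feature", "fold_change") %in% names(de_plan)))
    if (any(de_plan$feature < 1 | de_plan$feature > n_features)) {
      stop("de_plan feature index out of range")
    }
    if (any(de_plan$fold_change == 0) || any(abs(de_plan$fold_change) < 1)) {
      stop("planted fold changes must satisfy |fold_change| >= 1")
    }
    dup <- split(de_plan$fold_change, de_plan$feature)
    bad <- names(dup)[vapply(dup, function(v) length(unique(v)) > 1, logical(1))]
    if (length(bad) > 0) {
      stop(
        "contradictory fold changes planted at feature(s): ",
        paste(bad, collapse = ", ")
      )
    }
    de_plan <- de_plan[!duplicated(de_plan$feature), , drop = FALSE]
  }
  for (mod in module_plan) {
    stopifnot(is.list(mod), !is.null(mod$features), !is.null(mod$rho))
    if (length(mod$features) < 2) stop("module feature sets need size >= 2")
    if (any(mod$features < 1 | mod$features > n_features)) {
      stop("module_plan feature index out of range")
    }
    if (mod$rho <= -1 || mod$rho >= 1) stop("target correlation must be in (-1, 1)")
  }
  all_mod <- unlist(lapply(module_plan, `[[`, "features"))
  if (anyDuplicated(all_mod)) stop("modules must not share features")
  structure(
    list(
      n_pairs = as.integer(n_pairs), n_features = as.integer(n_features),
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      noise_sd = noise_sd, de_plan = de_plan, module_plan = module_plan,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# deterministic per-stage sub-seed from the single global seed
substream_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, ct = 29L, mda = 57L, forest = 83L)
  s <- (as.integer(seed) %% 1000000L) * 2011L + offsets[[stage]]
  as.integer(s %% .Machine$integer.max)
}

#' Generate a paired tumour/normal cohort
#'
#' Draws a log2 expression matrix under the additive model
#' `value = baseline + subject effect + tissue effect + module factor + noise`.
#' Planted differentially expressed features receive a tumour-only shift of
#' `sign(fold_change) * log2(|fold_change|)`; module members are driven by a
#' shared per-sample standard-normal factor so their pairwise correlation
#' approaches the target as the cohort grows.
#'
#' @param config A [generator_config()].
#' @return A [paired_study()]. Sample ids are `P<k>_T` / `P<k>_N`.
#' @export
generate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_pairs
  m <- config$n_features
  set.seed(substream_seed(config$seed, "cohort"))

  feature_ids <- sprintf("miR-%03d", seq_len(m))
  subj <- sprintf("P%02d", seq_len(n))
  tumor_ids <- paste0(subj, "_T")
  normal_ids <- paste0(subj, "_N")

  subject_eff <- matrix(stats::rnorm(m * n, 0, config$baseline_sd), m, n)
  noise_t <- matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)
  noise_n <- matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)

  tum <- config$baseline_mean + subject_eff + noise_t
  nor <- config$baseline_mean + subject_eff + noise_n

  if (nrow(config$de_plan) > 0) {
    idx <- config$de_plan$feature
    fc <- config$de_plan$fold_change
    shift <- sign(fc) * log2(abs(fc))
    tum[idx, ] <- tum[idx, ] + shift
  }

  # module members: equicorrelated per-sample component with total marginal
  # variance baseline_sd^2 + noise_sd^2 (replaces their subject effect/noise)
  sigma_tot <- sqrt(config$baseline_sd^2 + config$noise_sd^2)
  for (mod in config$module_plan) {
    rho <- mod$rho
    s <- sign(rho)
    a <- sqrt(abs(rho))
    b <- sqrt(1 - abs(rho))
    f_t <- stats::rnorm(n)
    f_n <- stats::rnorm(n)
    for (j in mod$features) {
      # alternate loading sign for negative target correlations
      lam <- if (s >= 0) a else a * ifelse(match(j, mod$features) %% 2 == 0, -1, 1)
      z_t <- stats::rnorm(n)
      z_n <- stats::rnorm(n)
      base_t <- config$baseline_mean + sigma_tot * (lam * f_t + b * z_t)
      base_n <- config$baseline_mean + sigma_tot * (lam * f_n + b * z_n)
      de_row <- config$de_plan$feature == j
      shift <- if (any(de_row)) {
        fc <- config$de_plan$fold_change[de_row][1]
        sign(fc) * log2(abs(fc))
      } else 0
      tum[j, ] <- base_t + shift
      nor[j, ] <- base_n
    }
  }

  mat <- cbind(tum, nor)
  rownames(mat) <- feature_ids
  colnames(mat) <- c(tumor_ids, normal_ids)
  paired_study(mat, stats::setNames(normal_ids, tumor_ids))
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a validation cohort measured by comparative-Ct qPCR: one target
#' assay and one reference assay (default `RNU6B`) per subject and tissue.
#' The planted linear-scale tumour/normal ratio is `fold_change` for
#' up-regulation (`fold_change >= 1`) and `-1/fold_change` for
#' down-regulation (`fold_change <= -1`), so the expected `2^-ddCt` over
#' subjects equals the planted ratio.
#'
#' @param n_subjects Number of subjects.
#' @param fold_change Signed fold change (`|fold_change| >= 1`).
#' @param ct_sd SD of the Gaussian noise added to every Ct measurement
#'   (cycles); `0` gives noise-free tables, negative values are rejected.
#' @param seed Integer seed.
#' @param target,reference Assay names.
#' @param target_base_ct,reference_base_ct Baseline threshold cycles.
#' @return A `ct_table` data frame with columns
#'   `subject`, `tissue`, `target`, `ct` and attribute `reference_target`.
#' @export
generate_ct_table <- function(n_subjects, fold_change, ct_sd, seed = 1L,
                              target = "miR-target", reference = "RNU6B",
                              target_base_ct = 26, reference_base_ct = 19) {
  stopifnot(n_subjects >= 1)
  if (ct_sd < 0) stop("ct_sd must be nonnegative")
  if (abs(fold_change) < 1) stop("|fold_change| must be >= 1")
  set.seed(substream_seed(seed, "ct"))
  ratio <- if (fold_change >= 1) fold_change else -1 / fold_change
  # tumour target Ct is lowered by log2(ratio): ddCt = -log2(ratio)
  shift <- log2(ratio)
  subj <- sprintf("S%03d", seq_len(n_subjects))
  grid <- expand.grid(
    subject = subj, tissue = c("tumor", "normal"),
    target = c(target, reference),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  base <- ifelse(grid$target == reference, reference_base_ct, target_base_ct)
  base <- base - ifelse(grid$target == target & grid$tissue == "tumor", shift, 0)
  grid$ct <- base + stats::rnorm(nrow(grid), 0, ct_sd)
  grid <- grid[order(grid$subject, grid$tissue, grid$target), ]
  rownames(grid) <- NULL
  structure(grid, reference_target = reference, class = c("ct_table", "data.frame"))
}

#' Write / read Ct tables as CSV (`subject,tissue,target,ct`)
#' @param table A `ct_table` data frame.
#' @param path File path.
#' @param reference_target Reference assay name used when reading.
#' @name ct_io
#' @return `read_ct_table` returns a `ct_table`.
#' @export
write_ct_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("subject", "tissue", "target", "ct")],
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname ct_io
#' @export
read_ct_table <- function(path, reference_target = "RNU6B") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "tissue", "target", "ct") %in% names(df)))
  structure(df, reference_target = reference_target, class = c("ct_table", "data.frame"))
}
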