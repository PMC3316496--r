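#' Random-forest configuration
#'
#' Settings for the tumour/normal tissue classifier. Defaults follow the
#' bias-avoiding recommendations for permutation importance: trees are grown
#' on subsamples drawn *without* replacement (fraction 0.632), to full depth
#' without pruning, with Gini splits on `floor(sqrt(m))` candidate features
#' per node.
#'
#' @param n_trees Number of trees (default 1000; large studies may use
#'   100000).
#' @param subsample_fraction Fraction of observations per tree, in (0, 1].
#' @param mtry `"sqrt"` (default, `floor(sqrt(n_features))`) or a positive
#'   integer.
#' @param replace Draw the per-tree learning sets with replacement
#'   (classic bagging) instead of subsampling without replacement.
#' @param conditional_corr_threshold Features whose absolute Spearman
#'   correlation with the permuted feature exceeds this value form the
#'   conditioning set of the conditional permutation scheme; `1` (or more)
#'   gives unconditional permutation.
#' @param seed Integer seed; fixes the fit and the importance permutations.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 1000, subsample_fraction = 0.632,
                          mtry = "sqrt", replace = FALSE,
                          conditional_corr_threshold = 0.2, seed = 1L) {
  stopifnot(
    n_trees >= 1,
    subsample_fraction > 0, subsample_fraction <= 1,
    conditional_corr_threshold >= 0,
    is.numeric(seed), length(seed) == 1
  )
  if (!identical(mtry, "sqrt")) {
    stopifnot(is.numeric(mtry), mtry >= 1)
    mtry <- as.integer(mtry)
  }
  structure(
    list(
      n_trees = as.integer(n_trees),
      subsample_fraction = subsample_fraction,
      mtry = mtry, replace = isTRUE(replace),
      conditional_corr_threshold = conditional_corr_threshold,
      seed = as.integer(seed)
    ),
    class = "forest_config"
  )
}

#' Fit the tumour/normal random forest
#'
#' Grows an ensemble of CART trees on the sample x feature matrix of a
#' paired study, labelling each sample tumour or normal from the pairing
#' map, and estimates the out-of-bag (OOB) error: the fraction of samples
#' misclassified by the majority vote of the trees for which they were out
#' of sample.
#'
#' @param study A [paired_study()] with at least 4 samples.
#' @param config A [forest_config()].
#' @return A `mir_forest` object: `trees`, `oob` (per-tree out-of-sample
#'   row indices), `X` (samples x features), `y` (0 = normal, 1 = tumor),
#'   `oob_error`, `oob_votes`, `config`.
#' @export
fit_forest <- function(study, config = forest_config()) {
  stopifnot(inherits(study, "paired_study"), inherits(config, "forest_config"))
  X <- t(study$matrix)
  y <- as.integer(tissue_labels(study) == "tumor")
  if (nrow(X) < 4) stop("random forest needs at least 4 samples")
  if (length(unique(y)) < 2) stop("both tissue classes must be present")
  mtry <- if (identical(config$mtry, "sqrt")) {
    max(1L, floor(sqrt(ncol(X))))
  } else {
    if (config$mtry > ncol(X)) stop("mtry exceeds the number of features")
    config$mtry
  }
  set.seed(substream_seed(config$seed, "forest"))
  fit <- grow_forest_cpp(
    X, y, config$n_trees, mtry,
    config$subsample_fraction, config$replace
  )
  preds <- forest_predict_per_tree_cpp(fit$trees, X)
  oob_mask <- matrix(FALSE, nrow(X), config$n_trees)
  for (t in seq_len(config$n_trees)) oob_mask[fit$oob[[t]], t] <- TRUE
  votes1 <- rowSums(preds * oob_mask)
  nvotes <- rowSums(oob_mask)
  # majority vote; ties and never-OOB samples resolve to class 0 (normal)
  oob_pred <- as.integer(votes1 > nvotes / 2)
  counted <- nvotes > 0
  structure(
    list(
      trees = fit$trees, oob = fit$oob, X = X, y = y,
      feature_ids = colnames(X), sample_ids = rownames(X),
      mtry = mtry,
      oob_error = mean(oob_pred[counted] != y[counted]),
      oob_votes = data.frame(
        sample_id = rownames(X), n_oob_trees = nvotes,
        oob_prediction = ifelse(counted, oob_pred, NA_integer_)
      ),
      config = config
    ),
    class = "mir_forest"
  )
}

#' @export
print.mir_forest <- function(x, ...) {
  cat(sprintf(
    "mir_forest: %d trees, %d samples x %d features, OOB error %.4f\n",
    length(x$trees), nrow(x$X), ncol(x$X), x$oob_error
  ))
  invisible(x)
}

#' Conditional permutation importance (mean decrease in accuracy)
#'
#' For each feature, its out-of-bag values are permuted within the strata
#' that the in-tree split points of correlated covariates induce (Strobl's
#' conditional permutation scheme), and the increase in per-tree OOB
#' misclassification is averaged over trees. The conditioning set of a
#' feature contains the covariates whose absolute Spearman correlation with
#' it (computed once on the full data) exceeds
#' `config$conditional_corr_threshold`; an empty conditioning set reduces to
#' the classical unconditional permutation importance.
#'
#' @param model A fitted [fit_forest()] model.
#' @param conditional_corr_threshold Override of the threshold stored in the
#'   model's config.
#' @return An importance table (data frame): `feature_id`, `mda`, `rank`
#'   (rank 1 = largest MDA; ties broken by feature id).
#' @export
conditional_mda <- function(model, conditional_corr_threshold = NULL) {
  stopifnot(inherits(model, "mir_forest"))
  thr <- conditional_corr_threshold %||% model$config$conditional_corr_threshold
  m <- ncol(model$X)
  if (thr < 1) {
    rho <- suppressWarnings(stats::cor(model$X, method = "spearman"))
    cond_sets <- lapply(seq_len(m), function(j) {
      cand <- which(abs(rho[j, ]) > thr & seq_len(m) != j)
      as.integer(cand)
    })
  } else {
    cond_sets <- rep(list(integer(0)), m)
  }
  set.seed(substream_seed(model$config$seed, "mda"))
  mda <- conditional_mda_cpp(model$trees, model$oob, model$X, model$y, cond_sets)
  ord <- order(-mda, model$feature_ids)
  rank <- integer(m)
  rank[ord] <- seq_len(m)
  data.frame(feature_id = model$feature_ids, mda = mda, rank = rank)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Out-of-bag proximity matrix
#'
#' Proximity of two samples is the fraction of trees in which they fall in
#' the same leaf. By default only trees for which *both* samples are out of
#' sample are counted (the less optimistic OOB variant); `all_trees = TRUE`
#' counts every tree. Pairs never jointly out of sample are `NA` and listed
#' in the `missing_pairs` attribute.
#'
#' @param model A fitted [fit_forest()] model.
#' @param all_trees Count all trees instead of jointly-OOB trees only.
#' @return Symmetric samples x samples matrix in `[0, 1]`, unit diagonal.
#' @export
proximity_matrix <- function(model, all_trees = FALSE) {
  stopifnot(inherits(model, "mir_forest"))
  n <- nrow(model$X)
  leaves <- forest_leaf_ids_cpp(model$trees, model$X)
  n_trees <- ncol(leaves)
  same <- matrix(0, n, n)
  denom <- matrix(0, n, n)
  if (all_trees) {
    for (t in seq_len(n_trees)) {
      eq <- outer(leaves[, t], leaves[, t], "==")
      same <- same + eq
    }
    denom[] <- n_trees
  } else {
    oob_mask <- matrix(FALSE, n, n_trees)
    for (t in seq_len(n_trees)) oob_mask[model$oob[[t]], t] <- TRUE
    for (t in seq_len(n_trees)) {
      ob <- which(oob_mask[, t])
      if (length(ob) < 1) next
      eq <- outer(leaves[ob, t], leaves[ob, t], "==")
      same[ob, ob] <- same[ob, ob] + eq
      denom[ob, ob] <- denom[ob, ob] + 1
    }
  }
  prox <- ifelse(denom > 0, same / denom, NA_real_)
  diag(prox) <- 1
  dimnames(prox) <- list(model$sample_ids, model$sample_ids)
  miss <- which(is.na(prox) & upper.tri(prox), arr.ind = TRUE)
  attr(prox, "missing_pairs") <- if (nrow(miss) > 0) {
    data.frame(
      sample_a = model$sample_ids[miss[, 1]],
      sample_b = model$sample_ids[miss[, 2]]
    )
  } else {
    NULL
  }
  prox
}

#' Classical MDS embedding of a proximity matrix
#'
#' Torgerson (classical) multidimensional scaling on the dissimilarity
#' `1 - proximity`. Dimensions whose eigenvalues are zero (coincident
#' configurations) come back as zero coordinates.
#'
#' @param proximity Symmetric matrix with unit diagonal (no `NA`s; see
#'   [proximity_matrix()] with `all_trees = TRUE` if the OOB variant leaves
#'   gaps).
#' @param dims Number of leading coordinates (must be `< nrow`).
#' @return Samples x `dims` coordinate matrix.
#' @export
mds_embedding <- function(proximity, dims = 2) {
  p <- unclass(proximity)
  attr(p, "missing_pairs") <- NULL
  if (anyNA(p)) stop("proximity matrix has missing entries; use all_trees = TRUE")
  if (!isSymmetric(unname(p), tol = 1e-8)) stop("proximity matrix must be symmetric")
  if (any(abs(diag(p) - 1) > 1e-8)) stop("proximity diagonal must be 1")
  n <- nrow(p)
  if (dims >= n) stop("dims must be smaller than the number of samples")
  d <- 1 - p
  fit <- suppressWarnings(stats::cmdscale(d, k = dims))
  if (ncol(fit) < dims) { # rank-deficient: pad null dimensions with zeros
    fit <- cbind(fit, matrix(0, n, dims - ncol(fit)))
  }
  rownames(fit) <- rownames(p)
  colnames(fit) <- paste0("MDS", seq_len(dims))
  fit
}

#' Write the importance table as TSV
#' @param imp_table Output of [conditional_mda()].
#' @param path File path.
#' @export
write_importance_table <- function(imp_table, path) {
  utils::write.table(imp_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an importance table written by [write_importance_table()]
#' @param path File path.
#' @export
read_importance_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
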