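#' Assemble a pipeline configuration
#'
#' End-to-end settings for the discovery pipeline: either a synthetic
#' cohort description (`simulate`) or paths to an expression matrix and
#' pairing table, plus the per-stage parameters. Signature thresholds are
#' study decisions and have no defaults.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed; per-stage sub-seeds derive from it.
#' @param simulate `NULL`, or a list of [generator_config()] arguments for
#'   a synthetic cohort.
#' @param expression_path,pairing_path Input files used when `simulate` is
#'   `NULL`.
#' @param ratio_scale `"geometric"` or `"arithmetic"` expression ratios.
#' @param forest List of [forest_config()] arguments.
#' @param p_threshold,mda_threshold Signature thresholds
#'   (see [merge_rankings()]).
#' @param alpha,tissue,weight_mode Network stage settings
#'   (see [build_network()]).
#' @param ct_path Optional Ct CSV for a qPCR validation stage.
#' @param ct_reference Reference assay of the Ct table.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            simulate = NULL,
                            expression_path = NULL, pairing_path = NULL,
                            ratio_scale = "geometric",
                            forest = list(),
                            p_threshold, mda_threshold,
                            alpha = 0.05, tissue = "tumor",
                            weight_mode = "raw_abs",
                            ct_path = NULL, ct_reference = "RNU6B") {
  if (is.null(simulate)) {
    if (is.null(expression_path) || is.null(pairing_path)) {
      stop("either `simulate` or both `expression_path` and `pairing_path` are required")
    }
    for (p in c(expression_path, pairing_path, ct_path)) {
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
    }
  } else if (!is.null(ct_path) && !file.exists(ct_path)) {
    stop("input file not found: ", ct_path)
  }
  if (missing(p_threshold) || missing(mda_threshold)) {
    stop("signature thresholds p_threshold and mda_threshold must be given")
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
      expression_path = expression_path, pairing_path = pairing_path,
      ratio_scale = ratio_scale, forest = forest,
      p_threshold = p_threshold, mda_threshold = mda_threshold,
      alpha = alpha, tissue = tissue, weight_mode = weight_mode,
      ct_path = ct_path, ct_reference = ct_reference
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the [pipeline_config()] arguments; `seed` and
#' `out_dir` arguments override the file.
#'
#' @param path YAML file.
#' @param seed,out_dir Optional overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL, out_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

#' Run the full discovery pipeline
#'
#' Orchestrates every stage — cohort (simulated or loaded), paired
#' differential expression, random forest with conditional permutation
#' importance, signature merge, correlation network with centralities, and
#' optional qPCR validation — writing each stage's table to `out_dir`
#' together with a JSON manifest recording package version, seed,
#' parameters and stage status. On stage failure the manifest records the
#' failing stage and partial outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) list with the in-memory stage results and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "mirsignet",
    version = as.character(utils::packageVersion("mirsignet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("out_dir"))],
    outputs = list(),
    stages = list()
  )
  results <- list(out_dir = config$out_dir)
  outfile <- function(name) file.path(config$out_dir, name)
  write_manifest <- function() {
    jsonlite::write_json(manifest, outfile("manifest.json"),
      auto_unbox = TRUE, null = "null", force = TRUE, pretty = TRUE
    )
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  study <- run_stage("cohort", function() {
    if (!is.null(config$simulate)) {
      gc_args <- config$simulate
      gc_args$seed <- gc_args$seed %||% config$seed
      st <- generate_paired_cohort(do.call(generator_config, gc_args))
      write_expression_matrix(st, outfile("expression_matrix.tsv"))
      write_pairing(st, outfile("pairing.tsv"))
      manifest$outputs$expression_matrix <<- "expression_matrix.tsv"
      manifest$outputs$pairing <<- "pairing.tsv"
      st
    } else {
      if (!file.exists(config$expression_path)) {
        stop("expression matrix not found: ", config$expression_path)
      }
      if (!file.exists(config$pairing_path)) {
        stop("pairing file not found: ", config$pairing_path)
      }
      paired_study(
        read_expression_matrix(config$expression_path),
        read_pairing(config$pairing_path)
      )
    }
  })
  results$study <- study

  de <- run_stage("diffexpr", function() {
    tab <- differential_table(study, scale = config$ratio_scale)
    write_differential_table(tab, outfile("differential.tsv"))
    manifest$outputs$differential <<- "differential.tsv"
    tab
  })
  results$differential <- de

  imp <- run_stage("rf", function() {
    fc_args <- config$forest
    fc_args$seed <- fc_args$seed %||% config$seed
    model <- fit_forest(study, do.call(forest_config, fc_args))
    tab <- conditional_mda(model)
    write_importance_table(tab, outfile("importance.tsv"))
    manifest$outputs$importance <<- "importance.tsv"
    manifest$stages$rf$oob_error <<- model$oob_error
    results$forest <<- model
    tab
  })
  results$importance <- imp

  sig <- run_stage("signature", function() {
    s <- merge_rankings(de, imp, config$p_threshold, config$mda_threshold)
    write_signature(s, outfile("signature.tsv"))
    manifest$outputs$signature <<- "signature.tsv"
    s
  })
  results$signature <- sig

  net <- run_stage("network", function() {
    if (nrow(sig) == 0) {
      stop("signature is empty; no network to build")
    }
    nw <- build_network(study, sig,
      alpha = config$alpha,
      tissue = config$tissue, weight_mode = config$weight_mode
    )
    write_edge_list(nw, outfile("network_edges.tsv"))
    write_network_graphml(nw, outfile("network.graphml"))
    utils::write.table(centrality_report(nw), outfile("centrality.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    manifest$outputs$network_edges <<- "network_edges.tsv"
    manifest$outputs$network_graphml <<- "network.graphml"
    manifest$outputs$centrality <<- "centrality.tsv"
    nw
  })
  results$network <- net

  if (!is.null(config$ct_path)) {
    results$qpcr <- run_stage("qpcr", function() {
      if (!file.exists(config$ct_path)) {
        stop("Ct table not found: ", config$ct_path)
      }
      tab <- read_ct_table(config$ct_path, reference_target = config$ct_reference)
      rep <- qpcr_report(tab)
      write_qpcr_report(rep, outfile("qpcr_report.tsv"))
      manifest$outputs$qpcr_report <<- "qpcr_report.tsv"
      rep
    })
  }

  write_manifest()
  invisible(results)
}
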