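#' Default pipeline configuration
#'
#' Analysis settings mirror the study design the package implements:
#' density grid 10-34% in 1% steps, 10,000 permutations, NBS primary
#' threshold p < 0.001 (two-tailed) with component alpha 0.025 per
#' direction, FDR 0.05, Tikhonov partial correlation with lambda = 1.
#'
#' @param ... Overrides for any configuration field.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    method = "tikhonov_partial",
    lambda = 1,
    densities = density_grid(),
    n_null = 100L,
    n_perm = 10000L,
    nbs_primary_alpha = 0.001,
    nbs_component_alpha = 0.025,
    fdr_alpha = 0.05,
    seed = 1L,
    stages = c("connectivity", "graph", "gtest", "nbs", "blocks",
               "assoc"),
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] fields.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Per-stage seeds derived from the master seed by a fixed counter
# scheme, so partial reruns of a stage are reproducible on their own.
stage_seed <- function(master, stage) {
  offsets <- c(simulate = 1L, connectivity = 2L, graph = 3L, gtest = 4L,
               nbs = 5L, blocks = 6L, assoc = 7L)
  (as.integer(master) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full connectome group-analysis pipeline
#'
#' Orchestrates connectivity construction, density-grid graph metrics
#' with AUC, covariate-adjusted max-statistic permutation tests, the
#' Network-Based Statistic, Yeo-7 block comparison and the clinical
#' correlation scan on a cohort of time series; stages can be toggled
#' via `config$stages`. Results are returned and, when
#' `config$out_dir` is set, written with [write_results()].
#'
#' @param ts_list Named list of `fc_timeseries` (e.g. from
#'   [sample_cohort()] or [read_timeseries()]).
#' @param pheno Validated phenotype table.
#' @param atlas The `fc_atlas`.
#' @param config Configuration list ([pipeline_config()]), or a path to
#'   a YAML file.
#' @return List with elements `fc`, `metrics`, `gtest`, `nbs`,
#'   `blocks`, `assoc` (enabled stages only) and `config`.
#' @export
run_pipeline <- function(ts_list, pheno, atlas,
                         config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  pheno <- as_phenotypes(pheno, names(ts_list))
  res <- list(config = config)
  stages <- config$stages
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  res$fc <- run_stage("connectivity", function() {
    build_fc_stack(ts_list, method = config$method,
                   lambda = config$lambda)
  })
  if ("graph" %in% stages) {
    res$metrics <- run_stage("graph", function() {
      cohort_metrics(res$fc, densities = config$densities,
                     n_null = config$n_null,
                     seed = stage_seed(config$seed, "graph"))
    })
  }
  if ("gtest" %in% stages && !is.null(res$metrics)) {
    res$gtest <- run_stage("gtest", function() {
      metric_group_test(res$metrics, pheno, n_perm = config$n_perm,
                        seed = stage_seed(config$seed, "gtest"),
                        atlas = atlas)
    })
  }
  if ("nbs" %in% stages) {
    res$nbs <- run_stage("nbs", function() {
      nbs_test(res$fc, pheno,
               nbs_config(primary_alpha = config$nbs_primary_alpha,
                          n_perm = config$n_perm,
                          component_alpha = config$nbs_component_alpha,
                          seed = stage_seed(config$seed, "nbs")),
               atlas = atlas)
    })
  }
  if ("blocks" %in% stages) {
    res$blocks <- run_stage("blocks", function() {
      blk <- block_average_stack(res$fc, atlas)
      out <- block_group_test(blk, pheno, n_perm = config$n_perm,
                              seed = stage_seed(config$seed, "blocks"))
      out$values <- blk
      out
    })
  }
  if ("assoc" %in% stages && !is.null(res$metrics)) {
    res$assoc <- run_stage("assoc", function() {
      pat <- pheno$group == "patient"
      idx <- res$metrics$global_auc[pat,
                                    setdiff(names(res$metrics$global_auc),
                                            "subject_id")]
      scores <- pheno[pat, intersect(c("sas", "sds", "wexner"),
                                     names(pheno)), drop = FALSE]
      covs <- pheno[pat, c("age", "sex", "mean_fd", "cortex_volume")]
      assoc_scan(idx, scores, covs)
    })
  }
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}
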