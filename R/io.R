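#' Construct a per-subject parcel time-series object
#'
#' @param subject_id Subject identifier.
#' @param data Numeric matrix, timepoints x parcels, columns in atlas
#'   order.
#' @param tr_seconds Repetition time in seconds.
#' @param atlas Optional `fc_atlas`; when given, the column count is
#'   checked against it.
#' @return An object of class `fc_timeseries`.
#' @export
as_timeseries <- function(subject_id, data, tr_seconds = 2, atlas = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.null(atlas) && ncol(data) != nrow(atlas)) {
    stop(sprintf("subject %s: %d columns but atlas has %d parcels",
                 subject_id, ncol(data), nrow(atlas)), call. = FALSE)
  }
  if (tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  bad <- which(!is.finite(data))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1L], dim(data))
    stop(sprintf("subject %s: non-finite value at timepoint %d, parcel %d",
                 subject_id, rc[1L], rc[2L]), call. = FALSE)
  }
  if (nrow(data) < 30L) {
    stop(sprintf("subject %s: only %d timepoints; at least 30 required for a usable covariance estimate",
                 subject_id, nrow(data)), call. = FALSE)
  }
  sds <- apply(data, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("subject %s: zero-variance parcel column(s): %s",
                 subject_id, paste(which(sds == 0), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(data) < ncol(data) / 10) {
    warning(sprintf("subject %s: T = %d is short relative to N = %d parcels; covariance estimates will be unstable",
                    subject_id, nrow(data), ncol(data)), call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), data = data,
                 tr_seconds = tr_seconds),
            class = "fc_timeseries")
}

#' Read per-subject time-series TSV files from a directory
#'
#' One tab-separated file per subject (no header), `T` rows by `N`
#' columns; the file name without extension is the subject id.
#'
#' @param dir Directory containing `<subject_id>.tsv` files.
#' @param atlas An `fc_atlas`; every file must have `nrow(atlas)` columns.
#' @param tr_seconds Repetition time in seconds (shared across subjects).
#' @return Named list of `fc_timeseries`, ordered by file name.
#' @export
read_timeseries <- function(dir, atlas, tr_seconds = 2) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .tsv files in ", dir, call. = FALSE)
  out <- lapply(files, function(f) {
    id <- sub("\\.tsv$", "", basename(f))
    mat <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    dimnames(mat) <- NULL
    as_timeseries(id, mat, tr_seconds = tr_seconds, atlas = atlas)
  })
  names(out) <- vapply(out, `[[`, character(1L), "subject_id")
  out
}

#' Write a list of time-series objects to a directory
#' @param ts_list Named list of `fc_timeseries`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the file paths.
#' @export
write_timeseries <- function(ts_list, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(ts_list, function(ts) {
    p <- file.path(dir, paste0(ts$subject_id, ".tsv"))
    utils::write.table(ts$data, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    p
  }, character(1L))
  invisible(paths)
}

#' Validate a phenotype table against a time-series collection
#'
#' @param pheno data.frame with columns `subject_id`, `group`
#'   (`"patient"`/`"control"`), `age`, `sex` (0 = F, 1 = M), `mean_fd`,
#'   `cortex_volume`, and clinical score columns (`sas`, `sds`,
#'   `wexner`; may contain NA, e.g. Wexner for controls).
#' @param subject_ids Character vector the table must match exactly
#'   (typically `names(ts_list)`), or NULL to skip the check.
#' @return The validated data.frame, reordered to `subject_ids`.
#' @export
as_phenotypes <- function(pheno, subject_ids = NULL) {
  pheno <- as.data.frame(pheno, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "mean_fd",
                "cortex_volume")
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(pheno$subject_id)) {
    stop("duplicate subject_id in phenotype table", call. = FALSE)
  }
  if (!all(pheno$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'", call. = FALSE)
  }
  if (!all(c("patient", "control") %in% pheno$group)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  covs <- c("age", "sex", "mean_fd", "cortex_volume")
  for (cv in covs) {
    if (anyNA(pheno[[cv]]) || any(!is.finite(pheno[[cv]]))) {
      stop("covariate column '", cv, "' has missing/non-finite values",
           call. = FALSE)
    }
  }
  if (!all(pheno$sex %in% c(0, 1))) {
    stop("sex must be coded 0 (F) / 1 (M)", call. = FALSE)
  }
  if (!is.null(subject_ids)) {
    if (!setequal(pheno$subject_id, subject_ids) ||
        nrow(pheno) != length(subject_ids)) {
      stop("phenotype subject_ids do not match the time-series subjects",
           call. = FALSE)
    }
    pheno <- pheno[match(subject_ids, pheno$subject_id), , drop = FALSE]
    rownames(pheno) <- NULL
  }
  pheno
}

#' Read a phenotype TSV file
#' @inheritParams as_phenotypes
#' @param path Path to a tab-separated file with header.
#' @return Validated phenotype data.frame.
#' @export
read_phenotypes <- function(path, subject_ids = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path,
                               call. = FALSE)
  as_phenotypes(utils::read.delim(path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE), subject_ids)
}

#' Write / read a square matrix as dense TSV keyed by parcel id
#'
#' The first row and first column carry parcel ids, so a round trip is
#' value-identical and order-checked.
#'
#' @param m Square numeric matrix.
#' @param path File path.
#' @return `write_matrix`: invisibly `path`; `read_matrix`: the matrix.
#' @export
write_matrix <- function(m, path) {
  n <- nrow(m)
  out <- cbind(parcel = seq_len(n), m)
  colnames(out) <- c("parcel_id", seq_len(n))
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Write the result tables of a pipeline run
#'
#' Writes the per-subject z-matrices (subdirectory `zmatrices/`), the
#' metric AUC table, the global and nodal permutation tables, the NBS
#' edge list, the block-FC table, the clinical correlation table, and a
#' YAML run-metadata file recording seed, thresholds, permutation count
#' and package version.
#'
#' @param results A list as returned by [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, a character vector of written paths.
#' @export
write_results <- function(results, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0L)
  if (!is.null(results$fc)) {
    zd <- file.path(dir, "zmatrices")
    dir.create(zd, showWarnings = FALSE)
    for (fc in results$fc) {
      paths <- c(paths, write_matrix(fc$z, file.path(
        zd, paste0(fc$subject_id, "_z.tsv"))))
    }
  }
  if (!is.null(results$metrics)) {
    paths <- c(paths, wt(results$metrics$global_auc,
                         "metric_auc_global.tsv"))
  }
  if (!is.null(results$gtest)) {
    paths <- c(paths, wt(results$gtest$global, "perm_global.tsv"))
    if (!is.null(results$gtest$nodal)) {
      paths <- c(paths, wt(results$gtest$nodal, "perm_nodal.tsv"))
    }
  }
  if (!is.null(results$nbs)) {
    paths <- c(paths, wt(nbs_edge_table(results$nbs), "nbs_edges.tsv"))
  }
  if (!is.null(results$blocks)) {
    paths <- c(paths, wt(results$blocks$table, "block_fc.tsv"))
  }
  if (!is.null(results$assoc)) {
    paths <- c(paths, wt(results$assoc, "clinical_assoc.tsv"))
  }
  meta <- list(
    package_version = as.character(utils::packageVersion("connectoperm")),
    seed = results$config$seed,
    n_perm = results$config$n_perm,
    method = results$config$method,
    lambda = results$config$lambda,
    densities = results$config$densities,
    n_null = results$config$n_null,
    nbs_primary_alpha = results$config$nbs_primary_alpha,
    nbs_component_alpha = results$config$nbs_component_alpha,
    fdr_alpha = results$config$fdr_alpha
  )
  mp <- file.path(dir, "run_metadata.yaml")
  yaml::write_yaml(meta, mp)
  invisible(c(paths, mp))
}
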