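#' Specify a synthetic two-group cohort
#'
#' Defines a seeded generative model for a case-control resting-state
#' cohort: per-subject Gaussian parcel time series with AR(1) temporal
#' autocorrelation and a block-structured spatial correlation keyed to
#' the atlas's Yeo-7 labels, plus phenotypes (age, sex, head motion,
#' cortex volume) and clinical scores. Group differences are injected
#' either on individual edges (`effect_edges`) or on whole network
#' blocks (`effect_blocks`), always on the patient group's target
#' correlation matrix.
#'
#' Defaults emulate a cohort of 35 patients and 40 matched controls with
#' 170 retained volumes at TR = 2 s; age, sex ratio, anxiety/depression
#' (SAS/SDS) and constipation (Wexner) score distributions follow values
#' typical of functional-constipation case-control samples.
#'
#' @param atlas An `fc_atlas` ([synthetic_atlas()] by default builds one).
#' @param n_patients,n_controls Group sizes.
#' @param n_timepoints Retained timepoints per subject.
#' @param tr_seconds Repetition time (s).
#' @param base_within_block_r Correlation between parcels of the same
#'   network, in `[0, 1)`.
#' @param base_between_block_r Correlation between parcels of different
#'   networks.
#' @param effect_edges data.frame (`node_i`, `node_j`, `delta_r`) of
#'   edge-wise correlation shifts applied to patients, or NULL.
#' @param effect_blocks data.frame (`network_a`, `network_b`, `delta_r`)
#'   of block-wise shifts applied to patients, or NULL.
#' @param temporal_smoothing AR(1) coefficient in `[0, 1)`; 0 gives
#'   i.i.d. timepoints.
#' @param age_mean,age_sd,male_prop Per-group covariate parameters
#'   (length-2 vectors, patient first).
#' @param fd_meanlog,fd_sdlog Log-normal mean-FD parameters (length 2).
#' @param cortex_volume_mean,cortex_volume_sd Cortex volume (mm^3).
#' @param sas_mean,sas_sd,sds_mean,sds_sd Clinical score parameters
#'   (length 2, patient first).
#' @param wexner_mean,wexner_sd Constipation score (patients only).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(atlas = synthetic_atlas(400L),
                        n_patients = 35L, n_controls = 40L,
                        n_timepoints = 170L, tr_seconds = 2,
                        base_within_block_r = 0.4,
                        base_between_block_r = 0.1,
                        effect_edges = NULL, effect_blocks = NULL,
                        temporal_smoothing = 0.3,
                        age_mean = c(47.2, 45.1), age_sd = c(12.8, 13.1),
                        male_prop = c(6 / 35, 13 / 40),
                        fd_meanlog = c(log(0.055), log(0.051)),
                        fd_sdlog = c(0.35, 0.35),
                        cortex_volume_mean = 4.9e5,
                        cortex_volume_sd = 4.5e4,
                        sas_mean = c(49.8, 35.1), sas_sd = c(7.2, 9.0),
                        sds_mean = c(53.1, 36.9), sds_sd = c(9.0, 12.1),
                        wexner_mean = 13.5, wexner_sd = 4.3,
                        seed = 1L) {
  stopifnot(inherits(atlas, "fc_atlas"),
            n_patients >= 2L, n_controls >= 2L, n_timepoints >= 30L,
            base_within_block_r >= 0, base_within_block_r < 1,
            abs(base_between_block_r) < 1,
            temporal_smoothing >= 0, temporal_smoothing < 1)
  spec <- list(atlas = atlas, n_patients = as.integer(n_patients),
               n_controls = as.integer(n_controls),
               n_timepoints = as.integer(n_timepoints),
               tr_seconds = tr_seconds,
               base_within_block_r = base_within_block_r,
               base_between_block_r = base_between_block_r,
               effect_edges = effect_edges, effect_blocks = effect_blocks,
               temporal_smoothing = temporal_smoothing,
               age_mean = age_mean, age_sd = age_sd, male_prop = male_prop,
               fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
               cortex_volume_mean = cortex_volume_mean,
               cortex_volume_sd = cortex_volume_sd,
               sas_mean = sas_mean, sas_sd = sas_sd,
               sds_mean = sds_mean, sds_sd = sds_sd,
               wexner_mean = wexner_mean, wexner_sd = wexner_sd,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Nearest positive-definite repair by eigenvalue clipping
#'
#' Clips eigenvalues below `eps`, reconstructs, and rescales to unit
#' diagonal. Deterministic; used when injected effects break positive
#' definiteness of a target correlation matrix.
#'
#' @param m Symmetric matrix.
#' @param eps Eigenvalue floor.
#' @return List with the repaired matrix (`mat`), whether repair was
#'   needed (`repaired`), and the original minimum eigenvalue
#'   (`min_eigenvalue`).
#' @export
nearest_pd <- function(m, eps = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  min_ev <- min(e$values)
  if (min_ev > eps) {
    return(list(mat = m, repaired = FALSE, min_eigenvalue = min_ev))
  }
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  if (min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("covariance repair failed; minimum eigenvalue ", min_ev,
         call. = FALSE)
  }
  list(mat = out, repaired = TRUE, min_eigenvalue = min_ev)
}

#' Build the target correlation matrix for one group
#'
#' Unit-diagonal matrix with `base_within_block_r` inside each Yeo-7
#' block, `base_between_block_r` elsewhere; for patients, the
#' `effect_edges` and `effect_blocks` deltas are added and the result is
#' clipped to `|r| <= 0.95` and repaired to positive definiteness if
#' required.
#'
#' @param spec A `cohort_spec`.
#' @param group `"patient"` or `"control"`.
#' @return N x N positive-definite correlation matrix with attribute
#'   `"repaired"`.
#' @export
build_target_covariance <- function(spec, group = c("patient", "control")) {
  group <- match.arg(group)
  net <- spec$atlas$network
  n <- length(net)
  same <- outer(net, net, "==")
  sigma <- ifelse(same, spec$base_within_block_r,
                  spec$base_between_block_r)
  diag(sigma) <- 1
  if (group == "patient") {
    eb <- spec$effect_blocks
    if (!is.null(eb) && nrow(eb) > 0L) {
      for (k in seq_len(nrow(eb))) {
        ia <- net == eb$network_a[k]
        ib <- net == eb$network_b[k]
        sigma[ia, ib] <- sigma[ia, ib] + eb$delta_r[k]
        if (eb$network_a[k] != eb$network_b[k]) {
          sigma[ib, ia] <- sigma[ib, ia] + eb$delta_r[k]
        }
      }
    }
    ee <- spec$effect_edges
    if (!is.null(ee) && nrow(ee) > 0L) {
      for (k in seq_len(nrow(ee))) {
        i <- ee$node_i[k]; j <- ee$node_j[k]
        sigma[i, j] <- sigma[i, j] + ee$delta_r[k]
        sigma[j, i] <- sigma[i, j]
      }
    }
    diag(sigma) <- 1
    off <- row(sigma) != col(sigma)
    sigma[off] <- pmin(pmax(sigma[off], -0.95), 0.95)
  }
  rep_out <- nearest_pd(sigma)
  out <- rep_out$mat
  attr(out, "repaired") <- rep_out$repaired
  out
}

# Stationary AR(1) Gaussian series with spatial covariance sigma:
# x_1 ~ N(0, sigma); x_t = phi x_{t-1} + sqrt(1 - phi^2) L eps_t.
sample_ar1_mvn <- function(n_t, chol_sigma, phi) {
  n <- ncol(chol_sigma)
  eps <- matrix(stats::rnorm(n_t * n), n_t, n) %*% chol_sigma
  if (phi == 0) return(eps)
  x <- matrix(0, n_t, n)
  x[1L, ] <- eps[1L, ]
  s <- sqrt(1 - phi^2)
  for (t in 2:n_t) x[t, ] <- phi * x[t - 1L, ] + s * eps[t, ]
  x
}

#' Sample a full synthetic cohort
#'
#' Draws per-subject time series from the group-specific target
#' covariance with AR(1) temporal structure, plus phenotypes and
#' clinical scores, fully reproducible from `spec$seed`.
#'
#' @param spec A `cohort_spec`.
#' @return List with `timeseries` (named list of `fc_timeseries`),
#'   `phenotypes` (validated data.frame) and `truth` (injected effects,
#'   target matrices, repair flags, seed).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sig_p <- build_target_covariance(spec, "patient")
  sig_c <- build_target_covariance(spec, "control")
  chol_p <- chol(sig_p)
  chol_c <- chol(sig_c)
  n_tot <- spec$n_patients + spec$n_controls
  group <- rep(c("patient", "control"),
               c(spec$n_patients, spec$n_controls))
  ids <- sprintf("sub-%03d", seq_len(n_tot))
  ts_list <- vector("list", n_tot)
  for (s in seq_len(n_tot)) {
    ch <- if (group[s] == "patient") chol_p else chol_c
    x <- sample_ar1_mvn(spec$n_timepoints, ch, spec$temporal_smoothing)
    ts_list[[s]] <- as_timeseries(ids[s], x, tr_seconds = spec$tr_seconds,
                                  atlas = spec$atlas)
  }
  names(ts_list) <- ids
  gi <- ifelse(group == "patient", 1L, 2L)  # index into c(patient, control) parameter vectors
  pheno <- data.frame(
    subject_id = ids,
    group = group,
    age = stats::rnorm(n_tot, spec$age_mean[gi], spec$age_sd[gi]),
    sex = stats::rbinom(n_tot, 1L, spec$male_prop[gi]),
    mean_fd = stats::rlnorm(n_tot, spec$fd_meanlog[gi], spec$fd_sdlog[gi]),
    cortex_volume = stats::rnorm(n_tot, spec$cortex_volume_mean,
                                 spec$cortex_volume_sd),
    sas = stats::rnorm(n_tot, spec$sas_mean[gi], spec$sas_sd[gi]),
    sds = stats::rnorm(n_tot, spec$sds_mean[gi], spec$sds_sd[gi]),
    wexner = ifelse(group == "patient",
                    stats::rnorm(n_tot, spec$wexner_mean, spec$wexner_sd),
                    NA_real_),
    stringsAsFactors = FALSE
  )
  pheno <- as_phenotypes(pheno, ids)
  truth <- list(effect_edges = spec$effect_edges,
                effect_blocks = spec$effect_blocks,
                target_patient = sig_p, target_control = sig_c,
                repaired_patient = attr(sig_p, "repaired"),
                repaired_control = attr(sig_c, "repaired"),
                seed = spec$seed)
  list(timeseries = ts_list, phenotypes = pheno, truth = truth)
}
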