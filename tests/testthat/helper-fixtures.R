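# Shared fixtures: a minimal 14-parcel atlas (2 parcels per Yeo
# network) and small seeded cohorts.

test_atlas14 <- function() {
  synthetic_atlas(14L)
}

# small cohort generator used across module tests
small_cohort <- function(n_patients = 6L, n_controls = 6L,
                         n_parcels = 14L, n_timepoints = 80L,
                         seed = 42L, ...) {
  at <- synthetic_atlas(n_parcels)
  sample_cohort(cohort_spec(atlas = at, n_patients = n_patients,
                            n_controls = n_controls,
                            n_timepoints = n_timepoints, seed = seed,
                            ...))
}

# phenotype table with fixed covariates for deterministic GLM checks
fixed_pheno <- function(n_patients, n_controls, seed = 7L) {
  set.seed(seed)
  n <- n_patients + n_controls
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("patient", "control"), c(n_patients, n_controls)),
    age = stats::rnorm(n, 46, 12),
    sex = stats::rbinom(n, 1, 0.3),
    mean_fd = stats::rlnorm(n, log(0.05), 0.3),
    cortex_volume = stats::rnorm(n, 4.9e5, 4e4),
    sas = stats::rnorm(n, 40, 8),
    sds = stats::rnorm(n, 45, 10),
    wexner = ifelse(rep(c(TRUE, FALSE), c(n_patients, n_controls)),
                    stats::rnorm(n, 13, 4), NA_real_),
    stringsAsFactors = FALSE
  )
}
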