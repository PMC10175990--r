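# Shared simulated fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# Small study for unit-level checks: 32 parcels, 40 reference subjects.
small_study <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- synthetic_config(n_reference = 40, n_parcels = 32, n_volumes = 96,
                            seed = 42)
    atlas <- synthetic_atlas(cfg$n_parcels)
    cohort <- generate_reference_cohort(cfg, parcel_ids = atlas$parcel_id)
    ref <- embed_cohort(cohort)
    .fixtures$small <- list(cfg = cfg, atlas = atlas, cohort = cohort,
                            ref = ref, model = fit_normative(ref$tangents))
  }
  .fixtures$small
}

# Study at the calibration scale used for the property checks:
# 64 parcels, 200 reference subjects, 128 volumes.
calibration_study <- function() {
  if (is.null(.fixtures$calib)) {
    cfg <- synthetic_config(n_reference = 200, n_parcels = 64,
                            n_volumes = 128, seed = 1)
    atlas <- synthetic_atlas(cfg$n_parcels)
    cohort <- generate_reference_cohort(cfg, parcel_ids = atlas$parcel_id)
    ref <- embed_cohort(cohort)
    .fixtures$calib <- list(cfg = cfg, atlas = atlas, cohort = cohort,
                            ref = ref, model = fit_normative(ref$tangents))
  }
  .fixtures$calib
}

# Hand-built anomaly matrix for target-selection tests: statuses are set
# explicitly so counts are known by construction.
manual_anomaly_matrix <- function(parcel_ids, hyper = list(), hypo = list(),
                                  excluded = list()) {
  p <- length(parcel_ids)
  status <- matrix("normal", p, p, dimnames = list(parcel_ids, parcel_ids))
  z <- matrix(0, p, p, dimnames = list(parcel_ids, parcel_ids))
  set_pairs <- function(pairs, st, zval) {
    for (pr in pairs) {
      status[pr[1], pr[2]] <<- st; status[pr[2], pr[1]] <<- st
      z[pr[1], pr[2]] <<- zval; z[pr[2], pr[1]] <<- zval
    }
  }
  set_pairs(hyper, "hyper", 4)
  set_pairs(hypo, "hypo", -4)
  set_pairs(excluded, "excluded", NA_real_)
  diag(status) <- NA_character_
  diag(z) <- NA_real_
  structure(list(z = z, status = status, parcel_ids = parcel_ids,
                 sigma_threshold = 3, subject_id = "manual"),
            class = "anomaly_matrix")
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}
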