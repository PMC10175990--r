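#' Configuration for synthetic rsfMRI cohorts
#'
#' Describes the simulated study conditions: a reference cohort of healthy
#' subjects whose parcel time series share a block-structured base
#' correlation matrix, with per-subject heterogeneity expressed as Gaussian
#' perturbations of the edges in tangent space around that base structure.
#' The defaults mirror the acquisition the analysis assumes (128 volumes at
#' TR 2.8 s over 377 parcels, a 200-subject reference cohort); smaller
#' desk-scale settings are used throughout the tests.
#'
#' @param n_reference number of reference subjects (default 200).
#' @param n_parcels number of parcels (default 377).
#' @param n_volumes time points per subject (default 128).
#' @param tr_seconds repetition time in seconds (default 2.8; metadata only,
#'   time courses are white in time).
#' @param seed integer RNG seed.
#' @param base_correlation within-block correlation of the shared base
#'   structure, in (-1, 1) (default 0.4).
#' @param subject_sd between-subject SD of tangent-space edge perturbations
#'   (default 0.1).
#' @param block_size parcels per correlated block (default 4).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reference = 200L, n_parcels = 377L,
                             n_volumes = 128L, tr_seconds = 2.8,
                             seed = 1L, base_correlation = 0.4,
                             subject_sd = 0.1, block_size = 4L) {
  if (n_parcels < 2) config_error("n_parcels must be >= 2")
  if (n_volumes < 2) config_error("n_volumes must be >= 2")
  if (n_reference < 0) config_error("n_reference must be >= 0")
  if (tr_seconds <= 0) config_error("tr_seconds must be positive")
  if (abs(base_correlation) >= 1)
    config_error("base_correlation must be in (-1, 1)")
  if (subject_sd < 0) config_error("subject_sd must be >= 0")
  b <- min(block_size, n_parcels)
  if (b > 1 && base_correlation <= -1 / (b - 1))
    config_error("base_correlation makes the block structure indefinite")
  structure(list(n_reference = as.integer(n_reference),
                 n_parcels = as.integer(n_parcels),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds, seed = as.integer(seed),
                 base_correlation = base_correlation,
                 subject_sd = subject_sd, block_size = as.integer(b)),
            class = "synthetic_config")
}

#' Shared base correlation structure of a synthetic cohort
#'
#' Compound-symmetric blocks of `block_size` consecutive parcels at
#' `base_correlation`, zero between blocks.
#'
#' @param config a [synthetic_config()].
#' @return A correlation matrix (plain matrix, `n_parcels` square).
#' @export
base_structure <- function(config) {
  p <- config$n_parcels
  m <- diag(p)
  starts <- seq(1L, p, by = config$block_size)
  for (s in starts) {
    idx <- s:min(s + config$block_size - 1L, p)
    m[idx, idx] <- config$base_correlation
  }
  diag(m) <- 1
  m
}

## One subject's generating covariance: the base structure perturbed in its
## tangent space by a symmetric Gaussian matrix with off-diagonal SD `sd`.
subject_structure <- function(base_sqrt, p, sd) {
  if (sd == 0) return(NULL)  # signals "use the base structure as-is"
  d <- matrix(0, p, p)
  d[lower.tri(d)] <- stats::rnorm(p * (p - 1) / 2, 0, sd)
  d <- d + t(d)
  symmetrize(base_sqrt %*% sym_expm(d) %*% base_sqrt)
}

sample_series <- function(sigma_chol, n_volumes, p) {
  matrix(stats::rnorm(n_volumes * p), n_volumes, p) %*% sigma_chol
}

#' Generate a synthetic reference cohort
#'
#' Draws `n_reference` subjects. Each subject's time series is sampled as
#' white-in-time multivariate normal data from a subject-specific covariance:
#' the shared base structure perturbed in tangent space by `subject_sd`.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param parcel_ids optional parcel ids (defaults to a [synthetic_atlas()]
#'   naming).
#' @return A list of [time_series_matrix()] objects.
#' @export
generate_reference_cohort <- function(config, parcel_ids = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(parcel_ids))
    parcel_ids <- synthetic_atlas(config$n_parcels)$parcel_id
  if (length(parcel_ids) != config$n_parcels)
    config_error("parcel_ids length must equal n_parcels")
  if (config$n_reference == 0L) return(list())
  p <- config$n_parcels
  base <- base_structure(config)
  base_sqrt <- sym_sqrtm(base)
  base_chol <- chol(base)
  set.seed(config$seed)
  lapply(seq_len(config$n_reference), function(s) {
    sigma <- subject_structure(base_sqrt, p, config$subject_sd)
    ch <- if (is.null(sigma)) base_chol else chol(sigma)
    time_series_matrix(sample_series(ch, config$n_volumes, p),
                       parcel_ids, subject_id = sprintf("ref%03d", s))
  })
}

#' Ground-truth anomaly specification
#'
#' Describes one injected connectivity anomaly: all (or a fraction of)
#' edges incident to `parcel_id` are shifted by `magnitude_sigma` normative
#' SDs in the patient's generating tangent structure, upward for `"hyper"`
#' and downward for `"hypo"`.
#'
#' The default `affected_edge_fraction` is deliberately sparse (0.15, about
#' one in seven incident edges). Large per-edge offsets on *every* edge of
#' a parcel simultaneously are not representable: a correlation row is
#' Gram-constrained and the matrix log compresses coherent dominant modes,
#' capping the achievable mean tangent offset of a full incident fan near
#' two normative SDs however strong the generating perturbation. Sparse
#' anomalies — a parcel strongly abnormal against a handful of regions —
#' are both geometrically representable at several sigma and the pattern
#' the anomaly matrices display in practice.
#'
#' @param parcel_id parcel carrying the anomaly.
#' @param sign `"hyper"` or `"hypo"`.
#' @param magnitude_sigma effect size in units of the normative edge SD.
#' @param affected_edge_fraction fraction of candidate incident edges
#'   shifted (0, 1], default 0.25.
#' @param pool optional parcel ids the affected neighbors are drawn from
#'   (e.g. the DMN/CEN parcels, mimicking a parcel abnormal against
#'   multiple members of those networks); default all other parcels.
#' @export
anomaly_spec <- function(parcel_id, sign = c("hyper", "hypo"),
                         magnitude_sigma = 4, affected_edge_fraction = 0.25,
                         pool = NULL) {
  sign <- match.arg(sign)
  if (magnitude_sigma <= 0) config_error("magnitude_sigma must be positive")
  if (affected_edge_fraction <= 0 || affected_edge_fraction > 1)
    config_error("affected_edge_fraction must be in (0, 1]")
  structure(list(parcel_id = parcel_id, sign = sign,
                 magnitude_sigma = magnitude_sigma,
                 affected_edge_fraction = affected_edge_fraction,
                 pool = pool),
            class = "anomaly_spec")
}

## Total normative edge SD in tangent units: between-subject spread plus
## finite-series sampling noise of a correlation edge (~ 1/sqrt(T)).
anomaly_edge_scale <- function(config) {
  sqrt(config$subject_sd^2 + 1 / config$n_volumes)
}

## Solve for the generating tangent perturbation whose image under a
## measurement map (generating structure -> correlation -> optional common
## shrinkage -> matrix log at a base point) carries the prescribed offsets
## on the injected edges. A constant offset along a whole row is a large
## coherent perturbation; the exponential map, the unit-diagonal constraint
## of a correlation matrix, and the log's compression of dominant modes all
## attenuate it, so the required generating perturbation is found by a
## damped fixed point: the injected entries are nudged by the measured
## error while the remaining entries are free to carry the compensating
## structure the SPD geometry requires.
calibrate_injection <- function(base_sqrt, measure, targets, mask, init,
                                max_iter = 200L, tol = 1e-3) {
  resid <- function(delta) {
    sigma <- symmetrize(base_sqrt %*% sym_expm(delta) %*% base_sqrt)
    (targets - measure(stats::cov2cor(sigma))) * mask
  }
  scale <- max(abs(targets[mask]), 1e-8)
  delta <- init
  err <- resid(delta)
  worst <- max(abs(err))
  step <- 1
  for (it in seq_len(max_iter)) {
    if (worst < tol * scale) break
    cand <- delta + step * err
    err_cand <- resid(cand)
    worst_cand <- max(abs(err_cand))
    if (worst_cand < worst) {      # accept and grow the step
      delta <- cand; err <- err_cand; worst <- worst_cand
      step <- min(1.5, step * 1.2)
    } else {                       # backtrack
      step <- step / 2
      if (step < 1e-4) break
    }
  }
  delta
}

#' Generate a patient with injected connectivity anomalies
#'
#' The patient is drawn exactly like a reference subject, except that the
#' specified anomalies are built into the generating correlation structure
#' before the series is sampled: edges incident to each anomalous parcel
#' are offset by `magnitude_sigma` reference edge SDs, upward for hyper-
#' and downward for hypoconnectivity.
#'
#' "Reference edge SD" is taken literally: when the study's cohort
#' embedding and fitted normative model are supplied, the generator solves
#' a damped fixed point for the generating structure whose image under the
#' *scoring* transform (shrunk correlation, matrix log at the cohort
#' geometric mean) lands `magnitude_sigma` fitted SDs from the fitted
#' per-edge mean — so an injected "4 sigma" anomaly is recovered near
#' z = 4. This calibration is necessary because a coherent whole-row offset
#' is strongly attenuated by the exponential map, the unit-diagonal
#' constraint of a correlation matrix, and the log's compression of
#' dominant modes; a naive additive offset would come out several-fold
#' smaller than prescribed. Without a reference/model the same fixed point
#' is solved against the idealized noiseless transform at the base
#' structure, with the nominal edge scale `sqrt(subject_sd^2 +
#' 1/n_volumes)`; magnitudes are then approximate.
#'
#' With an empty anomaly list the patient is statistically exchangeable
#' with the reference cohort.
#'
#' @param config a [synthetic_config()].
#' @param anomalies list of [anomaly_spec()] objects (possibly empty).
#' @param seed RNG seed for this patient.
#' @param parcel_ids optional parcel ids (defaults to [synthetic_atlas()]).
#' @param subject_id subject identifier.
#' @param reference optional [embed_cohort()] result used to calibrate
#'   injected magnitudes in the measured tangent space.
#' @param model optional [fit_normative()] model giving the per-edge
#'   normative mean/SD the magnitudes refer to.
#' @return A list with elements `ts` (the [time_series_matrix()]) and
#'   `anomalies` (the ground-truth records, for recovery testing).
#' @export
generate_patient <- function(config, anomalies = list(), seed,
                             parcel_ids = NULL, subject_id = "patient",
                             reference = NULL, model = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(parcel_ids))
    parcel_ids <- synthetic_atlas(config$n_parcels)$parcel_id
  p <- config$n_parcels
  if (length(parcel_ids) != p)
    config_error("parcel_ids length must equal n_parcels")
  for (a in anomalies)
    if (!a$parcel_id %in% parcel_ids)
      atlas_error("anomaly parcel not in atlas: ", a$parcel_id)
  base <- base_structure(config)
  base_sqrt <- sym_sqrtm(base)
  scale <- anomaly_edge_scale(config)
  set.seed(seed)
  d <- matrix(0, p, p)
  if (config$subject_sd > 0) {
    d[lower.tri(d)] <- stats::rnorm(p * (p - 1) / 2, 0, config$subject_sd)
    d <- d + t(d)
  }
  if (length(anomalies)) {
    if (!is.null(reference)) {
      stopifnot(inherits(reference, "cohort_embedding"),
                inherits(model, "normative_model"))
      lam <- reference$shrinkage
      gi <- sym_isqrtm(reference$g$values)
      ident <- diag(p)
      measure <- function(r)
        sym_logm(gi %*% ((1 - lam) * r + lam * ident) %*% gi)
      mean_mat <- edges_to_matrix(model$edge_mean, p)
      sd_mat <- edges_to_matrix(model$edge_sd, p)
    } else {
      bi <- sym_isqrtm(base)
      measure <- function(r) sym_logm(bi %*% r %*% bi)
      mean_mat <- matrix(0, p, p)
      sd_mat <- matrix(scale, p, p)
    }
    shift <- matrix(0, p, p)
    for (i in seq_along(anomalies)) {
      a <- anomalies[[i]]
      k <- match(a$parcel_id, parcel_ids)
      others <- if (is.null(a$pool)) setdiff(seq_len(p), k)
                else setdiff(match(a$pool, parcel_ids), k)
      if (anyNA(others) || !length(others))
        atlas_error("anomaly pool parcels not in atlas")
      n_aff <- max(1L, round(a$affected_edge_fraction * length(others)))
      aff <- if (n_aff == length(others)) others else sample(others, n_aff)
      s <- (if (a$sign == "hyper") 1 else -1) * a$magnitude_sigma
      shift[k, aff] <- shift[k, aff] + s
      shift[aff, k] <- shift[aff, k] + s
      anomalies[[i]]$affected_parcels <- parcel_ids[aff]
    }
    mask <- shift != 0
    targets <- (mean_mat + shift * sd_mat) * mask
    ## calibrate on top of the realized subject structure: only the
    ## injected entries are adjusted, so their generating values sit at
    ## exactly the prescribed normative offset for *this* patient
    sig0 <- symmetrize(base_sqrt %*% sym_expm(d) %*% base_sqrt)
    t0 <- measure(stats::cov2cor(sig0))
    d <- calibrate_injection(base_sqrt, measure, targets, mask,
                             init = d + (targets - t0) * mask)
    if (!is.null(reference)) {
      ## finite-series correction: sampling noise through the concave
      ## matrix log biases the *measured* offsets downward, so re-target
      ## at the Monte-Carlo estimate of that bias (magnitude_sigma is
      ## defined on the expected measured z-score)
      lam <- reference$shrinkage
      adj <- targets
      for (round in 1:2) {
        sigma <- symmetrize(base_sqrt %*% sym_expm(d) %*% base_sqrt)
        ch <- chol(sigma)
        tbar <- matrix(0, p, p)
        n_mc <- 24L
        for (k in seq_len(n_mc)) {
          r_hat <- stats::cor(sample_series(ch, config$n_volumes, p))
          tbar <- tbar + measure(r_hat)
        }
        bias <- (targets - tbar / n_mc) * mask
        if (max(abs(bias[mask]) / sd_mat[mask]) < 0.3) break
        adj <- adj + bias
        d <- calibrate_injection(base_sqrt, measure, adj, mask, init = d)
      }
    }
  }
  sigma <- symmetrize(base_sqrt %*% sym_expm(d) %*% base_sqrt)
  ts <- time_series_matrix(sample_series(chol(sigma), config$n_volumes, p),
                           parcel_ids, subject_id = subject_id)
  list(ts = ts, anomalies = anomalies)
}

#' Read and write parcel time series as delimited text
#'
#' One file per subject: tab-delimited, header row of parcel ids, one row
#' per time point.
#'
#' @param ts a [time_series_matrix()].
#' @param path file path.
#' @export
write_time_series <- function(ts, path) {
  stopifnot(inherits(ts, "time_series_matrix"))
  m <- ts$values
  colnames(m) <- ts$parcel_ids
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_series
#' @param subject_id subject identifier for the loaded series.
#' @export
read_time_series <- function(path, subject_id = basename(path)) {
  m <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  time_series_matrix(as.matrix(m), colnames(m), subject_id = subject_id)
}
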