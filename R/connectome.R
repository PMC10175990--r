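#' Connectivity matrices
#'
#' A `connectivity_matrix` is a symmetric parcel-by-parcel matrix tagged
#' with its `kind` (`"correlation"`, `"covariance"` or `"tangent"`) and the
#' ordered parcel ids it is indexed by. Correlation matrices have unit
#' diagonal and entries in [-1, 1]; covariance matrices are symmetric
#' positive definite (SPD) after shrinkage; tangent matrices are symmetric
#' but need not be definite.
#'
#' @param values symmetric numeric matrix.
#' @param kind one of `"correlation"`, `"covariance"`, `"tangent"`.
#' @param parcel_ids character vector of parcel ids, one per row/column.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind, parcel_ids) {
  kind <- match.arg(kind, c("correlation", "covariance", "tangent"))
  values <- unname(as.matrix(values))
  if (nrow(values) != ncol(values) || nrow(values) != length(parcel_ids))
    geometry_error("matrix dimension does not match parcel_ids")
  if (max(abs(values - t(values))) > 1e-10)
    geometry_error("matrix is not symmetric within 1e-10")
  values <- symmetrize(values)
  if (kind == "correlation") {
    if (max(abs(diag(values) - 1)) > 1e-8 || max(abs(values)) > 1 + 1e-8)
      geometry_error("correlation matrix must have unit diagonal and |r| <= 1")
  }
  structure(list(values = values, kind = kind,
                 parcel_ids = as.character(parcel_ids)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix: %s, %d x %d parcels>\n",
              x$kind, length(x$parcel_ids), length(x$parcel_ids)))
  invisible(x)
}

#' Parcel time series container
#'
#' Wraps a time-by-parcel BOLD matrix with its parcel ids and subject id.
#' Every column must have nonzero variance (a constant column means a
#' degenerate extraction upstream and is rejected by name).
#'
#' @param values numeric matrix, time points in rows, parcels in columns.
#' @param parcel_ids parcel ids, one per column.
#' @param subject_id subject identifier.
#' @export
time_series_matrix <- function(values, parcel_ids, subject_id = "subject") {
  values <- unname(as.matrix(values))
  if (ncol(values) != length(parcel_ids))
    config_error("column count does not match parcel_ids")
  if (anyNA(values)) degenerate_error("time series contains missing values")
  v <- apply(values, 2L, stats::var)
  if (any(v <= 0))
    degenerate_error("constant time series for parcel(s): ",
                     paste(parcel_ids[v <= 0], collapse = ", "))
  structure(list(values = values, parcel_ids = as.character(parcel_ids),
                 subject_id = subject_id),
            class = "time_series_matrix")
}

#' Pearson correlation matrix of a parcel time series
#'
#' @param ts a [time_series_matrix()].
#' @return A `connectivity_matrix` of kind `"correlation"`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "time_series_matrix"))
  cm <- connectivity_matrix(stats::cor(ts$values), "correlation", ts$parcel_ids)
  cm$subject_id <- ts$subject_id
  cm
}

## Ledoit-Wolf-style analytic shrinkage intensity toward the identity,
## computed on standardized data: lambda* = sum var(r_ij) / sum r_ij^2
## over off-diagonal pairs, clamped to [0, 1].
lw_shrinkage <- function(x) {
  n <- nrow(x)
  xs <- scale(x) * sqrt((n - 1) / n)   # unit "population" variance columns
  r <- crossprod(xs) / n
  num <- 0; den <- 0
  p <- ncol(x)
  for (j in seq_len(p - 1L)) {
    w <- xs[, j] * xs[, (j + 1L):p, drop = FALSE]   # cross products per pair
    wbar <- colMeans(w)
    num <- num + sum(colSums((w - rep(wbar, each = n))^2)) * n / (n - 1)^3
    den <- den + sum(wbar^2)
  }
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Shrunk covariance and correlation estimates
#'
#' With fewer time points than parcels the sample covariance is
#' rank-deficient, but the tangent-space embedding needs an SPD input.
#' `shrunk_covariance()` shrinks the sample covariance toward the scaled
#' identity `mean(diag(S)) * I`; `shrunk_correlation()` normalizes to unit
#' variance first and shrinks toward the identity, preserving the unit
#' diagonal. `shrinkage = "auto"` uses an analytic Ledoit-Wolf-style
#' intensity estimated from the data.
#'
#' @param ts a [time_series_matrix()].
#' @param shrinkage a number in [0, 1] or `"auto"`.
#' @return A `connectivity_matrix` (kind `"covariance"` or `"correlation"`).
#' @export
shrunk_covariance <- function(ts, shrinkage = "auto") {
  stopifnot(inherits(ts, "time_series_matrix"))
  if (nrow(ts$values) < 2) degenerate_error("need at least 2 time points")
  s <- stats::cov(ts$values)
  lam <- if (identical(shrinkage, "auto")) lw_shrinkage(ts$values)
         else as.numeric(shrinkage)
  if (lam < 0 || lam > 1) config_error("shrinkage must be in [0, 1]")
  out <- (1 - lam) * s + lam * mean(diag(s)) * diag(nrow(s))
  cm <- connectivity_matrix(out, "covariance", ts$parcel_ids)
  cm$shrinkage <- lam
  cm$subject_id <- ts$subject_id
  cm
}

#' @rdname shrunk_covariance
#' @export
shrunk_correlation <- function(ts, shrinkage = "auto") {
  stopifnot(inherits(ts, "time_series_matrix"))
  if (nrow(ts$values) < 2) degenerate_error("need at least 2 time points")
  r <- stats::cor(ts$values)
  lam <- if (identical(shrinkage, "auto")) lw_shrinkage(ts$values)
         else as.numeric(shrinkage)
  if (lam < 0 || lam > 1) config_error("shrinkage must be in [0, 1]")
  out <- (1 - lam) * r + lam * diag(nrow(r))
  cm <- connectivity_matrix(out, "correlation", ts$parcel_ids)
  cm$shrinkage <- lam
  cm$subject_id <- ts$subject_id
  cm
}

## Symmetric matrix functions via eigendecomposition. Eigenvalues of SPD
## inputs are floored at 1e-12 before taking logs, for safety on
## near-singular shrunk matrices.
sym_fun <- function(m, f, floor = NULL) {
  e <- eigen(symmetrize(m), symmetric = TRUE)
  vals <- e$values
  if (!is.null(floor)) vals <- pmax(vals, floor)
  symmetrize(e$vectors %*% (f(vals) * t(e$vectors)))
}

sym_logm  <- function(m) sym_fun(m, log, floor = 1e-12)
sym_expm  <- function(m) sym_fun(m, exp)
sym_sqrtm <- function(m) sym_fun(m, sqrt, floor = 0)
sym_isqrtm <- function(m) sym_fun(m, function(v) 1 / sqrt(v), floor = 1e-12)

#' Embed a cohort, and patients, in a common tangent space
#'
#' `embed_cohort()` runs the reference half of the connectivity pipeline:
#' a single common shrinkage intensity is fixed for the whole cohort (with
#' `"auto"`, the mean of the per-subject analytic estimates), every
#' subject's shrunk correlation matrix is computed, and all are embedded at
#' their geometric mean. `embed_patient()` embeds a new subject with the
#' *same* shrinkage and base point — using a subject-specific intensity
#' instead would shift every edge of an atypical patient relative to the
#' normative cohort and distort the z-scores.
#'
#' @param ts_list list of [time_series_matrix()] objects.
#' @param shrinkage common shrinkage intensity in [0, 1], or `"auto"`.
#' @return A list of class `cohort_embedding`: `g` (the [geometric_mean()]
#'   base point), `tangents` (list of tangent matrices), `shrinkage` (the
#'   common intensity used).
#' @export
embed_cohort <- function(ts_list, shrinkage = "auto") {
  if (length(ts_list) < 2) degenerate_error("need at least 2 subjects")
  if (identical(shrinkage, "auto"))
    shrinkage <- mean(vapply(ts_list, function(ts) lw_shrinkage(ts$values),
                             numeric(1)))
  mats <- lapply(ts_list, shrunk_correlation, shrinkage = shrinkage)
  g <- geometric_mean(mats)
  structure(list(g = g, tangents = lapply(mats, tangent_embed, g = g),
                 shrinkage = shrinkage),
            class = "cohort_embedding")
}

#' @rdname embed_cohort
#' @param ts a patient [time_series_matrix()].
#' @param ref a `cohort_embedding`.
#' @export
embed_patient <- function(ts, ref) {
  stopifnot(inherits(ref, "cohort_embedding"))
  tangent_embed(shrunk_correlation(ts, ref$shrinkage), ref$g)
}

#' Affine-invariant geometric mean of SPD matrices
#'
#' Fixed-point iteration `G <- G^{1/2} exp(step * mean_i log(G^{-1/2} C_i
#' G^{-1/2})) G^{1/2}` starting from the arithmetic mean, with step halving
#' whenever the tangent residual increases. Convergence is declared when the
#' Frobenius norm of the mean tangent residual drops below `tol`. If the
#' iteration does not converge within `max_iter` steps the log-Euclidean
#' mean `exp(mean_i log C_i)` is returned with `converged = FALSE` and a
#' warning.
#'
#' @param mats list of SPD `connectivity_matrix` objects (or plain SPD
#'   matrices) with identical parcel ids.
#' @param tol convergence tolerance on the mean tangent residual.
#' @param max_iter maximum fixed-point iterations.
#' @return An object of class `reference_mean` with elements `values`
#'   (SPD matrix), `iterations_used`, `converged`, `parcel_ids`.
#' @export
geometric_mean <- function(mats, tol = 1e-7, max_iter = 50L) {
  if (!length(mats)) geometry_error("need at least one matrix")
  vals <- lapply(mats, function(m)
    if (inherits(m, "connectivity_matrix")) m$values else unname(as.matrix(m)))
  parcel_ids <- if (inherits(mats[[1L]], "connectivity_matrix"))
    mats[[1L]]$parcel_ids else as.character(seq_len(nrow(vals[[1L]])))
  p <- nrow(vals[[1L]])
  for (m in vals) {
    if (!all(dim(m) == c(p, p))) geometry_error("matrix dimensions differ")
    if (!is_spd(m)) geometry_error("input matrix is not SPD")
  }
  if (length(vals) == 1L)
    return(structure(list(values = vals[[1L]], iterations_used = 0L,
                          converged = TRUE, parcel_ids = parcel_ids),
                     class = "reference_mean"))
  g <- symmetrize(Reduce(`+`, vals) / length(vals))
  step <- 1
  prev_res <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gi <- sym_isqrtm(g)
    gs <- sym_sqrtm(g)
    tanmean <- Reduce(`+`, lapply(vals, function(m)
      sym_logm(gi %*% m %*% gi))) / length(vals)
    res <- sqrt(sum(tanmean^2))
    if (res <= tol) { converged <- TRUE; break }
    if (res > prev_res) step <- step / 2
    prev_res <- res
    g <- symmetrize(gs %*% sym_expm(step * tanmean) %*% gs)
  }
  if (!converged) {
    warning("geometric mean did not converge in ", max_iter,
            " iterations; falling back to the log-Euclidean mean")
    g <- sym_expm(Reduce(`+`, lapply(vals, sym_logm)) / length(vals))
  }
  structure(list(values = g, iterations_used = iter, converged = converged,
                 parcel_ids = parcel_ids),
            class = "reference_mean")
}

#' @export
print.reference_mean <- function(x, ...) {
  cat(sprintf("<reference_mean: %d parcels, %d iterations, %s>\n",
              nrow(x$values), x$iterations_used,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tangent-space embedding at a reference point
#'
#' Maps an SPD connectivity matrix `C` to `log(G^{-1/2} C G^{-1/2})`, the
#' tangent-space representation at the reference mean `G`. At the base point
#' itself the embedding is the zero matrix. `tangent_invert()` applies the
#' inverse map `G^{1/2} exp(T) G^{1/2}`.
#'
#' @param c an SPD `connectivity_matrix` (correlation or covariance kind).
#' @param g a `reference_mean` (or SPD matrix) of the same dimension.
#' @return A `connectivity_matrix` of kind `"tangent"`.
#' @export
tangent_embed <- function(c, g) {
  gm <- if (inherits(g, "reference_mean")) g$values else unname(as.matrix(g))
  cv <- if (inherits(c, "connectivity_matrix")) c$values else unname(as.matrix(c))
  ids <- if (inherits(c, "connectivity_matrix")) c$parcel_ids
         else as.character(seq_len(nrow(cv)))
  if (!all(dim(cv) == dim(gm))) geometry_error("dimension mismatch")
  gi <- sym_isqrtm(gm)
  out <- connectivity_matrix(sym_logm(gi %*% cv %*% gi), "tangent", ids)
  if (inherits(c, "connectivity_matrix")) out$subject_id <- c$subject_id
  out
}

#' @rdname tangent_embed
#' @param t a `connectivity_matrix` of kind `"tangent"`.
#' @export
tangent_invert <- function(t, g) {
  gm <- if (inherits(g, "reference_mean")) g$values else unname(as.matrix(g))
  tv <- if (inherits(t, "connectivity_matrix")) t$values else unname(as.matrix(t))
  ids <- if (inherits(t, "connectivity_matrix")) t$parcel_ids
         else as.character(seq_len(nrow(tv)))
  if (!all(dim(tv) == dim(gm))) geometry_error("dimension mismatch")
  gs <- sym_sqrtm(gm)
  connectivity_matrix(gs %*% sym_expm(tv) %*% gs, "covariance", ids)
}
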