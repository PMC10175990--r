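#' agiletms: normative connectivity modelling for TMS target selection
#'
#' Fits per-edge normative models of tangent-space functional connectivity
#' from a reference cohort, scores patients for 3-sigma edge anomalies,
#' selects theta-burst stimulation targets from in-network anomaly column
#' counts, plans accelerated TBS courses, and reproduces the associated
#' GAD-7 outcome statistics. See [fit_normative()] for the central model
#' and [run_pipeline()] for the end-to-end analysis.
#'
#' @keywords internal
"_PACKAGE"

## Classed conditions so callers (and the CLI) can distinguish config, data
## and numerical failures.
abort <- function(class, ...) {
  stop(structure(class = c(class, "agiletms_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

config_error     <- function(...) abort("agiletms_config_error", ...)
atlas_error      <- function(...) abort("agiletms_atlas_error", ...)
geometry_error   <- function(...) abort("agiletms_geometry_error", ...)
degenerate_error <- function(...) abort("agiletms_degenerate_error", ...)

#' Edge indexing for symmetric parcel-by-parcel matrices
#'
#' Connectivity edges are the unique unordered parcel pairs: the upper
#' triangle in row-major order, giving E = P(P-1)/2 edges. `edge_pairs()`
#' returns the (i, j) index table in that order; `edge_values()` extracts a
#' matrix's edge vector; `edges_to_matrix()` rebuilds a symmetric matrix
#' (diagonal supplied separately).
#'
#' @param p number of parcels.
#' @return `edge_pairs()`: a two-column integer matrix with one row per edge.
#' @keywords internal
edge_pairs <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  cbind(i = idx[, 2L], j = idx[, 1L])  # row-major upper triangle
}

edge_values <- function(m) m[lower.tri(m)]

edges_to_matrix <- function(values, p, diag = 0) {
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- values
  m <- m + t(m)
  diag(m) <- diag
  m
}

## Index of the edge between parcels i and j (i != j) in edge-vector order.
edge_index <- function(i, j, p) {
  a <- pmin(i, j); b <- pmax(i, j)
  (a - 1L) * p - (a * (a - 1L)) %/% 2L + (b - a)
}

symmetrize <- function(m) (m + t(m)) / 2

is_spd <- function(m, tol = 1e-10) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  min(eigen(symmetrize(m), symmetric = TRUE, only.values = TRUE)$values) > tol
}

## Derive a stream of distinct 31-bit seeds from one master seed.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.double(seed) * 7919 + salt * 104729 + seq_len(n) * 131) %% 2147483647
}
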