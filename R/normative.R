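#' Fit a per-edge normative model of tangent-space connectivity
#'
#' The central fitting function of the package. Given tangent-space
#' connectivity matrices from a healthy reference cohort, it estimates for
#' every unique parcel pair (edge) the normative mean and standard deviation
#' (denominator n - 1) across subjects, and marks the `exclusion_fraction`
#' of edges with the largest reference variance as excluded: highly variable
#' edges carry little diagnostic information and would inflate the false
#' discovery rate of the outlier step. A patient edge is later called
#' anomalous when it lies more than `sigma_threshold` normative SDs from the
#' normative mean (hyperconnected above, hypoconnected below).
#'
#' Exactly `round(E * exclusion_fraction)` of the `E = P(P-1)/2` edges are
#' excluded; ties at the variance cutoff are broken by edge index (upper
#' triangle, row-major) so the fit is deterministic.
#'
#' @param refs list of `connectivity_matrix` objects of kind `"tangent"`
#'   (at least 2) with identical parcel ids.
#' @param sigma_threshold outlier threshold in normative SD units
#'   (default 3).
#' @param exclusion_fraction fraction of highest-variance edges to exclude
#'   (default 1/3).
#' @return An object of class `normative_model` with elements `edge_mean`,
#'   `edge_sd`, `excluded_mask`, `n_reference`, `sigma_threshold`,
#'   `exclusion_fraction`, `parcel_ids`.
#' @seealso [predict.normative_model()] to score a patient,
#'   [anomaly_report()] for network-restricted reports.
#' @examples
#' cfg <- synthetic_config(n_reference = 20, n_parcels = 8, n_volumes = 64)
#' cohort <- generate_reference_cohort(cfg)
#' mats <- lapply(cohort, shrunk_correlation)
#' g <- geometric_mean(mats)
#' tans <- lapply(mats, tangent_embed, g = g)
#' fit <- fit_normative(tans)
#' fit
#' @export
fit_normative <- function(refs, sigma_threshold = 3, exclusion_fraction = 1/3) {
  if (length(refs) < 2) degenerate_error("need at least 2 reference matrices")
  if (sigma_threshold <= 0) config_error("sigma_threshold must be positive")
  if (exclusion_fraction < 0 || exclusion_fraction >= 1)
    config_error("exclusion_fraction must be in [0, 1)")
  ids <- refs[[1L]]$parcel_ids
  for (r in refs) {
    stopifnot(inherits(r, "connectivity_matrix"))
    if (r$kind != "tangent")
      geometry_error("reference matrices must be tangent kind")
    if (!identical(r$parcel_ids, ids))
      atlas_error("reference matrices have differing parcel ids")
  }
  p <- length(ids)
  e <- (p * (p - 1L)) %/% 2L
  edges <- vapply(refs, function(r) edge_values(r$values), numeric(e))
  edge_mean <- rowMeans(edges)
  edge_var <- apply(edges, 1L, stats::var)
  n_excl <- round(e * exclusion_fraction)
  excluded <- logical(e)
  if (n_excl > 0)
    excluded[order(edge_var, decreasing = TRUE)[seq_len(n_excl)]] <- TRUE
  edge_sd <- sqrt(edge_var)
  if (any(edge_sd[!excluded] < 1e-12))
    degenerate_error("reference cohort has (near-)zero spread on included ",
                     "edges; the normative SD is undefined")
  structure(list(edge_mean = edge_mean, edge_sd = edge_sd,
                 excluded_mask = excluded, n_reference = length(refs),
                 sigma_threshold = sigma_threshold,
                 exclusion_fraction = exclusion_fraction,
                 parcel_ids = ids),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  e <- length(x$edge_mean)
  cat("Normative tangent-space connectivity model\n")
  cat(sprintf("  parcels: %d  edges: %d  reference subjects: %d\n",
              length(x$parcel_ids), e, x$n_reference))
  cat(sprintf("  excluded (high-variance): %d edges (%.1f%%)\n",
              sum(x$excluded_mask), 100 * mean(x$excluded_mask)))
  cat(sprintf("  outlier threshold: %.4g sigma\n", x$sigma_threshold))
  invisible(x)
}

#' @export
summary.normative_model <- function(object, ...) {
  inc <- !object$excluded_mask
  out <- list(
    n_parcels = length(object$parcel_ids),
    n_edges = length(object$edge_mean),
    n_excluded = sum(object$excluded_mask),
    n_reference = object$n_reference,
    sigma_threshold = object$sigma_threshold,
    mean_quartiles = stats::quantile(object$edge_mean[inc]),
    sd_quartiles = stats::quantile(object$edge_sd[inc])
  )
  class(out) <- "summary.normative_model"
  out
}

#' @export
print.summary.normative_model <- function(x, ...) {
  cat(sprintf(
    "Normative model: %d parcels, %d edges (%d excluded), n = %d\n",
    x$n_parcels, x$n_edges, x$n_excluded, x$n_reference))
  cat("Included-edge normative means:\n"); print(signif(x$mean_quartiles, 3))
  cat("Included-edge normative SDs:\n"); print(signif(x$sd_quartiles, 3))
  invisible(x)
}

#' @export
coef.normative_model <- function(object, ...) {
  pr <- edge_pairs(length(object$parcel_ids))
  data.frame(parcel_a = object$parcel_ids[pr[, 1L]],
             parcel_b = object$parcel_ids[pr[, 2L]],
             mean = object$edge_mean, sd = object$edge_sd,
             excluded = object$excluded_mask)
}

#' Score a patient's tangent connectivity against the normative model
#'
#' Computes the per-edge z-score `(patient - mean) / sd` on included edges
#' and classifies each edge as `hyper` (z above the sigma threshold),
#' `hypo` (below its negative), `normal`, or `excluded`. Excluded edges and
#' the diagonal carry no z-score.
#'
#' @param object a [fit_normative()] model.
#' @param newdata a `connectivity_matrix` of kind `"tangent"` with the
#'   model's parcel ids.
#' @param ... unused.
#' @return An object of class `anomaly_matrix` with symmetric `z` and
#'   `status` matrices, `parcel_ids`, and the threshold used.
#' @export
predict.normative_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "connectivity_matrix"))
  if (newdata$kind != "tangent")
    geometry_error("patient matrix must be tangent kind")
  if (!identical(newdata$parcel_ids, object$parcel_ids))
    atlas_error("patient parcel ids do not match the model")
  p <- length(object$parcel_ids)
  zv <- (edge_values(newdata$values) - object$edge_mean) / object$edge_sd
  zv[object$excluded_mask] <- NA_real_
  st <- ifelse(object$excluded_mask, "excluded",
        ifelse(zv > object$sigma_threshold, "hyper",
        ifelse(zv < -object$sigma_threshold, "hypo", "normal")))
  z <- matrix(NA_real_, p, p)
  z[lower.tri(z)] <- zv
  z <- t(z)
  z[lower.tri(z)] <- zv
  status <- matrix(NA_character_, p, p)
  status[lower.tri(status)] <- st
  status <- t(status)
  status[lower.tri(status)] <- st
  dimnames(z) <- dimnames(status) <-
    list(object$parcel_ids, object$parcel_ids)
  structure(list(z = z, status = status, parcel_ids = object$parcel_ids,
                 sigma_threshold = object$sigma_threshold,
                 subject_id = newdata$subject_id),
            class = "anomaly_matrix")
}

#' @rdname predict.normative_model
#' @param patient a tangent `connectivity_matrix`.
#' @param model a `normative_model`.
#' @export
score_anomalies <- function(patient, model) predict(model, patient)

#' @export
print.anomaly_matrix <- function(x, ...) {
  tab <- table(factor(x$status[lower.tri(x$status)],
                      levels = c("normal", "hyper", "hypo", "excluded")))
  cat(sprintf("<anomaly_matrix: %d parcels; %s>\n", length(x$parcel_ids),
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Simulate null tangent matrices from a fitted normative model
#'
#' Draws edge vectors independently from the fitted per-edge Gaussian
#' (including excluded edges, from their own mean/SD) and reassembles
#' symmetric tangent matrices — useful for model-based null calibration.
#'
#' @param object a `normative_model`.
#' @param nsim number of matrices.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A list of tangent `connectivity_matrix` objects.
#' @export
simulate.normative_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(object$parcel_ids)
  e <- length(object$edge_mean)
  lapply(seq_len(nsim), function(k) {
    v <- stats::rnorm(e, object$edge_mean, object$edge_sd)
    connectivity_matrix(edges_to_matrix(v, p, diag = 0), "tangent",
                        object$parcel_ids)
  })
}

#' Serialize a normative model to JSON
#'
#' Writes the full model (per-edge means/SDs, exclusion mask, parameters,
#' parcel ids) as a single JSON document; `read_normative()` restores it.
#'
#' @param model a `normative_model`.
#' @param path file path (`.json`).
#' @export
write_normative <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$excluded_mask <- as.logical(raw$excluded_mask)
  raw$n_reference <- as.integer(raw$n_reference)
  structure(raw, class = "normative_model")
}

#' Network-restricted anomaly report
#'
#' Restricts an anomaly matrix to the parcels of the named networks,
#' ordered by (network, hemisphere, parcel id), giving the block-matrix
#' view used to read off target columns: each cell is one of `normal`,
#' `hyper`, `hypo`, `excluded`.
#'
#' @param am an `anomaly_matrix`.
#' @param atlas a `parcel_atlas` covering the matrix's parcels.
#' @param networks networks to include (default DMN and CEN).
#' @return An object of class `anomaly_report`: a character matrix of
#'   statuses with parcel dimnames, plus the parcel ordering used.
#' @export
anomaly_report <- function(am, atlas, networks = c("DMN", "CEN")) {
  stopifnot(inherits(am, "anomaly_matrix"))
  parcels <- network_parcels(atlas, networks)
  parcels <- parcels[parcels %in% am$parcel_ids]
  if (!length(parcels))
    atlas_error("no parcels of network(s) ",
                paste(networks, collapse = ", "), " in the anomaly matrix")
  tab <- am$status[parcels, parcels, drop = FALSE]
  structure(list(status = tab, parcel_ids = parcels, networks = networks,
                 subject_id = am$subject_id),
            class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  k <- nrow(x$status)
  counts <- table(factor(x$status[lower.tri(x$status)],
                         levels = c("normal", "hyper", "hypo", "excluded")))
  cat(sprintf("<anomaly_report: %d parcels (%s); %s>\n", k,
              paste(x$networks, collapse = "+"),
              paste(names(counts), counts, sep = "=", collapse = " ")))
  invisible(x)
}

#' @rdname anomaly_report
#' @param report an `anomaly_report`.
#' @param path output TSV path.
#' @export
write_anomaly_report <- function(report, path) {
  utils::write.table(report$status, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Heatmap of an anomaly matrix or report
#'
#' Renders the categorical status matrix with the conventional encoding:
#' light grey for normal edges, white for excluded (highly variable) edges,
#' red for hyperconnected and blue for hypoconnected anomalies.
#'
#' @param x an `anomaly_matrix` or `anomaly_report`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.anomaly_matrix <- function(x, main = "Anomalous connectivity", ...) {
  status_image(x$status, main = main, ...)
}

#' @export
plot.anomaly_report <- function(x, main = "Anomalous connectivity", ...) {
  status_image(x$status, main = main, ...)
}

status_image <- function(status, main, ...) {
  lv <- c("normal", "excluded", "hyper", "hypo")
  m <- matrix(match(status, lv), nrow(status), ncol(status))
  m[is.na(m)] <- 2L  # diagonal rendered like excluded
  p <- nrow(m)
  graphics::image(seq_len(p), seq_len(p), t(m[p:1, , drop = FALSE]),
                  col = c("grey80", "white", "firebrick", "steelblue"),
                  zlim = c(1, 4), axes = FALSE, xlab = "", ylab = "",
                  main = main, ...)
  graphics::box()
  invisible(NULL)
}
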