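#' Count anomalous edges per parcel column within selected networks
#'
#' For every parcel in the union of the requested networks, counts its
#' hyper- and hypoconnected edges to the *other* parcels of that union.
#' Excluded edges never contribute. Each anomalous edge is counted once in
#' each of the two columns it touches (so column totals sum to twice the
#' number of flagged in-network edges).
#'
#' @param am an `anomaly_matrix`.
#' @param atlas a `parcel_atlas`.
#' @param networks networks defining the search space (default DMN + CEN).
#' @return A data frame of class `column_counts` with columns `parcel_id`,
#'   `hyper_count`, `hypo_count`, `total`, `is_dlpfc`, ordered as the
#'   network parcel list.
#' @export
count_column_anomalies <- function(am, atlas, networks = c("DMN", "CEN")) {
  stopifnot(inherits(am, "anomaly_matrix"))
  parcels <- network_parcels(atlas, networks)
  parcels <- parcels[parcels %in% am$parcel_ids]
  if (length(parcels) < 2)
    atlas_error("networks must resolve to at least 2 parcels present in ",
                "the anomaly matrix")
  st <- am$status[parcels, parcels, drop = FALSE]
  hyper <- rowSums(st == "hyper", na.rm = TRUE)
  hypo <- rowSums(st == "hypo", na.rm = TRUE)
  out <- data.frame(parcel_id = parcels,
                    hyper_count = as.integer(hyper),
                    hypo_count = as.integer(hypo),
                    total = as.integer(hyper + hypo),
                    is_dlpfc = atlas$is_dlpfc[match(parcels, atlas$parcel_id)],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("column_counts", "data.frame")
  out
}

#' Assign a theta-burst protocol from the anomaly majority
#'
#' A parcel whose anomalous edges are mostly hyperconnected receives cTBS
#' (continuous theta-burst, putatively inhibitory); a mostly hypoconnected
#' parcel receives iTBS (intermittent, putatively excitatory). An exact tie
#' falls to cTBS, the dominant prescription in practice.
#'
#' @param hyper_count,hypo_count non-negative anomaly counts (vectorized;
#'   a parcel with no anomalies at all is never a target and is rejected).
#' @return `"cTBS"` or `"iTBS"` per element.
#' @export
assign_protocol <- function(hyper_count, hypo_count) {
  if (any(hyper_count < 0 | hypo_count < 0))
    config_error("counts must be non-negative")
  if (any(hyper_count + hypo_count == 0))
    config_error("assign_protocol called with no anomalies")
  ifelse(hypo_count > hyper_count, "iTBS", "cTBS")
}

#' Agile target selection from column anomaly counts
#'
#' Ranks the network parcels by their anomaly column counts and prescribes
#' the top two to three as stimulation targets. Parcels must carry at least
#' `min_anomalies` anomalous in-network edges to qualify ("multiple
#' anomalies"); DLPFC parcels get a slight multiplicative priority
#' (`biased_score = total * dlpfc_bias`). Ranking is by biased score
#' descending, ties broken by raw total then atlas order. The top
#' `min(k_max, qualifying)` parcels are selected; a warning is issued when
#' fewer than `k_min` qualify. Protocols follow [assign_protocol()].
#'
#' @param counts a `column_counts` table (or an `anomaly_matrix`, which is
#'   counted first via [count_column_anomalies()]).
#' @param min_anomalies minimum in-network anomaly count to qualify
#'   (default 2).
#' @param k_min,k_max target count range (defaults 2 and 3).
#' @param dlpfc_bias multiplicative DLPFC priority, >= 1 (default 1.2).
#' @param atlas a `parcel_atlas` (required when `counts` is an
#'   `anomaly_matrix`).
#' @param networks networks used when counting from an `anomaly_matrix`.
#' @param subject_id subject identifier recorded in the prescription.
#' @return An object of class `prescription`: `subject_id`, a `targets`
#'   data frame (`parcel_id`, `protocol`, `hyper_count`, `hypo_count`,
#'   `biased_score`) in rank order, and `selection_params`.
#' @export
select_targets <- function(counts, min_anomalies = 2L, k_min = 2L,
                           k_max = 3L, dlpfc_bias = 1.2, atlas = NULL,
                           networks = c("DMN", "CEN"),
                           subject_id = NULL) {
  if (inherits(counts, "anomaly_matrix")) {
    if (is.null(atlas))
      config_error("an atlas is required to count from an anomaly_matrix")
    if (is.null(subject_id)) subject_id <- counts$subject_id
    counts <- count_column_anomalies(counts, atlas, networks)
  }
  stopifnot(inherits(counts, "data.frame"))
  if (k_min > k_max) config_error("k_min must be <= k_max")
  if (dlpfc_bias < 1) config_error("dlpfc_bias must be >= 1")
  if (is.null(subject_id)) subject_id <- "subject"
  if (is.null(counts$is_dlpfc)) counts$is_dlpfc <- FALSE
  counts$biased_score <- counts$total * ifelse(counts$is_dlpfc, dlpfc_bias, 1)
  qual <- counts[counts$total >= min_anomalies, , drop = FALSE]
  qual <- qual[order(-qual$biased_score, -qual$total,
                     seq_len(nrow(qual))), , drop = FALSE]
  k <- min(k_max, nrow(qual))
  if (k < k_min)
    warning(sprintf("only %d parcel(s) qualify (k_min = %d)", k, k_min))
  sel <- qual[seq_len(k), , drop = FALSE]
  targets <- data.frame(
    parcel_id = sel$parcel_id,
    protocol = if (k) assign_protocol(sel$hyper_count, sel$hypo_count)
               else character(),
    hyper_count = sel$hyper_count, hypo_count = sel$hypo_count,
    biased_score = sel$biased_score,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(subject_id = subject_id, targets = targets,
                 selection_params = list(networks = networks,
                                         min_anomalies = min_anomalies,
                                         k_min = k_min, k_max = k_max,
                                         dlpfc_bias = dlpfc_bias)),
            class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("Prescription for %s (%d target%s)\n", x$subject_id,
              nrow(x$targets), if (nrow(x$targets) == 1) "" else "s"))
  if (nrow(x$targets)) {
    for (i in seq_len(nrow(x$targets)))
      cat(sprintf("  %d. %-12s %s  (hyper %d / hypo %d)\n", i,
                  x$targets$parcel_id[i], x$targets$protocol[i],
                  x$targets$hyper_count[i], x$targets$hypo_count[i]))
  } else cat("  (no qualifying targets)\n")
  invisible(x)
}

#' Write a prescription as JSON or TSV
#'
#' @param p a `prescription`.
#' @param path output path; `.json` writes JSON, anything else a TSV with
#'   columns subject, rank, parcel, protocol, hyper, hypo.
#' @export
write_prescription <- function(p, path) {
  stopifnot(inherits(p, "prescription"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(subject_id = p$subject_id, targets = p$targets,
                              selection_params = p$selection_params),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    n <- nrow(p$targets)
    tab <- data.frame(subject = rep(p$subject_id, n),
                      rank = seq_len(n),
                      parcel = p$targets$parcel_id,
                      protocol = p$targets$protocol,
                      hyper = p$targets$hyper_count,
                      hypo = p$targets$hypo_count)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
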