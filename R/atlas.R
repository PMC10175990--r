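#' Parcel atlases: inventory, networks, and DLPFC membership
#'
#' A parcel atlas is a data frame with one row per parcel and columns
#' `parcel_id` (unique, hemisphere-prefixed `L_`/`R_` for cortical parcels),
#' `hemisphere` (`left`/`right`/`midline`), `network` (`DMN`, `CEN`,
#' `salience`, or `other`) and `is_dlpfc` (logical). The bundled default
#' atlas covers the HCP multimodal parcellation (180 areas per hemisphere)
#' plus 17 subcortical structures, 377 parcels in all; network labels are
#' assigned only to parcels with an established lateralized or bilateral
#' affiliation in the coordinate-based meta-analytic literature, and both
#' the labels and the DLPFC flag are intended to be edited for local use.
#'
#' @param path path to a tab-delimited atlas file with header
#'   `parcel_id hemisphere network is_dlpfc`. `load_atlas()` with no
#'   argument loads the bundled default.
#' @return A data frame of class `parcel_atlas`.
#' @examples
#' atlas <- load_atlas()
#' nrow(atlas)                       # 377
#' subset(atlas, parcel_id == "L_8Av")$network
#' @export
load_atlas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atlas_default.tsv", package = "agiletms")
  if (!file.exists(path)) atlas_error("atlas file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  required <- c("parcel_id", "hemisphere", "network", "is_dlpfc")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    atlas_error("atlas is missing column(s): ", paste(missing, collapse = ", "))
  validate_atlas(tab)
}

validate_atlas <- function(tab) {
  line <- function(rows) paste(rows + 1L, collapse = ", ")  # +1 for header
  dup <- which(duplicated(tab$parcel_id))
  if (length(dup))
    atlas_error("duplicate parcel_id at line(s) ", line(dup), ": ",
                paste(unique(tab$parcel_id[dup]), collapse = ", "))
  bad_hemi <- which(!tab$hemisphere %in% c("left", "right", "midline"))
  if (length(bad_hemi))
    atlas_error("unknown hemisphere at line(s) ", line(bad_hemi))
  bad_net <- which(!tab$network %in% c("DMN", "CEN", "salience", "other"))
  if (length(bad_net))
    atlas_error("unknown network label at line(s) ", line(bad_net), ": ",
                paste(unique(tab$network[bad_net]), collapse = ", "))
  tab$is_dlpfc <- as.logical(tab$is_dlpfc)
  if (anyNA(tab$is_dlpfc)) atlas_error("is_dlpfc must be true/false")
  class(tab) <- c("parcel_atlas", "data.frame")
  tab
}

#' @rdname load_atlas
#' @param atlas a `parcel_atlas`.
#' @param networks character vector of network labels to select.
#' @return `network_parcels()`: parcel ids whose network is in `networks`,
#'   ordered by (network, hemisphere, parcel_id).
#' @export
network_parcels <- function(atlas, networks) {
  if (!length(networks)) atlas_error("networks must be non-empty")
  bad <- setdiff(networks, c("DMN", "CEN", "salience", "other"))
  if (length(bad))
    atlas_error("unknown network(s): ", paste(bad, collapse = ", "))
  sel <- atlas[atlas$network %in% networks, , drop = FALSE]
  if (!nrow(sel)) {
    warning("no parcels in network(s) ", paste(networks, collapse = ", "))
    return(character())
  }
  sel <- sel[order(sel$network, sel$hemisphere, sel$parcel_id), ]
  sel$parcel_id
}

#' Small synthetic atlas for simulated cohorts
#'
#' Builds an atlas for `n_parcels` synthetic parcels named `L_S001`,
#' `R_S002`, ... with networks assigned in rotation (DMN, CEN, salience,
#' other) so that simulated anomaly matrices always have in-network blocks
#' to select targets from; every eighth parcel is flagged DLPFC.
#'
#' @param n_parcels number of parcels (>= 2).
#' @return A `parcel_atlas`.
#' @export
synthetic_atlas <- function(n_parcels) {
  if (n_parcels < 2) config_error("n_parcels must be >= 2")
  i <- seq_len(n_parcels)
  hemi <- ifelse(i %% 2L == 1L, "left", "right")
  tab <- data.frame(
    parcel_id = sprintf("%s_S%03d", ifelse(hemi == "left", "L", "R"), i),
    hemisphere = hemi,
    network = c("DMN", "CEN", "salience", "other")[((i - 1L) %% 4L) + 1L],
    is_dlpfc = (i %% 8L) == 1L,
    stringsAsFactors = FALSE
  )
  validate_atlas(tab)
}
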