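#' Theta-burst stimulation protocol parameters
#'
#' Both protocols deliver 3-pulse bursts at 50 Hz within the burst, bursts
#' repeating every 200 ms (5 Hz), at 80% of the resting motor threshold.
#' iTBS gives 40 trains of 10 bursts (2 s on) separated by 6.3 s, 1200
#' pulses in all; cTBS gives one continuous train of 600 bursts, 1800
#' pulses. Derived quantities (total pulses, train and session durations)
#' are computed from the stored parameters, never stored.
#'
#' @param name `"iTBS"` or `"cTBS"`.
#' @return An object of class `tbs_protocol`.
#' @examples
#' total_pulses(tbs_protocol("iTBS"))   # 1200
#' total_pulses(tbs_protocol("cTBS"))   # 1800
#' @export
tbs_protocol <- function(name = c("iTBS", "cTBS")) {
  if (!is.character(name) || !name[1] %in% c("iTBS", "cTBS"))
    config_error("unknown protocol: ", paste(name[1], collapse = ""))
  name <- name[1]
  par <- switch(name,
    iTBS = list(n_trains = 40L, bursts_per_train = 10L,
                intertrain_interval_s = 6.3),
    cTBS = list(n_trains = 1L, bursts_per_train = 600L,
                intertrain_interval_s = 0))
  structure(c(list(name = name, pulses_per_burst = 3L,
                   burst_frequency_hz = 50, burst_period_s = 0.2,
                   intensity_pct_rmt = 80L), par),
            class = "tbs_protocol")
}

#' @rdname tbs_protocol
#' @param p a `tbs_protocol`.
#' @export
total_pulses <- function(p) {
  stopifnot(inherits(p, "tbs_protocol"))
  p$n_trains * p$bursts_per_train * p$pulses_per_burst
}

#' @rdname tbs_protocol
#' @export
train_duration_s <- function(p) {
  stopifnot(inherits(p, "tbs_protocol"))
  p$bursts_per_train * p$burst_period_s
}

#' @rdname tbs_protocol
#' @export
session_duration_s <- function(p) {
  stopifnot(inherits(p, "tbs_protocol"))
  p$n_trains * train_duration_s(p) +
    (p$n_trains - 1L) * p$intertrain_interval_s
}

#' @export
print.tbs_protocol <- function(x, ...) {
  cat(sprintf(paste0("%s: %d trains x %d bursts x %d pulses @ %g Hz ",
                     "(burst every %g s), ITI %g s, %d%% RMT\n",
                     "  total %d pulses, %.1f s per target\n"),
              x$name, x$n_trains, x$bursts_per_train, x$pulses_per_burst,
              x$burst_frequency_hz, x$burst_period_s,
              x$intertrain_interval_s, x$intensity_pct_rmt,
              total_pulses(x), session_duration_s(x)))
  invisible(x)
}

#' Plan an accelerated TBS course for a prescription
#'
#' The accelerated schedule delivers `sessions_per_day` sessions per day
#' (started at `session_interval_min` spacing) for `n_days` days; in every
#' session all prescribed targets are stimulated consecutively with their
#' assigned protocol. The default 5 x 5 course gives 25 sessions, so a
#' single cTBS target accumulates 45,000 pulses over the course and an iTBS
#' target 30,000.
#'
#' @param p a `prescription` with at least one target.
#' @param sessions_per_day sessions per day (default 5).
#' @param n_days treatment days (default 5).
#' @param session_interval_min minutes between session starts (default 60).
#' @return An object of class `course_schedule` with the per-target pulse
#'   budget and total course pulse count.
#' @export
plan_course <- function(p, sessions_per_day = 5L, n_days = 5L,
                        session_interval_min = 60) {
  stopifnot(inherits(p, "prescription"))
  if (!nrow(p$targets)) config_error("prescription has no targets")
  total_sessions <- as.integer(sessions_per_day) * as.integer(n_days)
  per_target <- data.frame(
    parcel_id = p$targets$parcel_id,
    protocol = p$targets$protocol,
    pulses_per_session = vapply(p$targets$protocol,
                                function(n) total_pulses(tbs_protocol(n)),
                                integer(1)),
    row.names = NULL
  )
  per_target$course_pulses <- per_target$pulses_per_session * total_sessions
  structure(list(subject_id = p$subject_id,
                 sessions_per_day = as.integer(sessions_per_day),
                 n_days = as.integer(n_days),
                 session_interval_min = session_interval_min,
                 total_sessions = total_sessions,
                 per_target = per_target,
                 course_pulses = sum(per_target$course_pulses)),
            class = "course_schedule")
}

#' @export
print.course_schedule <- function(x, ...) {
  cat(sprintf("Course for %s: %d sessions (%d/day x %d days, every %g min)\n",
              x$subject_id, x$total_sessions, x$sessions_per_day, x$n_days,
              x$session_interval_min))
  for (i in seq_len(nrow(x$per_target)))
    cat(sprintf("  %-12s %s  %d pulses/session, %d over the course\n",
                x$per_target$parcel_id[i], x$per_target$protocol[i],
                x$per_target$pulses_per_session[i],
                x$per_target$course_pulses[i]))
  cat(sprintf("  course total: %d pulses\n", x$course_pulses))
  invisible(x)
}

#' Export per-target binary masks from a labeled parcellation volume
#'
#' For each prescribed target, writes (or returns) a binary NIfTI mask on
#' the grid and affine of the input parcellation volume, plus the mask
#' centroid in world coordinates — the point the stimulation coil is
#' centered over.
#'
#' @param p a `prescription`.
#' @param parcellation a labeled 3-D volume: an `RNifti` image or an array
#'   (an array is taken with an identity affine).
#' @param label_map named integer vector mapping `parcel_id` to volume
#'   label.
#' @param out_dir optional directory; when given, masks are written as
#'   `<subject>_<parcel>_mask.nii.gz`.
#' @return A list per target with `parcel_id`, `mask` (integer volume),
#'   `n_voxels`, `centroid_world`, and `path` when written.
#' @export
export_target_masks <- function(p, parcellation, label_map, out_dir = NULL) {
  stopifnot(inherits(p, "prescription"))
  img <- RNifti::asNifti(parcellation)
  arr <- as.array(img)
  xfm <- RNifti::xform(img)
  lapply(seq_len(nrow(p$targets)), function(i) {
    parcel <- p$targets$parcel_id[i]
    if (!parcel %in% names(label_map))
      atlas_error("no volume label for target parcel ", parcel)
    lab <- label_map[[parcel]]
    mask <- array(0L, dim(arr))
    hit <- which(arr == lab)
    if (!length(hit)) atlas_error("label ", lab, " (", parcel,
                                  ") absent from the parcellation volume")
    mask[hit] <- 1L
    vox <- which(mask == 1L, arr.ind = TRUE)
    centre_vox <- colMeans(vox) - 1  # 0-based voxel coordinates
    centroid <- as.numeric(xfm %*% c(centre_vox, 1))[1:3]
    out <- RNifti::asNifti(mask, reference = img)
    path <- NULL
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, sprintf("%s_%s_mask.nii.gz",
                                         p$subject_id, gsub("/", "-", parcel)))
      RNifti::writeNifti(out, path)
    }
    list(parcel_id = parcel, mask = out, n_voxels = length(hit),
         centroid_world = centroid, path = path)
  })
}
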