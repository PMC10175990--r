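#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: either a directory of
#' reference time-series files plus patient files, or a simulation block
#' (a [synthetic_config()] and per-patient anomaly specs); the atlas; and
#' the analysis parameters with their standard defaults (3-sigma outliers,
#' exclusion of the most variable third of edges, DMN + CEN search space,
#' 2-3 targets with a 1.2 DLPFC priority, analytic shrinkage).
#'
#' `read_pipeline_config()` loads the same structure from a YAML or JSON
#' file.
#'
#' @param out_dir output directory (created if needed).
#' @param atlas a `parcel_atlas`, a path to one, or `NULL` to use the
#'   synthetic atlas matching the simulated parcel count.
#' @param cohort_dir directory of reference time-series TSVs (ignored when
#'   `simulation` is given).
#' @param patient_files character vector of patient time-series TSVs.
#' @param simulation list with elements `config` (a [synthetic_config()])
#'   and `patients` (list; each element a list of [anomaly_spec()]s).
#' @param sigma_threshold,exclusion_fraction normative-model parameters.
#' @param networks,min_anomalies,k_min,k_max,dlpfc_bias selection
#'   parameters.
#' @param shrinkage shrinkage intensity or `"auto"`.
#' @param seed master RNG seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, atlas = NULL, cohort_dir = NULL,
                            patient_files = NULL, simulation = NULL,
                            sigma_threshold = 3, exclusion_fraction = 1/3,
                            networks = c("DMN", "CEN"), min_anomalies = 2L,
                            k_min = 2L, k_max = 3L, dlpfc_bias = 1.2,
                            shrinkage = "auto", seed = 1L) {
  if (is.null(simulation) && is.null(cohort_dir))
    config_error("either a cohort_dir or a simulation block is required")
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    config_error("cohort_dir does not exist: ", cohort_dir)
  if (is.character(atlas)) atlas <- load_atlas(atlas)
  structure(list(out_dir = out_dir, atlas = atlas, cohort_dir = cohort_dir,
                 patient_files = patient_files, simulation = simulation,
                 sigma_threshold = sigma_threshold,
                 exclusion_fraction = exclusion_fraction,
                 networks = networks, min_anomalies = min_anomalies,
                 k_min = k_min, k_max = k_max, dlpfc_bias = dlpfc_bias,
                 shrinkage = shrinkage, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- raw$simulation
  if (!is.null(sim)) {
    sim$config <- do.call(synthetic_config, as.list(sim$config))
    sim$patients <- lapply(sim$patients, function(p)
      lapply(p, function(a) do.call(anomaly_spec, as.list(a))))
  }
  args <- raw[setdiff(names(raw), "simulation")]
  do.call(pipeline_config, c(args, list(simulation = sim)))
}

#' Run the full target-selection pipeline
#'
#' Executes every stage — cohort simulation or ingest, shrunk correlation,
#' tangent embedding at the cohort geometric mean, normative fit, patient
#' scoring, agile target selection, course planning, and report export —
#' and writes per-patient artifacts plus a JSON run manifest (parameters,
#' seeds, per-file checksums) to `config$out_dir`. Deterministic under a
#' fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return The run manifest, invisibly; artifact paths in
#'   `manifest$artifacts`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  simulated <- !is.null(config$simulation)
  if (simulated) {
    sim <- config$simulation
    atlas <- config$atlas
    if (is.null(atlas)) atlas <- synthetic_atlas(sim$config$n_parcels)
    ids <- atlas$parcel_id
    say("simulating reference cohort (n = ", sim$config$n_reference, ")")
    cohort <- generate_reference_cohort(sim$config, parcel_ids = ids)
  } else {
    atlas <- config$atlas
    if (is.null(atlas)) config_error("an atlas is required for file input")
    files <- list.files(config$cohort_dir, full.names = TRUE,
                        pattern = "\\.(tsv|txt)$")
    if (length(files) < 2) config_error("cohort_dir holds < 2 series files")
    cohort <- lapply(files, read_time_series)
  }

  say("embedding reference cohort (", length(cohort), " subjects)")
  ref <- embed_cohort(cohort, config$shrinkage)
  say("fitting normative model")
  model <- fit_normative(ref$tangents,
                         sigma_threshold = config$sigma_threshold,
                         exclusion_fraction = config$exclusion_fraction)

  if (simulated) {
    pat_seeds <- derive_seeds(config$seed, length(sim$patients), salt = 11L)
    patients <- lapply(seq_along(sim$patients), function(i) {
      say("simulating patient ", i)
      generate_patient(sim$config, sim$patients[[i]], seed = pat_seeds[i],
                       parcel_ids = ids, reference = ref, model = model,
                       subject_id = sprintf("patient%02d", i))$ts
    })
  } else {
    patients <- lapply(config$patient_files, read_time_series)
  }

  artifacts <- character()
  results <- lapply(patients, function(ts) {
    say("scoring ", ts$subject_id)
    am <- predict(model, embed_patient(ts, ref))
    rep <- anomaly_report(am, atlas, config$networks)
    presc <- select_targets(am, atlas = atlas, networks = config$networks,
                            min_anomalies = config$min_anomalies,
                            k_min = config$k_min, k_max = config$k_max,
                            dlpfc_bias = config$dlpfc_bias)
    paths <- c(
      report = file.path(config$out_dir,
                         paste0(ts$subject_id, "_anomalies.tsv")),
      prescription = file.path(config$out_dir,
                               paste0(ts$subject_id, "_prescription.tsv")))
    write_anomaly_report(rep, paths[["report"]])
    write_prescription(presc, paths[["prescription"]])
    if (nrow(presc$targets)) {
      schedule <- plan_course(presc)
      paths[["schedule"]] <- file.path(config$out_dir,
                                       paste0(ts$subject_id, "_course.json"))
      jsonlite::write_json(
        list(subject_id = schedule$subject_id,
             total_sessions = schedule$total_sessions,
             per_target = schedule$per_target,
             course_pulses = schedule$course_pulses),
        paths[["schedule"]], auto_unbox = TRUE, digits = NA)
    } else schedule <- NULL
    artifacts <<- c(artifacts, paths)
    list(subject_id = ts$subject_id, anomalies = am, prescription = presc,
         schedule = schedule)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("agiletms")),
    seed = config$seed,
    parameters = config[c("sigma_threshold", "exclusion_fraction",
                          "networks", "min_anomalies", "k_min", "k_max",
                          "dlpfc_bias", "shrinkage")],
    n_reference = length(cohort),
    n_patients = length(patients),
    geometric_mean = list(iterations = ref$g$iterations_used,
                          converged = ref$g$converged),
    shrinkage_used = ref$shrinkage,
    artifacts = as.list(artifacts),
    checksums = as.list(tools::md5sum(unname(artifacts)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  manifest$results <- results
  manifest$model <- model
  invisible(manifest)
}

#' Reduced-scale demonstration configuration
#'
#' A complete synthetic study that runs in seconds: 64 parcels, a
#' 60-subject reference cohort, and `n_patients` patients each carrying two
#' injected 4-sigma anomalies on network parcels (one hyper, one hypo).
#'
#' @param out_dir output directory.
#' @param n_patients number of simulated patients (default 5).
#' @param seed master seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(out_dir = tempfile("agiletms_demo"), n_patients = 5,
                        seed = 1L) {
  cfg <- synthetic_config(n_reference = 60, n_parcels = 64, n_volumes = 128,
                          seed = seed)
  atlas <- synthetic_atlas(cfg$n_parcels)
  net <- network_parcels(atlas, c("DMN", "CEN"))
  picks <- derive_seeds(seed, 2 * n_patients, salt = 3L) %% length(net) + 1
  patients <- lapply(seq_len(n_patients), function(i) {
    a <- net[picks[2 * i - 1]]
    b <- net[picks[2 * i]]
    if (b == a) b <- net[(picks[2 * i] %% length(net)) + 1]
    list(anomaly_spec(a, "hyper", 4, pool = net),
         anomaly_spec(b, "hypo", 4, pool = net))
  })
  pipeline_config(out_dir = out_dir, atlas = atlas,
                  simulation = list(config = cfg, patients = patients),
                  seed = seed)
}
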