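#' Plain-text interchange formats
#'
#' Recordings travel as two-column CSV (`time_s`, `value`) with a JSON
#' sidecar holding the metadata and ground truth; cohorts get a one-row
#' -per-subject manifest CSV. Foot annotations and normalization models
#' round-trip as JSON; feature tables as CSV.
#'
#' @name io
NULL

#' Write a recording as CSV plus JSON sidecar
#'
#' @param recording a [pulse_recording()].
#' @param path CSV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "pulse_recording"))
  n <- length(recording$samples)
  df <- data.frame(time_s = (0:(n - 1)) / recording$sampling_rate_hz,
                   value = recording$samples)
  write.csv(df, path, row.names = FALSE)
  side <- list(subject_id = recording$subject_id, label = recording$label,
               severity = recording$severity, channel = recording$channel,
               sampling_rate_hz = recording$sampling_rate_hz)
  if (!is.null(attr(recording, "feet")))
    side$ground_truth_feet <- attr(recording, "feet")
  sp <- attr(recording, "spec")
  if (!is.null(sp))
    side$template <- list(dc_level = sp$template$dc_level,
                          amp_proportions = sp$template$amp_proportions,
                          phases = sp$template$phases)
  jsonlite::write_json(side, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path (sidecar looked up next to it).
#' @return a [pulse_recording()]; ground-truth feet, if present in the
#'   sidecar, are restored as the `feet` attribute.
#' @export
read_recording <- function(path) {
  df <- read.csv(path)
  side_path <- sub("\\.[^.]+$", ".json", path)
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
  else list()
  fs <- side$sampling_rate_hz %||%
    (1 / stats::median(diff(df$time_s)))
  rec <- pulse_recording(df$value, fs,
                         channel = side$channel %||% "BPW",
                         subject_id = side$subject_id %||% "unknown",
                         label = side$label %||% "unknown",
                         severity = side$severity %||% "none")
  if (!is.null(side$ground_truth_feet))
    attr(rec, "feet") <- as.integer(side$ground_truth_feet)
  rec
}

#' Write a cohort to a directory
#'
#' One CSV + JSON sidecar per subject plus `manifest.csv` (subject_id,
#' label, severity, file).
#'
#' @param cohort a [synth_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pulse_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    id <- cohort$manifest$subject_id[i]
    files[i] <- file.path(dir, paste0(id, ".csv"))
    write_recording(cohort$recordings[[id]], files[i])
  }
  manifest <- data.frame(cohort$manifest, file = basename(files))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return a `pulse_cohort`-like list with `recordings` and `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(manifest$file, function(f) read_recording(file.path(dir, f)))
  names(recs) <- manifest$subject_id
  structure(list(recordings = recs,
                 manifest = manifest[, c("subject_id", "label", "severity")]),
            class = "pulse_cohort")
}

#' Foot-annotation JSON round-trip
#'
#' @param feet a [detect_feet()] annotation.
#' @param path JSON path.
#' @return `path` invisibly (`write_feet`); a `foot_annotation`
#'   (`read_feet`).
#' @export
write_feet <- function(feet, path) {
  stopifnot(inherits(feet, "foot_annotation"))
  jsonlite::write_json(list(indices = feet$indices, method = feet$method,
                            params = feet$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feet
#' @export
read_feet <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(indices = as.integer(j$indices), method = j$method,
                 params = j$params),
            class = "foot_annotation")
}

#' Normalization-model JSON round-trip
#'
#' @param model a [normalize_fit()] model.
#' @param path JSON path.
#' @return `path` invisibly (`write_normalization`); a
#'   `normalization_model` (`read_normalization`).
#' @export
write_normalization <- function(model, path) {
  stopifnot(inherits(model, "normalization_model"))
  jsonlite::write_json(list(mean = as.list(model$mean), sd = as.list(model$sd),
                            columns = model$columns),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = unlist(j$mean), sd = unlist(j$sd),
                 columns = j$columns),
            class = "normalization_model")
}
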