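#' End-to-end pipeline helpers
#'
#' Convenience wrappers chaining the stages: filter, segment, per-beat
#' harmonic indices, windowed features, and the cohort-level feature
#' matrix consumed by the classification protocol and the comparison
#' tables.
#'
#' @name pipeline
NULL

#' Per-beat indices for one recording (filter + segment + analyze)
#'
#' @param recording a raw [pulse_recording()].
#' @param fspec a [filter_spec()]; `NULL` skips filtering.
#' @param feet `"detect"` (default) to run [detect_feet()], `"truth"` to
#'   use the generator's ground-truth annotation, or an explicit integer
#'   vector / [detect_feet()] annotation.
#' @param baseline_mode see [fourier_coefficients()].
#' @param ... passed to [detect_feet()].
#' @return the [beat_indices()] data.frame.
#' @export
extract_indices <- function(recording, fspec = filter_spec(),
                            feet = c("detect", "truth"),
                            baseline_mode = "min_zero", ...) {
  rec <- if (is.null(fspec)) recording else apply_filter(recording, fspec)
  if (is.character(feet)) {
    feet <- match.arg(feet)
    feet <- if (feet == "detect") detect_feet(rec, ...)
    else {
      ft <- attr(recording, "feet")
      if (is.null(ft)) stop("no ground-truth feet on this recording")
      ft
    }
  }
  beat_indices(rec, feet, baseline_mode = baseline_mode)
}

#' Beat and window index tables for a whole cohort
#'
#' Runs [extract_indices()] and [assemble_features()] per subject and
#' binds the results. Subjects with fewer than `window` analyzable beats
#' are excluded with a message.
#'
#' @param cohort a [synth_cohort()] (or [read_cohort()]) object.
#' @param fspec a [filter_spec()]; `NULL` skips filtering.
#' @param feet `"detect"` or `"truth"` (see [extract_indices()]).
#' @param baseline_mode see [fourier_coefficients()].
#' @param window window length in beats.
#' @param ... passed to [detect_feet()].
#' @return list with `beats` (per-beat rows, all subjects) and
#'   `features` (per-window 40-feature rows, all subjects).
#' @export
cohort_indices <- function(cohort, fspec = filter_spec(),
                           feet = "detect", baseline_mode = "min_zero",
                           window = 15, ...) {
  beats <- list(); feats <- list(); excluded <- character(0)
  for (id in names(cohort$recordings)) {
    res <- tryCatch({
      b <- extract_indices(cohort$recordings[[id]], fspec, feet,
                           baseline_mode, ...)
      f <- assemble_features(b, window = window)
      list(b = b, f = f)
    }, error = function(e) e)
    if (inherits(res, "error")) { excluded <- c(excluded, id); next }
    beats[[id]] <- res$b
    feats[[id]] <- res$f
  }
  if (length(excluded) > 0L)
    message(length(excluded), " subject(s) excluded: ",
            paste(excluded, collapse = ", "))
  if (length(beats) == 0L) stop("no analyzable subjects")
  list(beats = do.call(rbind, c(beats, list(make.row.names = FALSE))),
       features = do.call(rbind, c(feats, list(make.row.names = FALSE))))
}

#' Simulate a cohort and run the full classification protocol
#'
#' One call = one complete in-silico study: generate the cohort, extract
#' the feature matrix through the filtering/segmentation/spectral
#' pipeline, draw the subject-level split and run the MLP protocol.
#'
#' @param config a [cohort_config()].
#' @param mlp an [mlp_config()]; its seed defaults to the cohort seed.
#' @param feet `"detect"` or `"truth"`.
#' @param level evaluation level for the reports.
#' @param window window length in beats.
#' @return list: `report` (the [run_protocol()] result), `indices`
#'   (beat/feature tables), `cohort`, `split`.
#' @export
protocol_simulation <- function(config, mlp = NULL, feet = "detect",
                                level = "pulse", window = 15) {
  cohort <- synth_cohort(config)
  idx <- cohort_indices(cohort, feet = feet, window = window)
  split <- make_split(cohort$manifest, seed = derive_seed(config$seed, "split"))
  if (is.null(mlp)) mlp <- mlp_config(seed = derive_seed(config$seed, "mlp"))
  report <- run_protocol(idx$features, split, mlp, level = level)
  list(report = report, indices = idx, cohort = cohort, split = split)
}
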