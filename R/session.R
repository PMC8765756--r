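#' Assemble a recording session
#'
#' A session bundles everything recorded while a monkey held fixation: one row
#' per trial with its event times, region-labeled units, their spike times
#' (milliseconds relative to trial start), and the continuously sampled pupil
#' diameter trace. All downstream analyses take a session (or tables derived
#' from one) as their first argument.
#'
#' @param session_id Single string identifying the session.
#' @param units Tibble with columns `unit_id` (character, unique) and `region`
#'   (one of `"LC"`, `"ACC"`).
#' @param trials Tibble with columns `trial_id` (integer, unique, ordered),
#'   `fix_on`, `stable_fix_on`, `beep_time` (`NA` on no-beep trials),
#'   `trial_end` (all ms relative to trial start) and `gaze_ok` (logical
#'   pass/fail summary of the fixation-window gaze criterion; raw eye traces
#'   are assumed to be quality-controlled upstream).
#' @param spikes Tibble with columns `trial_id`, `unit_id`, `time_ms`.
#' @param pupil Either `NULL` (no pupil data) or a list with elements
#'   `sample_rate` (Hz), `t0` (ms of the first sample relative to trial
#'   start) and `samples`, a tibble with columns `trial_id`, `sample_index`
#'   (1-based), `value` (diameter, arbitrary units).
#' @param meta Named list of scalar metadata (monkey label, notes, ...).
#' @param validate Check invariants (default `TRUE`).
#'
#' @return An object of class `lcacc_session`.
#' @seealso [read_session()], [write_session()], [simulate_session()]
#' @export
session <- function(session_id, units, trials, spikes, pupil = NULL,
                    meta = list(), validate = TRUE) {
  if (is.null(pupil)) {
    pupil <- list(
      sample_rate = 1000, t0 = 0,
      samples = tibble::tibble(
        trial_id = integer(), sample_index = integer(), value = double()
      )
    )
  }
  s <- structure(
    list(
      session_id = as.character(session_id),
      units = tibble::as_tibble(units),
      trials = tibble::as_tibble(trials),
      spikes = tibble::as_tibble(spikes),
      pupil = pupil,
      meta = meta
    ),
    class = "lcacc_session"
  )
  if (validate) validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks that unit regions are LC/ACC, trial ids are unique and event times
#' ordered (`fix_on < stable_fix_on < trial_end`, beep inside the trial), and
#' that every spike lies inside its trial. Errors name the offending trial or
#' unit.
#'
#' @param s An `lcacc_session`.
#' @return `s`, invisibly, if valid.
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "lcacc_session"))
  u <- s$units
  tr <- s$trials
  if (anyDuplicated(u$unit_id)) {
    rlang::abort(paste0("duplicate unit_id: ", u$unit_id[duplicated(u$unit_id)][1]),
                 class = "lcacc_validation_error")
  }
  bad_region <- !u$region %in% c("LC", "ACC")
  if (any(bad_region)) {
    rlang::abort(paste0("unit ", u$unit_id[bad_region][1],
                        " has region '", u$region[bad_region][1],
                        "' (must be LC or ACC)"),
                 class = "lcacc_validation_error")
  }
  if (anyDuplicated(tr$trial_id)) {
    rlang::abort(paste0("duplicate trial_id: ", tr$trial_id[duplicated(tr$trial_id)][1]),
                 class = "lcacc_validation_error")
  }
  if (is.unsorted(tr$trial_id, strictly = TRUE)) {
    rlang::abort("trial ids must be strictly increasing",
                 class = "lcacc_validation_error")
  }
  bad <- !(tr$fix_on < tr$stable_fix_on & tr$stable_fix_on < tr$trial_end)
  if (any(bad)) {
    rlang::abort(paste0("trial ", tr$trial_id[bad][1],
                        ": requires fix_on < stable_fix_on < trial_end"),
                 class = "lcacc_validation_error")
  }
  has_beep <- !is.na(tr$beep_time)
  bad <- has_beep & !(tr$beep_time > tr$stable_fix_on & tr$beep_time < tr$trial_end)
  if (any(bad)) {
    rlang::abort(paste0("trial ", tr$trial_id[bad][1],
                        ": beep_time outside (stable_fix_on, trial_end)"),
                 class = "lcacc_validation_error")
  }
  sp <- s$spikes
  if (nrow(sp)) {
    if (!all(sp$unit_id %in% u$unit_id)) {
      rlang::abort(paste0("spike references unknown unit ",
                          setdiff(sp$unit_id, u$unit_id)[1]),
                   class = "lcacc_validation_error")
    }
    if (!all(sp$trial_id %in% tr$trial_id)) {
      rlang::abort(paste0("spike references unknown trial ",
                          setdiff(sp$trial_id, tr$trial_id)[1]),
                   class = "lcacc_validation_error")
    }
    end_of <- stats::setNames(tr$trial_end, tr$trial_id)
    out <- sp$time_ms < 0 | sp$time_ms > end_of[as.character(sp$trial_id)]
    if (any(out)) {
      i <- which(out)[1]
      rlang::abort(paste0("spike at t = ", sp$time_ms[i], " ms from unit ",
                          sp$unit_id[i], " lies outside trial ", sp$trial_id[i]),
                   class = "lcacc_validation_error")
    }
  }
  ps <- s$pupil$samples
  if (nrow(ps) && !all(ps$trial_id %in% tr$trial_id)) {
    rlang::abort(paste0("pupil sample references unknown trial ",
                        setdiff(ps$trial_id, tr$trial_id)[1]),
                 class = "lcacc_validation_error")
  }
  invisible(s)
}

#' @export
print.lcacc_session <- function(x, ...) {
  cat("<lcacc_session> ", x$session_id, "\n", sep = "")
  cat("  trials: ", nrow(x$trials),
      " (beep on ", sum(!is.na(x$trials$beep_time)), ")\n", sep = "")
  cat("  units:  ", nrow(x$units), " (LC ", sum(x$units$region == "LC"),
      ", ACC ", sum(x$units$region == "ACC"), ")\n", sep = "")
  cat("  spikes: ", nrow(x$spikes), "\n", sep = "")
  cat("  pupil:  ", nrow(x$pupil$samples), " samples @ ",
      x$pupil$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Write a session to a directory
#'
#' Serializes a session as a JSON manifest plus four CSV tables (trials,
#' units, spikes, pupil). The format is plain text, inspectable, and
#' language-agnostic; [read_session()] restores an equal session. Output is
#' deterministic: the same session always produces byte-identical files.
#'
#' @param s An `lcacc_session`.
#' @param path Directory to create/overwrite files in.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "lcacc-session",
    version = 1L,
    session_id = s$session_id,
    pupil = list(sample_rate = s$pupil$sample_rate, t0 = s$pupil$t0),
    meta = s$meta,
    files = list(trials = "trials.csv", units = "units.csv",
                 spikes = "spikes.csv", pupil = "pupil.csv")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  wr <- function(x, file) {
    x <- dplyr::mutate(x, dplyr::across(
      dplyr::where(is.double),
      ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))
    ))
    readr::write_csv(x, file.path(path, file), progress = FALSE)
  }
  wr(s$trials, "trials.csv")
  wr(s$units, "units.csv")
  wr(s$spikes, "spikes.csv")
  wr(s$pupil$samples, "pupil.csv")
  invisible(path)
}

#' Read a session from a directory
#'
#' @param path Directory written by [write_session()].
#' @return An `lcacc_session` satisfying all invariants.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    rlang::abort(paste0("no manifest.json in ", path), class = "lcacc_format_error")
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("format", "session_id", "pupil", "files")
  if (!all(need %in% names(manifest)) ||
      !identical(manifest$format, "lcacc-session")) {
    rlang::abort("malformed manifest: not an lcacc-session directory",
                 class = "lcacc_format_error")
  }
  for (tab in c("trials", "units", "spikes", "pupil")) {
    f <- manifest$files[[tab]]
    if (is.null(f) || !file.exists(file.path(path, f))) {
      rlang::abort(paste0("manifest is missing the ", tab, " table"),
                   class = "lcacc_format_error")
    }
  }
  # doubles are read as text and converted with strtod so the 17-digit
  # representation written by write_session round-trips bit-exactly
  rd <- function(tab, types) {
    dbl <- names(types$cols)[vapply(types$cols, inherits, logical(1),
                                    "collector_double")]
    for (nm in dbl) types$cols[[nm]] <- readr::col_character()
    x <- readr::read_csv(file.path(path, manifest$files[[tab]]),
                         col_types = types, progress = FALSE, lazy = FALSE)
    for (nm in dbl) x[[nm]] <- as.numeric(x[[nm]])
    tibble::as_tibble(as.data.frame(x))  # drop reader-specific attributes
  }
  meta <- manifest$meta
  if (length(meta) == 0) meta <- list()
  session(
    session_id = manifest$session_id,
    units = rd("units", readr::cols(unit_id = "c", region = "c")),
    trials = rd("trials", readr::cols(
      trial_id = "i", fix_on = "d", stable_fix_on = "d",
      beep_time = "d", trial_end = "d", gaze_ok = "l"
    )),
    spikes = rd("spikes", readr::cols(trial_id = "i", unit_id = "c", time_ms = "d")),
    pupil = list(
      sample_rate = manifest$pupil$sample_rate,
      t0 = manifest$pupil$t0,
      samples = rd("pupil", readr::cols(trial_id = "i", sample_index = "i", value = "d"))
    ),
    meta = meta
  )
}

#' Stable-fixation analysis epochs
#'
#' One epoch per qualifying trial: a window of `duration_ms` that begins
#' `offset_ms` after stable fixation was attained. Trials whose gaze summary
#' failed or that end before the window closes are excluded.
#'
#' @param s An `lcacc_session`.
#' @param offset_ms Start of the window relative to `stable_fix_on` (default
#'   1000 ms).
#' @param duration_ms Window length (default 1100 ms).
#' @return Tibble with columns `trial_id`, `start`, `duration` (ms relative
#'   to trial start). May have zero rows.
#' @export
extract_stable_fixation_epochs <- function(s, offset_ms = 1000, duration_ms = 1100) {
  stopifnot(duration_ms > 0, offset_ms >= 0)
  s$trials |>
    dplyr::filter(.data$gaze_ok,
                  .data$trial_end >= .data$stable_fix_on + offset_ms + duration_ms) |>
    dplyr::transmute(
      trial_id = .data$trial_id,
      start = .data$stable_fix_on + offset_ms,
      duration = duration_ms
    )
}

# spike times of one unit split by trial, sorted; list names are trial ids
spikes_by_trial <- function(s, unit, trial_ids = s$trials$trial_id) {
  sp <- s$spikes[s$spikes$unit_id == unit, ]
  out <- split(sp$time_ms, factor(sp$trial_id, levels = trial_ids))
  lapply(out, sort)
}

#' Unit ids of one region
#'
#' @param s An `lcacc_session`.
#' @param region `"LC"` or `"ACC"`.
#' @return Character vector of unit ids, in session order.
#' @export
region_units <- function(s, region) s$units$unit_id[s$units$region == region]
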