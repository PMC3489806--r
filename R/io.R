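#' Read a two-channel EEG recording from CSV
#'
#' Reads the documented signal dialect: a CSV with header
#' `time_s, CA3_uV, MCX_uV` (one channel column may be absent). The
#' sampling rate is inferred from the time column, which must be uniform;
#' a skipped or irregular timestamp is rejected with the offending row
#' index.
#'
#' @param path Path to the CSV file.
#' @return An `eeg_recording` tibble with a `sampling_rate` attribute.
#' @export
read_recording <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  known <- c("time_s", "CA3_uV", "MCX_uV")
  if (!"time_s" %in% names(df) || !any(c("CA3_uV", "MCX_uV") %in% names(df)))
    abort(paste0("unrecognized channel labels; found: ",
                 paste(names(df), collapse = ", "),
                 " (expected time_s plus CA3_uV and/or MCX_uV)"))
  extra <- setdiff(names(df), known)
  if (length(extra))
    abort(paste0("unknown channel labels: ", paste(extra, collapse = ", ")))
  dt <- diff(df$time_s)
  if (length(dt) == 0) abort("recording contains fewer than 2 samples")
  bad <- which(abs(dt - dt[1]) > 1e-6 * max(dt[1], 1e-12))
  if (length(bad))
    abort(sprintf("non-uniform timebase at row %d (dt %.6g vs %.6g)",
                  bad[1] + 1L, dt[bad[1]], dt[1]))
  fs <- 1 / dt[1]
  out <- tibble::as_tibble(df)
  if (!"CA3_uV" %in% names(out)) out$CA3_uV <- NA_real_
  if (!"MCX_uV" %in% names(out)) out$MCX_uV <- NA_real_
  out <- out[, known]
  class(out) <- c("eeg_recording", class(out))
  attr(out, "sampling_rate") <- fs
  out
}

#' Write a recording to the CSV signal dialect
#'
#' @param recording An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  readr::write_csv(tibble::as_tibble(recording)[, c("time_s", "CA3_uV", "MCX_uV")],
                   path, progress = FALSE)
  invisible(path)
}

ANNOTATION_TYPES <- c("spike", "seizure", "stage", "injection", "hfs")

validate_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  needed <- c("event_type", "channel", "onset_s", "offset_s", "label")
  missing <- setdiff(needed, names(ann))
  if (length(missing))
    abort(paste0("annotation lacks column(s): ", paste(missing, collapse = ", ")))
  bad <- setdiff(unique(ann$event_type), ANNOTATION_TYPES)
  if (length(bad))
    abort(paste0("unknown event_type(s): ", paste(bad, collapse = ", ")))
  iv <- !is.na(ann$offset_s)
  if (any(iv & ann$offset_s <= ann$onset_s))
    abort("annotation intervals must satisfy onset < offset")
  stage_to_int(ann$label[ann$event_type == "stage"]) # validates labels
  spk <- ann[ann$event_type == "spike", ]
  if (nrow(spk) > 1) {
    for (ch in unique(spk$channel)) {
      s <- spk[spk$channel %in% ch, ]
      s <- s[order(s$onset_s), ]
      if (nrow(s) > 1 && any(s$onset_s[-1] < s$offset_s[-nrow(s)]))
        abort(paste0("overlapping true spikes on channel ", ch))
    }
  }
  ann[, needed]
}

#' Read / write session annotations
#'
#' Annotations travel as a CSV with columns `event_type` (one of spike,
#' seizure, stage, injection, hfs), `channel`, `onset_s`, `offset_s`,
#' `label`, with times in seconds at microsecond precision. Reading
#' validates the schema: unknown event types, stage labels outside I-V,
#' inverted intervals and overlapping same-channel true spikes are
#' rejected. The round trip is lossless.
#'
#' @param path CSV path.
#' @return `read_annotations()` returns a `session_annotation` tibble.
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    event_type = readr::col_character(), channel = readr::col_character(),
    onset_s = readr::col_double(), offset_s = readr::col_double(),
    label = readr::col_character()), progress = FALSE)
  new_annotation(validate_annotation(df))
}

#' @rdname read_annotations
#' @param annotation A `session_annotation` tibble.
#' @export
write_annotations <- function(annotation, path) {
  readr::write_csv(validate_annotation(annotation), path, progress = FALSE)
  invisible(path)
}

#' Write detected events to CSV
#'
#' Writes spike or seizure event tables in a stable column order; an empty
#' event list produces a header-only CSV that reads back as an empty
#' tibble.
#'
#' @param events A `spike_events` or `seizure_events` tibble (any event
#'   tibble with an `onset_s` column).
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}

#' Assemble the annotation intervals a spike detector must skip
#'
#' Interictal spikes are by definition outside seizures and stimulation
#' epochs; this helper collects those intervals from an annotation (truth)
#' and/or a segmentation result.
#'
#' @param annotation Optional `session_annotation`.
#' @param seizures Optional tibble of seizure intervals.
#' @return Tibble with `onset_s`, `offset_s`.
#' @export
exclusion_intervals <- function(annotation = NULL, seizures = NULL) {
  parts <- list()
  if (!is.null(annotation)) {
    ann <- tibble::as_tibble(annotation)
    parts[[1]] <- ann[ann$event_type %in% c("seizure", "hfs"),
                      c("onset_s", "offset_s")]
  }
  if (!is.null(seizures) && nrow(tibble::as_tibble(seizures)) > 0)
    parts[[length(parts) + 1]] <-
      tibble::as_tibble(seizures)[, c("onset_s", "offset_s")]
  if (!length(parts)) return(tibble::tibble(onset_s = numeric(), offset_s = numeric()))
  dplyr::distinct(dplyr::bind_rows(parts))
}
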