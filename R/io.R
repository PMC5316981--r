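#' Read a recording from disk
#'
#' Reads the plain-text on-disk dialect: a CSV pressure matrix (one row per
#' sensor, first column `sensor` holding labels `P1..Pn`, remaining columns
#' samples) plus a YAML sidecar `<path>.yaml` carrying sampling rate, sensor
#' spacing, tip position, functional mask, phases, subject id and group.
#' Rows are reordered to the internal P1 (distal) .. Pn (proximal) convention
#' regardless of file order. `NA` cells restore non-finite pressures.
#'
#' @param path path to the CSV matrix; the sidecar is `<path>.yaml`.
#' @return a validated [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  df <- readr::read_csv(path, col_types = readr::cols(
    sensor = readr::col_character(), .default = readr::col_double()))
  n <- meta$n_sensors %||% 36L
  if (nrow(df) != n)
    stop("pressure matrix has ", nrow(df), " rows; expected ", n, " sensors",
         call. = FALSE)
  idx <- as.integer(sub("^P", "", df$sensor))
  if (anyNA(idx) || !setequal(idx, seq_len(n)))
    stop("sensor labels must be P1..P", n, call. = FALSE)
  mat <- as.matrix(df[order(idx), setdiff(names(df), "sensor")])
  bad <- which(!is.finite(mat) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric pressure at row ", bad[1, 1], ", column ", bad[1, 2],
         call. = FALSE)
  dimnames(mat) <- NULL
  phases <- if (length(meta$phases)) {
    dplyr::bind_rows(lapply(meta$phases, tibble::as_tibble))
  } else NULL
  recording(mat,
            sampling_rate = meta$sampling_rate,
            sensor_spacing = meta$sensor_spacing %||% 1,
            tip_position = meta$tip_position %||% 85,
            functional_mask = as.logical(meta$functional_mask %||%
                                           rep(TRUE, n)),
            phases = phases,
            subject_id = meta$subject_id %||% "anon",
            group = meta$group %||% "synthetic")
}

#' Write a recording to disk
#'
#' Writes the CSV matrix + YAML sidecar read back by [read_recording()].
#' Lossless for pressures at the written precision (full double precision by
#' default); non-finite pressures are written as `NA`.
#'
#' @param rec an `hrcm_recording`.
#' @param path output CSV path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  mat <- rec$pressures
  mat[!is.finite(mat)] <- NA
  df <- tibble::as_tibble(as.data.frame(mat),
                          .name_repair = ~ paste0("s", seq_along(.x)))
  df <- dplyr::bind_cols(
    tibble::tibble(sensor = paste0("P", seq_len(rec$n_sensors))), df)
  readr::write_csv(df, path)
  meta <- list(
    sampling_rate = rec$sampling_rate,
    sensor_spacing = rec$sensor_spacing,
    n_sensors = rec$n_sensors,
    tip_position = rec$tip_position,
    functional_mask = rec$functional_mask,
    subject_id = rec$subject_id,
    group = rec$group,
    phases = if (nrow(rec$phases)) {
      lapply(seq_len(nrow(rec$phases)), function(i) as.list(rec$phases[i, ]))
    } else list())
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

.annotation_kinds <- c("cough", "talk", "body_shift", "drink", "gas_expulsion",
                       "bowel_urge", "meal_start", "meal_end", "reposition",
                       "other")

#' Build an annotation log
#'
#' Timestamped subject/observer events noted during acquisition (coughs,
#' talking, body shifts, drinks, gas expulsion, meal markers, repositioning).
#' Rows are sorted chronologically.
#'
#' @param time_s event times, seconds from recording start.
#' @param kind event kinds, from the closed set `r paste(.annotation_kinds,
#'   collapse = ", ")`.
#' @param note free text.
#' @return tibble with columns `time_s`, `kind`, `note`, sorted by time.
#' @export
annotation_log <- function(time_s = double(), kind = character(),
                           note = "") {
  bad <- setdiff(unique(kind), .annotation_kinds)
  if (length(bad))
    stop("unknown annotation kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  tibble::tibble(time_s = as.double(time_s), kind = kind,
                 note = rep_len(as.character(note), length(time_s))) |>
    dplyr::arrange(.data$time_s)
}

#' Read / write an annotation log
#'
#' Tab-separated columns `time_s`, `kind`, `note`. Chronological order is
#' enforced on read; unknown kinds are a format error.
#'
#' @param path TSV path.
#' @return [read_annotations()] returns the annotation tibble;
#'   [write_annotations()] returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    time_s = readr::col_double(), kind = readr::col_character(),
    note = readr::col_character()))
  df$note[is.na(df$note)] <- ""
  annotation_log(df$time_s, df$kind, df$note)
}

#' @rdname read_annotations
#' @param log annotation tibble as returned by [annotation_log()].
#' @export
write_annotations <- function(log, path) {
  readr::write_tsv(log, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
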