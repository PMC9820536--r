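#' @keywords internal
"_PACKAGE"

## Canonical metadata vocabularies. Groups follow the transection/ethidium
## bromide design; condition tags the drug-trial arm of a recording.
.groups <- c("TTnoEB", "TTx1EB", "TTx2EB")
.conditions <- c("pre_drug", "post_drug", "none")
.muscles <- c("Sol", "TA")

#' Parse a channel label
#'
#' Channel labels follow the `"Muscle-Side"` convention (`"Sol-L"`, `"TA-R"`).
#' Parsing is case-insensitive; labels that are not a recognised muscle/side
#' pair are kept verbatim with `muscle = "other"`, `side = "none"`.
#'
#' @param label character scalar, e.g. `"Sol-L"`.
#' @return list with `muscle`, `side`, `raw_name`.
#' @export
#' @examples
#' parse_channel("sol-l")
parse_channel <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  m <- regmatches(label, regexec("^([A-Za-z]+)-([LRlr])$", label))[[1]]
  if (length(m) == 3L) {
    muscle <- .muscles[match(tolower(m[2]), tolower(.muscles))]
    if (!is.na(muscle)) {
      return(list(muscle = muscle, side = toupper(m[3]), raw_name = label))
    }
  }
  list(muscle = "other", side = "none", raw_name = label)
}

#' Canonical text form of a channel label
#' @param label character scalar channel label.
#' @return `"Sol-L"`-style string for recognised channels, otherwise the
#'   label unchanged.
#' @export
channel_name <- function(label) {
  p <- parse_channel(label)
  if (p$muscle == "other") p$raw_name else paste0(p$muscle, "-", p$side)
}

#' Construct a multi-channel EMG recording
#'
#' The container used throughout the pipeline: a signal matrix (one column per
#' channel, one row per sample) plus acquisition metadata. Amplitudes are
#' unitless (volt-like); times are seconds.
#'
#' @param signal numeric matrix, samples x channels.
#' @param channels character vector of channel labels (`"Sol-L"` style);
#'   defaults to `colnames(signal)`.
#' @param sampling_rate sampling frequency in Hz (2000 in the reference
#'   acquisition setup).
#' @param animal_id animal identifier.
#' @param group experimental group, one of `"TTnoEB"`, `"TTx1EB"`, `"TTx2EB"`.
#' @param condition drug-trial condition: `"pre_drug"`, `"post_drug"` or
#'   `"none"`.
#' @param belt_speed treadmill belt speed in cm/s.
#' @param t0 time of the first sample in seconds.
#' @return object of class `emg_recording`.
#' @export
emg_recording <- function(signal, channels = colnames(signal), sampling_rate,
                          animal_id, group, condition = "none",
                          belt_speed = 5, t0 = 0) {
  signal <- as.matrix(signal)
  channels <- vapply(as.character(channels), channel_name, character(1),
                     USE.NAMES = FALSE)
  colnames(signal) <- channels
  rec <- structure(
    list(animal_id = as.character(animal_id),
         group = as.character(group),
         condition = as.character(condition),
         belt_speed = as.numeric(belt_speed),
         sampling_rate = as.numeric(sampling_rate),
         channels = channels,
         signal = signal,
         t0 = as.numeric(t0)),
    class = "emg_recording")
  validate_recording(rec)
}

#' Validate an EMG recording
#'
#' Enforces the container invariants: positive sampling rate, unique channel
#' labels, equal-length all-finite channels, known group/condition vocabulary.
#'
#' @param rec an `emg_recording`.
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "emg_recording")) stop("not an emg_recording", call. = FALSE)
  need <- c("animal_id", "group", "condition", "belt_speed", "sampling_rate",
            "channels", "signal", "t0")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("recording format error: missing field(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (f in c("animal_id", "group", "condition")) {
    v <- rec[[f]]
    if (length(v) != 1L || is.na(v) || !nzchar(v))
      stop("recording format error: blank metadata field '", f, "'", call. = FALSE)
  }
  if (!rec$group %in% .groups)
    stop("recording format error: unknown group '", rec$group, "'", call. = FALSE)
  if (!rec$condition %in% .conditions)
    stop("recording format error: unknown condition '", rec$condition, "'",
         call. = FALSE)
  if (!is.finite(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("recording format error: sampling_rate must be > 0", call. = FALSE)
  if (!is.matrix(rec$signal) || nrow(rec$signal) < 1L)
    stop("recording data error: signal must be a matrix with >= 1 sample",
         call. = FALSE)
  if (length(rec$channels) < 1L)
    stop("recording format error: empty channel list", call. = FALSE)
  if (anyDuplicated(rec$channels))
    stop("recording format error: duplicate channel labels", call. = FALSE)
  if (ncol(rec$signal) != length(rec$channels))
    stop("recording format error: signal columns != channel labels", call. = FALSE)
  if (!all(is.finite(rec$signal)))
    stop("recording data error: non-finite sample values", call. = FALSE)
  invisible(rec)
}

#' Recording duration in seconds
#' @param rec an `emg_recording`.
#' @return duration `n_samples / sampling_rate`.
#' @export
rec_duration <- function(rec) nrow(rec$signal) / rec$sampling_rate

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s [%s/%s] %.3g s @ %g Hz, channels: %s\n",
              x$animal_id, x$group, x$condition, rec_duration(x),
              x$sampling_rate, paste(x$channels, collapse = ", ")))
  invisible(x)
}

.stem <- function(path) sub("\\.csv$", "", path)

#' Load an EMG recording from CSV + JSON sidecar
#'
#' Reads the repository's canonical plain-text dialect: `<stem>.csv` holding an
#' optional `time_s` column plus one column per channel, and `<stem>.meta.json`
#' holding the acquisition metadata. A `time_s` column, if present, must be
#' uniform to within 1e-6 s and consistent with the declared sampling rate.
#'
#' @param path path to the `.csv` file (or its stem).
#' @return a validated [emg_recording].
#' @export
load_recording <- function(path) {
  stem <- .stem(path)
  csv <- paste0(stem, ".csv")
  metaf <- paste0(stem, ".meta.json")
  if (!file.exists(csv)) stop("recording I/O error: missing file ", csv, call. = FALSE)
  if (!file.exists(metaf)) stop("recording format error: missing metadata sidecar ",
                                metaf, call. = FALSE)
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  for (f in c("animal_id", "group", "condition", "sampling_rate")) {
    if (is.null(meta[[f]]) || !nzchar(as.character(meta[[f]])[1]))
      stop("recording format error: metadata missing '", f, "'", call. = FALSE)
  }
  dat <- utils::read.csv(csv, check.names = FALSE)
  if (ncol(dat) < 1L || nrow(dat) < 1L)
    stop("recording data error: empty signal table", call. = FALSE)
  t0 <- if (!is.null(meta$t0)) as.numeric(meta$t0) else 0
  if ("time_s" %in% names(dat)) {
    tt <- dat$time_s
    if (anyNA(tt) || !all(is.finite(tt)))
      stop("recording data error: non-finite time values", call. = FALSE)
    if (length(tt) > 1L) {
      dt <- diff(tt)
      if (max(abs(dt - 1 / as.numeric(meta$sampling_rate))) > 1e-6)
        stop("recording data error: time column not uniform at sampling_rate",
             call. = FALSE)
    }
    t0 <- tt[1]
    dat <- dat[, setdiff(names(dat), "time_s"), drop = FALSE]
  }
  sig <- as.matrix(dat)
  storage.mode(sig) <- "double"
  if (anyNA(sig) || !all(is.finite(sig)))
    stop("recording data error: non-finite sample values", call. = FALSE)
  emg_recording(sig, channels = names(dat),
                sampling_rate = as.numeric(meta$sampling_rate),
                animal_id = meta$animal_id, group = meta$group,
                condition = meta$condition,
                belt_speed = if (is.null(meta$belt_speed)) 5 else as.numeric(meta$belt_speed),
                t0 = t0)
}

#' Write an EMG recording to CSV + JSON sidecar
#'
#' Inverse of [load_recording]. Amplitudes are written with 12 significant
#' digits so the round trip reproduces them to at least 9 significant digits.
#'
#' @param rec a validated [emg_recording].
#' @param path target `.csv` path (or stem); the metadata sidecar is written
#'   next to it as `<stem>.meta.json`.
#' @return the csv path, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  stem <- .stem(path)
  csv <- paste0(stem, ".csv")
  dir <- dirname(csv)
  if (!dir.exists(dir)) stop("recording I/O error: no such directory ", dir,
                             call. = FALSE)
  n <- nrow(rec$signal)
  tt <- rec$t0 + (seq_len(n) - 1L) / rec$sampling_rate
  cols <- c(list(time_s = formatC(tt, digits = 12, format = "g")),
            lapply(seq_along(rec$channels), function(j)
              formatC(rec$signal[, j], digits = 12, format = "g")))
  names(cols) <- c("time_s", rec$channels)
  utils::write.csv(as.data.frame(cols, check.names = FALSE), csv,
                   row.names = FALSE, quote = FALSE)
  meta <- list(animal_id = rec$animal_id, group = rec$group,
               condition = rec$condition, belt_speed = rec$belt_speed,
               sampling_rate = rec$sampling_rate, t0 = rec$t0,
               channels = as.list(rec$channels), format_version = "1")
  jsonlite::write_json(meta, paste0(stem, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(csv)
}

#' Write an analysis result table
#'
#' Results are written in two forms: a tidy CSV (`<stem>.results.csv`, one row
#' per measurement) and a JSON summary (`<stem>.results.json`). Accepts the
#' tidy data frames produced by the metrics/coordination/comparison stages, or
#' a list of circular-statistics results (class `circ_stat`), which is
#' flattened to the documented
#' `pairing/reference/test/n/mean_angle_deg/r/cR/rayleigh_p/coordinated`
#' schema.
#'
#' @param results data frame, or list of `circ_stat` objects.
#' @param path output stem (a trailing `.csv`/`.json` is stripped).
#' @return invisible character vector of the two paths written.
#' @export
write_results <- function(results, path) {
  stem <- sub("\\.(csv|json)$", "", path)
  stem <- sub("\\.results$", "", stem)
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "circ_stat"))) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (!is.data.frame(results))
    stop("results usage error: unsupported result type", call. = FALSE)
  csv <- paste0(stem, ".results.csv")
  jsn <- paste0(stem, ".results.json")
  utils::write.csv(results, csv, row.names = FALSE)
  jsonlite::write_json(
    list(n_rows = nrow(results), columns = as.list(names(results)),
         rows = results),
    jsn, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv, jsn))
}
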