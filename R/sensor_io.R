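#' Construct a patient record
#'
#' Bundles one patient's time-ordered sensor readings with the ground-truth
#' activity annotation. Readings are sorted by time on construction; the RF
#' phase is normalized into `[0, 2*pi)`.
#'
#' @param patient_id Character scalar identifier.
#' @param gender `"female"` or `"male"`.
#' @param readings Data frame with columns `t` (seconds since trial start),
#'   `af`, `av`, `al` (acceleration in g along the dorsoventral,
#'   anteroposterior and left-right axes), `rssi` (dBm), `aid` (antenna
#'   identifier, 1-3), `freq` (channel frequency, MHz) and `phase` (RF phase,
#'   radians).
#' @param truth Data frame with columns `start`, `end` (seconds) and `label`
#'   (one of [activity_levels()]); intervals must be non-overlapping.
#'
#' @return An object of class `patient_record`: a list with elements
#'   `patient_id`, `gender`, `readings` and `truth`.
#' @export
patient_record <- function(patient_id, gender, readings, truth = empty_truth()) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  gender <- match.arg(gender, c("female", "male"))
  readings <- as.data.frame(readings)
  need <- canonical_columns()
  miss <- setdiff(need, names(readings))
  if (length(miss) > 0) {
    stop("readings missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  readings <- readings[need]
  if (nrow(readings) > 0) {
    readings <- readings[order(readings$t), , drop = FALSE]
    rownames(readings) <- NULL
    readings$phase <- wrap_phase(readings$phase)
    readings$aid <- as.integer(readings$aid)
  }
  truth <- as.data.frame(truth)
  if (nrow(truth) > 0) {
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    truth$label <- as.character(truth$label)
  }
  structure(
    list(patient_id = patient_id, gender = gender,
         readings = readings, truth = truth),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "<patient_record> %s (%s): %d readings over %.1f s, %d annotated intervals\n",
    x$patient_id, x$gender, nrow(x$readings),
    if (nrow(x$readings) > 0) diff(range(x$readings$t)) else 0,
    nrow(x$truth)
  ))
  invisible(x)
}

canonical_columns <- function() {
  c("t", "af", "av", "al", "rssi", "aid", "freq", "phase")
}

empty_truth <- function() {
  data.frame(start = numeric(0), end = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Canonical column dialect
#'
#' A dialect maps canonical column names onto the column names of a source
#' file, so streams exported by other software can be adapted without
#' rewriting them. The identity dialect reads the canonical layout
#' `t,af,av,al,rssi,aid,freq,phase`.
#'
#' @param columns Named character vector; names are canonical column names,
#'   values are the corresponding source-file column names.
#' @param time_origin Optional numeric offset subtracted from the source time
#'   column, so `t` is seconds relative to trial start.
#'
#' @return A list of class `stream_dialect`.
#' @export
stream_dialect <- function(columns = NULL, time_origin = NULL) {
  cols <- stats::setNames(canonical_columns(), canonical_columns())
  if (!is.null(columns)) {
    stopifnot(all(names(columns) %in% canonical_columns()))
    cols[names(columns)] <- columns
  }
  structure(list(columns = cols, time_origin = time_origin),
            class = "stream_dialect")
}

#' Read a patient sensor stream from disk
#'
#' Reads the canonical triplet written by [write_patient_stream()]: a readings
#' CSV, a `*_truth.csv` annotation sidecar and a `*.json` manifest carrying
#' `patient_id` and `gender`. Rows violating the reading invariants
#' (non-finite time or acceleration, negative time, antenna id outside 1-3)
#' are dropped with a warning; more than 10% dropped rows is an error.
#'
#' @param path Path to the readings CSV.
#' @param dialect A [stream_dialect()] describing the source columns.
#'
#' @return A [patient_record()] with attributes `n_parsed` (rows read) and
#'   `n_dropped` (rows discarded by validation).
#' @export
read_patient_stream <- function(path, dialect = stream_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- dialect$columns
  miss <- cols[!cols %in% names(raw)]
  if (length(miss) > 0) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  }
  readings <- stats::setNames(raw[unname(cols)], names(cols))
  for (nm in canonical_columns()) readings[[nm]] <- as.numeric(readings[[nm]])
  if (!is.null(dialect$time_origin)) {
    readings$t <- readings$t - dialect$time_origin
  }

  n_parsed <- nrow(readings)
  bad <- !is.finite(readings$t) | readings$t < 0 |
    !is.finite(readings$af) | !is.finite(readings$av) | !is.finite(readings$al) |
    is.na(readings$aid) | !(readings$aid %in% c(1, 2, 3))
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d invalid row(s) of %d in %s",
                    n_dropped, n_parsed, basename(path)))
    if (n_dropped > 0.1 * n_parsed) {
      stop(sprintf("more than 10%% of rows invalid in %s (%d of %d)",
                   basename(path), n_dropped, n_parsed))
    }
    readings <- readings[!bad, , drop = FALSE]
  }

  truth_path <- sidecar_path(path, "truth")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else {
    empty_truth()
  }
  manifest_path <- sidecar_path(path, "manifest")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    pid <- man$patient_id
    gender <- man$gender
  } else {
    pid <- sub("\\.csv$", "", basename(path))
    gender <- "female"
  }
  rec <- patient_record(pid, gender, readings, truth)
  attr(rec, "n_parsed") <- n_parsed
  attr(rec, "n_dropped") <- n_dropped
  rec
}

sidecar_path <- function(path, kind) {
  stem <- sub("\\.csv$", "", path)
  switch(kind,
         truth = paste0(stem, "_truth.csv"),
         manifest = paste0(stem, ".json"))
}

#' Write a patient record to disk in canonical form
#'
#' Writes `<patient_id>.csv` (readings), `<patient_id>_truth.csv`
#' (annotations) and `<patient_id>.json` (manifest) into `dir`. Numeric
#' fields are serialized with 17 significant digits so that
#' `read_patient_stream()` recovers the record exactly.
#'
#' @param record A [patient_record()].
#' @param dir Output directory (created if absent).
#'
#' @return Invisibly, the path of the readings CSV.
#' @export
write_patient_stream <- function(record, dir) {
  stopifnot(inherits(record, "patient_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(record$patient_id, ".csv"))
  df <- record$readings
  out <- data.frame(
    t = fmt_num(df$t), af = fmt_num(df$af), av = fmt_num(df$av),
    al = fmt_num(df$al), rssi = fmt_num(df$rssi), aid = df$aid,
    freq = fmt_num(df$freq), phase = fmt_num(wrap_phase(df$phase)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  tr <- record$truth
  utils::write.csv(
    data.frame(start = fmt_num(tr$start), end = fmt_num(tr$end),
               label = tr$label, stringsAsFactors = FALSE),
    sidecar_path(path, "truth"), row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(patient_id = record$patient_id, gender = record$gender),
    sidecar_path(path, "manifest"), auto_unbox = TRUE
  )
  invisible(path)
}

# %.17g round-trips IEEE doubles exactly
fmt_num <- function(x) {
  if (length(x) == 0) return(character(0))
  sprintf("%.17g", x)
}

#' Validate a patient record
#'
#' Checks every type invariant of the stream model and reports violations
#' rather than failing: time ordering and finiteness, antenna ids, phase
#' range, acceleration finiteness, annotation interval ordering and overlap,
#' and the mean read rate (a passive backscatter sensor cannot exceed 20
#' reads per second; a higher rate indicates a malformed or unrealistic
#' stream).
#'
#' @param record A [patient_record()].
#'
#' @return A list of class `stream_report` with elements `violations`
#'   (character vector, empty iff the record is valid), `mean_rate` (reads
#'   per second over the observed span) and `rate_flag` (`TRUE` if the mean
#'   rate exceeds 20 reads/s).
#' @export
validate_stream <- function(record) {
  v <- character(0)
  df <- record$readings
  if (nrow(df) > 0) {
    if (any(!is.finite(df$t))) v <- c(v, "non-finite reading timestamps")
    if (any(df$t < 0, na.rm = TRUE)) v <- c(v, "negative reading timestamps")
    if (is.unsorted(df$t, na.rm = TRUE)) v <- c(v, "readings not sorted by time")
    if (any(!df$aid %in% c(1L, 2L, 3L))) {
      v <- c(v, "antenna id outside {1,2,3}")
    }
    if (any(df$phase < 0 | df$phase >= 2 * pi, na.rm = TRUE)) {
      v <- c(v, "phase outside [0, 2*pi)")
    }
    if (any(!is.finite(df$af) | !is.finite(df$av) | !is.finite(df$al))) {
      v <- c(v, "non-finite acceleration values")
    }
  }
  tr <- record$truth
  if (nrow(tr) > 0) {
    if (any(tr$start >= tr$end)) v <- c(v, "annotation interval with start >= end")
    if (any(!tr$label %in% activity_levels())) {
      v <- c(v, "annotation label outside the activity set")
    }
    if (nrow(tr) > 1) {
      for (i in seq_len(nrow(tr) - 1)) {
        if (tr$end[i] > tr$start[i + 1]) {
          v <- c(v, sprintf("overlapping annotation intervals %d and %d", i, i + 1))
        }
      }
    }
  }
  span <- if (nrow(df) > 1) diff(range(df$t, finite = TRUE)) else 0
  mean_rate <- if (is.finite(span) && span > 0) nrow(df) / span else 0
  rate_flag <- mean_rate > 20
  if (rate_flag) {
    v <- c(v, sprintf("mean read rate %.1f/s exceeds 20 reads/s", mean_rate))
  }
  structure(list(violations = v, mean_rate = mean_rate, rate_flag = rate_flag),
            class = "stream_report")
}

#' @export
print.stream_report <- function(x, ...) {
  if (length(x$violations) == 0) {
    cat(sprintf("<stream_report> valid; mean read rate %.2f/s\n", x$mean_rate))
  } else {
    cat("<stream_report>", length(x$violations), "violation(s):\n")
    for (v in x$violations) cat(" -", v, "\n")
  }
  invisible(x)
}
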