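#' Alarm configuration
#'
#' @param T Score-window length in seconds; must lie in `[0.1, 5]` (the
#'   upper bound is more than double the minimum posture-transition time, so
#'   a complete transfer fits in one window). The deployed value in the
#'   hospital evaluation was 4.8 s.
#' @param refractory Seconds after an alarm during which further alarms are
#'   suppressed; 1.75 s is the minimum time a posture transition takes, so a
#'   second genuine exit cannot occur sooner.
#'
#' @return List of class `alarm_config`.
#' @export
alarm_config <- function(T = 4.8, refractory = 1.75) {
  stopifnot(T >= 0.1, T <= 5, refractory > 0)
  structure(list(T = T, refractory = refractory), class = "alarm_config")
}

#' Windowed score-function smoothing of class probabilities
#'
#' Partitions the trial into consecutive non-overlapping windows of length
#' `T`, anchored at the first reading, and sums the calibrated class
#' probabilities of the readings inside each window. The class with the
#' highest sum is the window's dominant activity; single misclassified
#' readings are thereby outvoted, which is what suppresses spurious alarms.
#' A tie is resolved by retaining the previous window's dominant class
#' (`Lying` for the first window); windows containing no readings emit no
#' decision.
#'
#' @param probs Data frame from [probs_frame()]: a `t` column and one
#'   probability column per class, rows in time order.
#' @param cfg An [alarm_config()].
#'
#' @return Data frame of class decisions: `window_start`, `window_end`,
#'   `dominant`, `n` and the per-class score sums.
#' @export
score_windows <- function(probs, cfg = alarm_config()) {
  classes <- setdiff(names(probs), "t")
  if (nrow(probs) == 0) {
    return(data.frame(window_start = numeric(0), window_end = numeric(0),
                      dominant = character(0), n = integer(0)))
  }
  t <- probs$t
  stopifnot(!is.unsorted(t))
  anchor <- t[1]
  win <- floor((t - anchor) / cfg$T) + 1L  # half-open [start, end)
  sums <- rowsum(as.matrix(probs[classes]), win)
  counts <- as.integer(table(win))
  win_ids <- as.integer(rownames(sums))

  dominant <- character(nrow(sums))
  prev <- "Lying"
  for (j in seq_len(nrow(sums))) {
    s <- sums[j, ]
    top <- which(s == max(s))
    dominant[j] <- if (length(top) > 1) prev else classes[top]
    prev <- dominant[j]
  }
  out <- data.frame(
    window_start = anchor + (win_ids - 1L) * cfg$T,
    window_end = anchor + win_ids * cfg$T,
    dominant = dominant,
    n = counts,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(sums, optional = TRUE))
}

#' Bed/chair-exit state machine over window decisions
#'
#' Walks the sequence of dominant window labels and emits alarms at posture
#' transitions of interest: a bed exit when `Lying` is followed by
#' `Sitting-on-bed` or `Ambulating` (patients sit with legs off the bed when
#' intending to get up, so sitting on the bed after lying already signals an
#' exit), and a chair exit when `Sitting-on-chair` is followed by any other
#' label. The alarm timestamp is the start of the window completing the
#' transition. Any alarm within the refractory period (1.75 s) of the
#' previous alarm is suppressed, since a second posture transition cannot
#' physically occur that fast. No alarm can fire on the first decision.
#'
#' @param decisions Data frame from [score_windows()] (time-ordered).
#' @param cfg An [alarm_config()].
#'
#' @return Data frame of alarms with columns `time` (seconds) and `type`
#'   (`"bed-exit"` or `"chair-exit"`).
#' @export
detect_exits <- function(decisions, cfg = alarm_config()) {
  empty <- data.frame(time = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  n <- nrow(decisions)
  if (n < 2) return(empty)
  lab <- decisions$dominant
  tw <- decisions$window_start
  times <- numeric(0)
  types <- character(0)
  last_alarm <- -Inf
  state <- lab[1]
  for (k in 2:n) {
    cur <- lab[k]
    type <- NULL
    if (state == "Lying" && cur %in% c("Sitting-on-bed", "Ambulating")) {
      type <- "bed-exit"
    } else if (state == "Sitting-on-chair" && cur != "Sitting-on-chair") {
      type <- "chair-exit"
    }
    if (!is.null(type) && (tw[k] - last_alarm) >= cfg$refractory) {
      times <- c(times, tw[k])
      types <- c(types, type)
      last_alarm <- tw[k]
    }
    state <- cur
  }
  data.frame(time = times, type = types, stringsAsFactors = FALSE)
}
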