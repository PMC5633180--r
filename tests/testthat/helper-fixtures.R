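# small in-code fixtures shared across test files

# minimal well-formed readings frame
toy_readings <- function(n = 3, t = seq_len(n) - 1) {
  data.frame(
    t = t,
    af = rep(0.1, n), av = rep(0.95, n), al = rep(0, n),
    rssi = rep(-55, n), aid = rep(2L, n),
    freq = rep(922.25, n), phase = rep(1, n)
  )
}

toy_record <- function(n = 3, ...) {
  patient_record("toy", "female", toy_readings(n, ...),
                 data.frame(start = 0, end = max(n, 2),
                            label = "Lying"))
}

# a segment built directly from vectors, for feature-level tests
make_segment <- function(t, af = 0, av = 0, al = 0, rssi = -50,
                         aid = 2L, freq = 922.25, phase = 0) {
  n <- length(t)
  df <- data.frame(
    t = t,
    af = rep_len(af, n), av = rep_len(av, n), al = rep_len(al, n),
    rssi = rep_len(rssi, n), aid = as.integer(rep_len(aid, n)),
    freq = rep_len(freq, n), phase = rep_len(phase, n)
  )
  rec <- patient_record("seg", "female", df)
  build_segment(rec, n, feature_config(T_seg = diff(range(t)) + 1))
}

# window-decision frame from a plain label sequence (windows of length T)
decisions_from_labels <- function(labels, T = 4.8, anchor = 0) {
  k <- length(labels)
  data.frame(
    window_start = anchor + (seq_len(k) - 1) * T,
    window_end = anchor + seq_len(k) * T,
    dominant = labels,
    n = rep(1L, k),
    stringsAsFactors = FALSE
  )
}

# independent restatement of the exit rules, for fuzz oracles
exit_alarm_oracle <- function(labels, times, refractory = 1.75) {
  out_t <- numeric(0)
  out_ty <- character(0)
  last <- -Inf
  if (length(labels) < 2) {
    return(data.frame(time = out_t, type = out_ty))
  }
  for (k in 2:length(labels)) {
    a <- labels[k - 1]
    b <- labels[k]
    ty <- NA_character_
    if (a == "Lying" && (b == "Sitting-on-bed" || b == "Ambulating")) {
      ty <- "bed-exit"
    }
    if (a == "Sitting-on-chair" && b != "Sitting-on-chair") {
      ty <- "chair-exit"
    }
    if (!is.na(ty) && times[k] - last >= refractory) {
      out_t <- c(out_t, times[k])
      out_ty <- c(out_ty, ty)
      last <- times[k]
    }
  }
  data.frame(time = out_t, type = out_ty, stringsAsFactors = FALSE)
}

# separable 2-class toy set in 2-D
toy_two_class <- function(n = 20, gap = 3, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), ncol = 2) + gap,
             matrix(rnorm(2 * n), ncol = 2) - gap)
  y <- rep(c("pos", "neg"), each = n)
  list(X = X, y = y)
}
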