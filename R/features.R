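#' Feature-extraction configuration
#'
#' Controls segment length, antenna roles and the feature mask. The default
#' mask keeps the features retained by the upstream feature-selection step
#' (logistic-regression / Bayes-network ranking): everything except lateral
#' acceleration, the inter-reading time difference, the raw antenna id and
#' the maximum-RSSI antenna. All features are always computed; the mask is
#' applied when building the numeric design matrix, so unmasked values remain
#' available for diagnostics.
#'
#' @param T_seg Contextual segment length in seconds (default 4).
#' @param mask Character vector of feature column names to keep, or `NULL`
#'   for the default mask ([default_feature_mask()]).
#' @param bed_antennas Antenna ids illuminating the bed (default `c(2, 3)`,
#'   ceiling-mounted above the bed).
#' @param chair_antenna Antenna id facing the chair (default `1`).
#' @param cfpr_ant2 Summary used for the antenna-2 constant-frequency phase
#'   rate: `"abs_sum"` (sum of absolute values, default) or `"abs_median"`
#'   (median of absolute values).
#' @param demean_displacement Subtract the segment mean of the anteroposterior
#'   acceleration before double integration, removing the quasi-static
#'   gravity projection (default `TRUE`).
#' @param rssi_linear Convert RSSI from dBm to linear milliwatt power before
#'   computing RSSI features (default `FALSE`, i.e. work in dBm).
#'
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(T_seg = 4, mask = NULL,
                           bed_antennas = c(2L, 3L), chair_antenna = 1L,
                           cfpr_ant2 = c("abs_sum", "abs_median"),
                           demean_displacement = TRUE,
                           rssi_linear = FALSE) {
  stopifnot(T_seg > 0)
  cfpr_ant2 <- match.arg(cfpr_ant2)
  roles <- sort(c(bed_antennas, chair_antenna))
  if (!identical(as.integer(roles), 1:3)) {
    stop("antenna roles must partition {1,2,3}")
  }
  if (is.null(mask)) mask <- default_feature_mask()
  unknown <- setdiff(mask, feature_names())
  if (length(unknown) > 0) {
    stop("unknown feature name(s) in mask: ", paste(unknown, collapse = ", "))
  }
  structure(list(T_seg = T_seg, mask = mask,
                 bed_antennas = as.integer(bed_antennas),
                 chair_antenna = as.integer(chair_antenna),
                 cfpr_ant2 = cfpr_ant2,
                 demean_displacement = demean_displacement,
                 rssi_linear = rssi_linear),
            class = "feature_config")
}

#' Names of all computed feature columns
#'
#' Eleven instantaneous features followed by the contextual segment features.
#'
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c(
    # instantaneous
    "af", "av", "al", "tilt_sine", "rssi", "accel_mag", "dt", "gender",
    "yaw", "roll", "aid",
    # contextual (4 s segment)
    "n_ant2", "argmax_rssi_ant", "argmin_rssi_ant", "vert_disp",
    "m_bed_chair", "pearson_r",
    "rssi_mean_ant1", "rssi_sd_ant1", "rssi_mean_ant3", "rssi_sd_ant3",
    "cfpr_median_ant1", "cfpr_median_ant3", "cfpr_abssum_ant2",
    "cfpr_sd_ant2", "cfpr_sd_ant3", "vfpr_sd_ant3",
    "mean_av", "mean_af", "mean_al", "sd_al"
  )
}

#' Default (selected) feature mask
#'
#' The features retained after upstream feature selection: all computed
#' features except lateral acceleration (`al`), the inter-reading time
#' difference (`dt`), the raw antenna id (`aid`) and the maximum-RSSI antenna
#' (`argmax_rssi_ant`).
#'
#' @return Character vector of selected feature column names.
#' @export
default_feature_mask <- function() {
  setdiff(feature_names(), c("al", "dt", "aid", "argmax_rssi_ant"))
}

#' Sine of the body tilting angle (pitch)
#'
#' Trunk pitch towards the front or back with respect to the vertical in the
#' midsagittal plane, approximated from the gravity projections as
#' `sin(arctan(af / av))` with a quadrant-correct two-argument arctangent.
#' The undefined orientation `af = av = 0` returns 0 and is flagged.
#'
#' @param af,av Dorsoventral and anteroposterior acceleration in g
#'   (vectorized).
#'
#' @return Numeric vector in `[-1, 1]` with attribute `flag` marking
#'   undefined-orientation entries.
#' @export
tilt_sine <- function(af, av) {
  flag <- af == 0 & av == 0
  out <- sin(atan2(af, av))
  out[flag] <- 0
  attr(out, "flag") <- flag
  out
}

#' Trunk yaw and roll angles
#'
#' Yaw `beta = arctan(al / af)` (rotation from the dorsoventral axis) and
#' roll `alpha = arctan(al / av)` (tilting in the coronal plane), both
#' approximated from gravity projections. A zero denominator yields
#' `+/- pi/2` by the sign of the numerator; `0 / 0` yields 0 and is flagged.
#'
#' @param af,av,al Acceleration in g along the dorsoventral, anteroposterior
#'   and left-right axes (vectorized).
#'
#' @return List with numeric vectors `yaw` and `roll` (radians), each with a
#'   `flag` attribute marking undefined entries.
#' @export
trunk_angles <- function(af, av, al) {
  ratio_angle <- function(num, den) {
    flag <- num == 0 & den == 0
    out <- ifelse(den == 0, sign(num) * pi / 2, atan(num / den))
    out[flag] <- 0
    attr(out, "flag") <- flag
    out
  }
  list(yaw = ratio_angle(al, af), roll = ratio_angle(al, av))
}

#' Resultant acceleration magnitude
#'
#' @param af,av,al Acceleration components in g (vectorized).
#' @return `sqrt(af^2 + av^2 + al^2)`, in g.
#' @export
resultant_accel <- function(af, av, al) {
  sqrt(af^2 + av^2 + al^2)
}

#' Build the contextual segment anchored at one reading
#'
#' The segment contains every reading with timestamp in the closed interval
#' `[t_i - T_seg, t_i]`, where `t_i` is the anchor reading's timestamp; the
#' anchor is always included, so `n >= 1`.
#'
#' @param record A [patient_record()].
#' @param i Anchor reading index (1-based).
#' @param cfg A [feature_config()].
#'
#' @return List of class `segment` with elements `anchor_t`, `T_seg`,
#'   `readings` (data frame) and `n`.
#' @export
build_segment <- function(record, i, cfg = feature_config()) {
  df <- record$readings
  stopifnot(i >= 1, i <= nrow(df))
  ti <- df$t[i]
  lo <- findInterval(ti - cfg$T_seg, df$t, left.open = TRUE) + 1L
  idx <- lo:i
  new_segment(ti, cfg$T_seg, df[idx, , drop = FALSE])
}

new_segment <- function(anchor_t, T_seg, readings) {
  structure(list(anchor_t = anchor_t, T_seg = T_seg,
                 readings = readings, n = nrow(readings)),
            class = "segment")
}

#' Cumulative vertical displacement over a segment
#'
#' Double time-integration of the anteroposterior (sensor-vertical) axis
#' acceleration over the segment, trapezoidal on the irregular timestamps,
#' with g converted to m/s^2. By default the segment mean of `av` is
#' subtracted first, removing the quasi-static gravity projection so the
#' integral reflects movement rather than posture.
#'
#' @param seg A [build_segment()] result.
#' @param demean Subtract the segment mean of `av` first (default taken from
#'   typical configuration, `TRUE`).
#'
#' @return Displacement in metres; 0 with attribute `flag = TRUE` when the
#'   segment holds fewer than two readings.
#' @export
vertical_displacement <- function(seg, demean = TRUE) {
  if (seg$n < 2) return(structure(0, flag = TRUE))
  t <- seg$readings$t
  a <- seg$readings$av
  if (demean) a <- a - mean(a)
  a <- a * 9.80665
  v <- pracma::cumtrapz(t, a)
  d <- pracma::trapz(t, as.numeric(v))
  structure(d, flag = FALSE)
}

#' Bed-chair mutual information of a segment
#'
#' Fraction (out of segment size `n`) of consecutive reading pairs whose
#' antennas span the bed and chair areas: qualifying unordered pairs are
#' `{bed antenna, chair antenna}` in either order, i.e. with the default
#' geometry `{3, 1}` and `{2, 1}`. Captures movement events between the two
#' monitored areas.
#'
#' @param seg A [build_segment()] result.
#' @param cfg A [feature_config()] (for the antenna role map).
#'
#' @return Value in `[0, (n - 1) / n]`.
#' @export
mutual_info_bed_chair <- function(seg, cfg = feature_config()) {
  a <- seg$readings$aid
  n <- seg$n
  if (n < 2) return(0)
  prev <- a[-n]
  nxt <- a[-1]
  qual <- (prev %in% cfg$bed_antennas & nxt == cfg$chair_antenna) |
    (prev == cfg$chair_antenna & nxt %in% cfg$bed_antennas)
  sum(qual) / n
}

#' Constant- and variable-frequency phase-rate summaries of a segment
#'
#' The constant-frequency phase rate (CFPR) is the first difference of RF
#' phase across successive readings of one antenna at the same channel
#' frequency; the variable-frequency phase rate (VFPR) divides the phase
#' difference of successive same-antenna readings by their frequency
#' difference (pairs at equal frequency are skipped). Phase differences are
#' wrapped into `(-pi, pi]` before summarizing, since reader phase is
#' modular. Summaries follow the deployed antenna roles: CFPR median for
#' antennas 1 and 3, sum of absolute CFPR for antenna 2, CFPR standard
#' deviation for antennas 2 and 3, and VFPR standard deviation for antenna 3.
#' Empty summary sets yield 0 and are flagged.
#'
#' @param seg A [build_segment()] result.
#' @param cfg A [feature_config()].
#'
#' @return Named list with elements `cfpr_median_ant1`, `cfpr_median_ant3`,
#'   `cfpr_abssum_ant2`, `cfpr_sd_ant2`, `cfpr_sd_ant3`, `vfpr_sd_ant3` and a
#'   logical vector `flag` marking which summaries had no data.
#' @export
phase_rate_features <- function(seg, cfg = feature_config()) {
  df <- seg$readings
  cfpr_by_ant <- lapply(1:3, function(a) {
    sub <- df[df$aid == a, , drop = FALSE]
    if (nrow(sub) < 2) return(numeric(0))
    same_f <- sub$freq[-1] == sub$freq[-nrow(sub)]
    wrap_pi(diff(sub$phase))[same_f]
  })
  vfpr_ant3 <- {
    sub <- df[df$aid == 3L, , drop = FALSE]
    if (nrow(sub) < 2) numeric(0) else {
      dfreq <- diff(sub$freq)
      keep <- dfreq != 0
      (wrap_pi(diff(sub$phase)) / dfreq)[keep]
    }
  }
  or0 <- function(x, f) if (length(x) == 0 || all(is.na(x))) 0 else f(x)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  abs2 <- if (cfg$cfpr_ant2 == "abs_sum") {
    or0(cfpr_by_ant[[2]], function(x) sum(abs(x)))
  } else {
    or0(cfpr_by_ant[[2]], function(x) stats::median(abs(x)))
  }
  out <- list(
    cfpr_median_ant1 = or0(cfpr_by_ant[[1]], stats::median),
    cfpr_median_ant3 = or0(cfpr_by_ant[[3]], stats::median),
    cfpr_abssum_ant2 = abs2,
    cfpr_sd_ant2 = sd0(cfpr_by_ant[[2]]),
    cfpr_sd_ant3 = sd0(cfpr_by_ant[[3]]),
    vfpr_sd_ant3 = sd0(vfpr_ant3)
  )
  out$flag <- c(
    cfpr_ant1 = length(cfpr_by_ant[[1]]) == 0,
    cfpr_ant2 = length(cfpr_by_ant[[2]]) == 0,
    cfpr_ant3 = length(cfpr_by_ant[[3]]) == 0,
    vfpr_ant3 = length(vfpr_ant3) == 0
  )
  out
}

#' RSSI and acceleration summary statistics of a segment
#'
#' Per-antenna reading count (antenna 2), antennas of minimum and maximum
#' RSSI, mean/standard deviation of RSSI for antennas 1 and 3, Pearson
#' correlation between the anteroposterior and dorsoventral accelerations
#' (sample standard deviation, `n - 1` denominator), per-axis acceleration
#' means and the lateral acceleration standard deviation. Statistics over
#' empty subsets and correlations with zero variance yield 0 and are flagged.
#'
#' @param seg A [build_segment()] result.
#' @param cfg A [feature_config()].
#'
#' @return Named list of summary entries plus a logical `flag` vector.
#' @export
rssi_and_accel_stats <- function(seg, cfg = feature_config()) {
  df <- seg$readings
  rssi <- if (cfg$rssi_linear) 10^(df$rssi / 10) else df$rssi
  flags <- c(ant1 = FALSE, ant3 = FALSE, pearson = FALSE)
  stat_ant <- function(a) {
    x <- rssi[df$aid == a]
    if (length(x) == 0) {
      c(mean = 0, sd = 0)
    } else {
      c(mean = mean(x), sd = if (length(x) < 2) 0 else stats::sd(x))
    }
  }
  s1 <- stat_ant(1L); flags["ant1"] <- !any(df$aid == 1L)
  s3 <- stat_ant(3L); flags["ant3"] <- !any(df$aid == 3L)
  r <- 0
  if (seg$n >= 2 && stats::sd(df$av) > 0 && stats::sd(df$af) > 0) {
    r <- stats::cor(df$av, df$af)
  } else {
    flags["pearson"] <- TRUE
  }
  list(
    n_ant2 = sum(df$aid == 2L),
    argmax_rssi_ant = df$aid[which.max(rssi)],
    argmin_rssi_ant = df$aid[which.min(rssi)],
    rssi_mean_ant1 = unname(s1["mean"]), rssi_sd_ant1 = unname(s1["sd"]),
    rssi_mean_ant3 = unname(s3["mean"]), rssi_sd_ant3 = unname(s3["sd"]),
    pearson_r = r,
    mean_av = mean(df$av), mean_af = mean(df$af), mean_al = mean(df$al),
    sd_al = if (seg$n < 2) 0 else stats::sd(df$al),
    flag = flags
  )
}

#' Extract the full feature matrix for a patient record
#'
#' Computes every instantaneous and contextual feature for each reading, in
#' time order. The inter-reading time difference of the first reading is 0;
#' gender is encoded female = 0, male = 1. The feature mask of `cfg` is not
#' applied here (all columns are returned for diagnostics); use
#' [feature_matrix()] to obtain the masked numeric design matrix.
#'
#' @param record A [patient_record()].
#' @param cfg A [feature_config()].
#'
#' @return Data frame with one row per reading and columns [feature_names()],
#'   plus a `t` column of reading timestamps; carries `cfg` as an attribute.
#' @export
extract_features <- function(record, cfg = feature_config()) {
  df <- record$readings
  n <- nrow(df)
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(feature_names()) + 1,
                                dimnames = list(NULL, c("t", feature_names()))))
    attr(out, "cfg") <- cfg
    return(out)
  }
  ang <- trunk_angles(df$af, df$av, df$al)
  inst <- data.frame(
    t = df$t,
    af = df$af, av = df$av, al = df$al,
    tilt_sine = as.numeric(tilt_sine(df$af, df$av)),
    rssi = if (cfg$rssi_linear) 10^(df$rssi / 10) else df$rssi,
    accel_mag = resultant_accel(df$af, df$av, df$al),
    dt = c(0, diff(df$t)),
    gender = if (record$gender == "male") 1 else 0,
    yaw = as.numeric(ang$yaw), roll = as.numeric(ang$roll),
    aid = as.numeric(df$aid)
  )
  ctx_names <- setdiff(feature_names(), names(inst))
  ctx <- matrix(0, n, length(ctx_names), dimnames = list(NULL, ctx_names))
  lo_all <- findInterval(df$t - cfg$T_seg, df$t, left.open = TRUE) + 1L
  for (i in seq_len(n)) {
    seg <- new_segment(df$t[i], cfg$T_seg, df[lo_all[i]:i, , drop = FALSE])
    pr <- phase_rate_features(seg, cfg)
    st <- rssi_and_accel_stats(seg, cfg)
    ctx[i, ] <- c(
      n_ant2 = st$n_ant2,
      argmax_rssi_ant = st$argmax_rssi_ant,
      argmin_rssi_ant = st$argmin_rssi_ant,
      vert_disp = as.numeric(vertical_displacement(seg, cfg$demean_displacement)),
      m_bed_chair = mutual_info_bed_chair(seg, cfg),
      pearson_r = st$pearson_r,
      rssi_mean_ant1 = st$rssi_mean_ant1, rssi_sd_ant1 = st$rssi_sd_ant1,
      rssi_mean_ant3 = st$rssi_mean_ant3, rssi_sd_ant3 = st$rssi_sd_ant3,
      cfpr_median_ant1 = pr$cfpr_median_ant1,
      cfpr_median_ant3 = pr$cfpr_median_ant3,
      cfpr_abssum_ant2 = pr$cfpr_abssum_ant2,
      cfpr_sd_ant2 = pr$cfpr_sd_ant2, cfpr_sd_ant3 = pr$cfpr_sd_ant3,
      vfpr_sd_ant3 = pr$vfpr_sd_ant3,
      mean_av = st$mean_av, mean_af = st$mean_af, mean_al = st$mean_al,
      sd_al = st$sd_al
    )[ctx_names]
  }
  out <- cbind(inst, as.data.frame(ctx))
  attr(out, "cfg") <- cfg
  out
}

#' Masked numeric design matrix from extracted features
#'
#' Applies the feature mask of `cfg` and drops the timestamp column,
#' producing the matrix consumed by the classifier.
#'
#' @param features Result of [extract_features()].
#' @param cfg A [feature_config()]; defaults to the configuration carried by
#'   `features`.
#'
#' @return Numeric matrix with `length(cfg$mask)` columns.
#' @export
feature_matrix <- function(features, cfg = attr(features, "cfg")) {
  if (is.null(cfg)) cfg <- feature_config()
  as.matrix(features[, cfg$mask, drop = FALSE])
}

#' Per-reading activity labels from ground-truth intervals
#'
#' Labels each reading timestamp with the annotation interval covering it
#' (`start <= t < end`; the final interval is closed at its end). Readings
#' outside every interval get `NA`.
#'
#' @param record A [patient_record()].
#'
#' @return Character vector of labels, one per reading.
#' @export
label_readings <- function(record) {
  tr <- record$truth
  t <- record$readings$t
  lab <- rep(NA_character_, length(t))
  if (nrow(tr) == 0) return(lab)
  for (k in seq_len(nrow(tr))) {
    hit <- t >= tr$start[k] &
      (t < tr$end[k] | (k == nrow(tr) & t <= tr$end[k]))
    lab[hit] <- tr$label[k]
  }
  lab
}
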