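#' Three-antenna ward room geometry
#'
#' Default layout mirroring the deployed room: two reader antennas at
#' ceiling level above the bed (ids 2 and 3, boresight down) and one wall
#' antenna opposite the chair, inclined towards it (id 1). Coordinates are
#' metres; exact values are a documented invention consistent with the
#' approximate room dimensions.
#'
#' @param positions 3x3 matrix of antenna positions (rows = antennas 1-3).
#' @param waypoints Named list of 3-vectors for the sensor (sternum)
#'   position during each scripted activity: `bed_lying`, `bed_sit`,
#'   `chair`, `door`.
#'
#' @return List of class `antenna_geometry` with per-antenna positions,
#'   boresight unit vectors and roles (`"chair"`, `"bed"`, `"bed"`).
#' @export
antenna_geometry <- function(positions = NULL, waypoints = NULL) {
  if (is.null(waypoints)) {
    waypoints <- list(
      bed_lying = c(1.2, 1.0, 0.85),
      bed_sit   = c(1.2, 1.6, 0.95),
      chair     = c(2.4, 1.9, 0.95),
      door      = c(3.6, 0.3, 1.25)
    )
  }
  if (is.null(positions)) {
    positions <- rbind(
      c(2.4, 3.4, 1.6),  # antenna 1: wall opposite the chair
      c(0.8, 1.0, 2.7),  # antenna 2: ceiling, over bed
      c(1.6, 1.0, 2.7)   # antenna 3: ceiling, over bed
    )
  }
  unitize <- function(v) v / sqrt(sum(v^2))
  boresight <- rbind(
    unitize(waypoints$chair - positions[1, ]),
    c(0, 0, -1),
    c(0, 0, -1)
  )
  structure(list(positions = positions, boresight = boresight,
                 roles = c("chair", "bed", "bed"), waypoints = waypoints),
            class = "antenna_geometry")
}

#' Scripted activities-of-daily-living trial
#'
#' The supervised script performed by each patient, repeated
#' `repetitions` times: walk to the chair, sit on the chair, get off the
#' chair and walk to the bed, lie on the bed, sit up with legs off the bed,
#' walk to the door. Each repetition therefore contains exactly one chair
#' exit (`Sitting-on-chair -> Ambulating`) and one bed exit
#' (`Lying -> Sitting-on-bed`).
#'
#' @param repetitions Number of script repetitions (2 or 3 in the trials).
#' @param durations Named numeric vector of per-activity durations in
#'   seconds: `ambulating` (each walking leg), `chair`, `lying`, `bed_sit`.
#'
#' @return Data frame of class `trial_script` with columns `label`,
#'   `duration`, `waypoint`.
#' @export
trial_script <- function(repetitions = 2,
                         durations = c(ambulating = 10, chair = 35,
                                       lying = 60, bed_sit = 15)) {
  stopifnot(repetitions >= 1, all(durations > 0))
  one <- data.frame(
    label = c("Ambulating", "Sitting-on-chair", "Ambulating", "Lying",
              "Sitting-on-bed", "Ambulating"),
    duration = unname(durations[c("ambulating", "chair", "ambulating",
                                  "lying", "bed_sit", "ambulating")]),
    waypoint = c("chair", "chair", "bed_lying", "bed_lying", "bed_sit",
                 "door"),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, replicate(repetitions, one, simplify = FALSE))
  rownames(out) <- NULL
  class(out) <- c("trial_script", "data.frame")
  out
}

#' Simulator configuration
#'
#' Defaults emulate the statistical structure reported for the hospital
#' streams: a mean read rate well under the 20 reads/s cap of the passive
#' sensor, and class-dependent sparsity targeting the observed shares of
#' sensor observations (lying about 56%, sitting on the chair about 22%,
#' ambulating about 9%, the remainder sitting on the bed) given the default
#' script durations. Posture transitions take between 1.75 and 5 s.
#'
#' @param read_rates Named reads-per-second rate for each activity.
#' @param accel_sd,rssi_sd,phase_sd Gaussian noise SDs (g, dB, radians).
#' @param transition_range Range (seconds) from which each posture
#'   transition's duration is drawn.
#' @param channels Channel frequencies (MHz) hopped uniformly.
#' @param rssi0 RSSI (dBm) at the reference distance `d0` on boresight.
#' @param d0 Reference distance in metres.
#' @param occlusion_floor Minimum relative illumination of an antenna the
#'   body faces away from (the trunk occludes backscatter).
#'
#' @return List of class `sim_config`.
#' @export
sim_config <- function(read_rates = c("Lying" = 10, "Sitting-on-bed" = 9.3,
                                      "Sitting-on-chair" = 6.7,
                                      "Ambulating" = 3.2),
                       accel_sd = 0.05, rssi_sd = 2, phase_sd = 0.1,
                       transition_range = c(1.75, 5),
                       channels = seq(920.25, 925.75, by = 0.5),
                       rssi0 = -45, d0 = 1, occlusion_floor = 0.05) {
  stopifnot(all(read_rates > 0), all(transition_range > 0),
            diff(transition_range) >= 0)
  structure(list(read_rates = read_rates, accel_sd = accel_sd,
                 rssi_sd = rssi_sd, phase_sd = phase_sd,
                 transition_range = transition_range, channels = channels,
                 rssi0 = rssi0, d0 = d0, occlusion_floor = occlusion_floor),
            class = "sim_config")
}

#' Low-noise simulator preset
#'
#' Same structure as [sim_config()] with measurement noise reduced tenfold;
#' used to demonstrate pipeline recoverability when the signal is clean.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_low_noise <- function(...) {
  sim_config(accel_sd = 0.005, rssi_sd = 0.2, phase_sd = 0.01, ...)
}

#' RSSI of a backscattered read at a given distance
#'
#' Received power falls with the fourth power of the line-of-sight distance
#' (two-way path of a passive tag), i.e. 40 dB per decade:
#' `RSSI = rssi0 - 40 * log10(d / d0) - atten_db`. Strictly decreasing in
#' `d`.
#'
#' @param d Distance in metres (> 0, vectorized).
#' @param rssi0 RSSI (dBm) at the reference distance.
#' @param d0 Reference distance (m).
#' @param atten_db Additional off-boresight attenuation in dB (>= 0).
#' @return RSSI in dBm.
#' @export
rssi_from_distance <- function(d, rssi0 = -45, d0 = 1, atten_db = 0) {
  if (any(d <= 0)) stop("distance must be positive")
  rssi0 - 40 * log10(d / d0) - atten_db
}

#' RF phase of a backscattered read
#'
#' The reader measures the phase of the round-trip carrier:
#' `phi = (4 * pi * d * F) / c (mod 2 * pi)` for carrier frequency `F` and
#' one-way distance `d`.
#'
#' @param d Distance in metres (vectorized).
#' @param freq_mhz Channel frequency in MHz.
#' @return Phase in `[0, 2 * pi)`.
#' @export
phase_from_distance <- function(d, freq_mhz) {
  wrap_phase(4 * pi * d * freq_mhz * 1e6 / 299792458)
}

# pitch angle from vertical (radians) adopted during each activity
activity_pitch <- function(label) {
  c("Lying" = 85, "Sitting-on-bed" = 15, "Sitting-on-chair" = 15,
    "Ambulating" = 8)[label] * pi / 180
}

#' Synthesize one patient trial
#'
#' Generates a full [patient_record()] whose annotation equals the script
#' and whose readings follow the sensing physics: the trunk pitch trajectory
#' per activity (gravity projections onto the accelerometer axes, smooth
#' logistic posture transitions completing at each annotation boundary),
#' candidate read events from a per-activity Poisson process (class-dependent
#' sparsity), antenna selection proportional to illumination (boresight
#' pattern, inverse-square candidate weighting and trunk occlusion), RSSI
#' from the inverse-fourth-power law and RF phase from the round-trip
#' carrier, all with Gaussian noise. Deterministic given `seed`.
#'
#' @param script A [trial_script()].
#' @param geom An [antenna_geometry()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param patient_id,gender Identity fields of the record.
#'
#' @return A [patient_record()].
#' @export
synthesize_trial <- function(script, geom = antenna_geometry(),
                             cfg = sim_config(), seed = 1,
                             patient_id = "sim", gender = "female") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n_act <- nrow(script)
  ends <- cumsum(script$duration)
  starts <- c(0, ends[-n_act])
  truth <- data.frame(start = starts, end = ends, label = script$label,
                      stringsAsFactors = FALSE)

  # posture transitions complete at each annotation boundary (the annotator
  # marks the new activity once the posture is attained)
  trans_dur <- stats::runif(n_act - 1, cfg$transition_range[1],
                            cfg$transition_range[2])
  pitch_tgt <- activity_pitch(script$label)

  pitch_at <- function(t) {
    th <- rep(pitch_tgt[1], length(t))
    for (k in seq_len(n_act - 1)) {
      centre <- ends[k] - trans_dur[k] / 2
      s <- stats::plogis((t - centre) / (trans_dur[k] / 8))
      th <- th + (pitch_tgt[k + 1] - pitch_tgt[k]) * s
    }
    th
  }

  wp <- geom$waypoints
  pos_of <- function(k, t) {
    # position during activity k at times t (sensor/sternum location)
    target <- wp[[script$waypoint[k]]]
    if (script$label[k] != "Ambulating") {
      matrix(target, length(t), 3, byrow = TRUE)
    } else {
      from <- if (k == 1) wp$door else wp[[script$waypoint[k - 1]]]
      from[3] <- 1.25  # standing sternum height while walking
      to <- target
      to2 <- to
      to2[3] <- 1.25
      frac <- (t - starts[k]) / script$duration[k]
      out <- outer(1 - frac, from) + outer(frac, to2)
      out
    }
  }
  facing_of <- function(k) {
    lab <- script$label[k]
    if (lab == "Lying") return(c(0, 0, 1))
    if (lab == "Sitting-on-chair") {
      v <- geom$positions[1, ] - wp$chair
    } else if (lab == "Sitting-on-bed") {
      v <- wp$chair - wp$bed_sit
    } else {
      tgt <- wp[[script$waypoint[k]]]
      from <- if (k == 1) wp$door else wp[[script$waypoint[k - 1]]]
      v <- tgt - from
    }
    v[3] <- 0
    n <- sqrt(sum(v^2))
    if (n == 0) c(0, 0, 1) else v / n
  }

  rows <- vector("list", n_act)
  for (k in seq_len(n_act)) {
    lam <- cfg$read_rates[[script$label[k]]]
    n_reads <- stats::rpois(1, lam * script$duration[k])
    if (n_reads == 0) next
    t <- sort(stats::runif(n_reads, starts[k], ends[k]))
    P <- pos_of(k, t)
    face <- facing_of(k)
    th <- pitch_at(t)
    af <- sin(th) + stats::rnorm(n_reads, 0, cfg$accel_sd)
    av <- cos(th) + stats::rnorm(n_reads, 0, cfg$accel_sd)
    al <- stats::rnorm(n_reads, 0, cfg$accel_sd)

    # per-antenna illumination: boresight pattern x 1/d^2 x trunk occlusion
    W <- matrix(0, n_reads, 3)
    D <- matrix(0, n_reads, 3)
    CB <- matrix(0, n_reads, 3)
    for (a in 1:3) {
      dvec <- sweep(P, 2, geom$positions[a, ])  # antenna -> sensor
      d <- sqrt(rowSums(dvec^2))
      dirn <- dvec / d
      cb <- pmax(dirn %*% geom$boresight[a, ], 0)  # boresight gain factor
      to_ant <- -dirn
      occ <- pmax(as.numeric(to_ant %*% face), cfg$occlusion_floor)
      D[, a] <- d
      CB[, a] <- cb
      W[, a] <- as.numeric(cb) * occ / d^2
    }
    W[rowSums(W) == 0, ] <- 1  # fully occluded: uniform antenna pick
    aid <- vapply(seq_len(n_reads), function(i) {
      sample.int(3, 1, prob = W[i, ])
    }, integer(1))
    d_sel <- D[cbind(seq_len(n_reads), aid)]
    cb_sel <- CB[cbind(seq_len(n_reads), aid)]
    rssi <- rssi_from_distance(d_sel, cfg$rssi0, cfg$d0,
                               atten_db = 10 * (1 - cb_sel)) +
      stats::rnorm(n_reads, 0, cfg$rssi_sd)
    freq <- sample(cfg$channels, n_reads, replace = TRUE)
    phase <- wrap_phase(phase_from_distance(d_sel, freq) +
                          stats::rnorm(n_reads, 0, cfg$phase_sd))
    rows[[k]] <- data.frame(t = t, af = af, av = av, al = al, rssi = rssi,
                            aid = aid, freq = freq, phase = phase)
  }
  readings <- do.call(rbind, rows)
  if (is.null(readings)) {
    readings <- as.data.frame(stats::setNames(
      replicate(8, numeric(0), simplify = FALSE), canonical_columns()))
  }
  patient_record(patient_id, gender, readings, truth)
}

# gender and repetition draws for a cohort; shared by synthesize_cohort so
# manifest-only sampling is cheap to test at large n
cohort_manifest <- function(n_patients, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("sim%02d", seq_len(n_patients)),
    gender = ifelse(stats::runif(n_patients) < 1 / 3, "male", "female"),
    repetitions = sample(2:3, n_patients, replace = TRUE),
    seed = sample.int(2^31 - 2, n_patients),
    stringsAsFactors = FALSE
  )
}

#' Sample a cohort manifest without generating readings
#'
#' Draws the per-patient identity fields (gender at the trial cohort's
#' roughly 1:2 male:female ratio, 2-3 script repetitions, derived seeds)
#' deterministically from the master seed.
#'
#' @param n_patients Number of patients.
#' @param seed Master seed.
#' @return Data frame with `patient_id`, `gender`, `repetitions`, `seed`.
#' @export
sample_cohort_manifest <- function(n_patients, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  cohort_manifest(n_patients, seed)
}

#' Synthesize a cohort of patient trials
#'
#' @param n_patients Number of patients (>= 1).
#' @param cfg A [sim_config()].
#' @param seed Master seed; per-patient seeds are derived from it, so the
#'   cohort is reproducible end to end.
#' @param geom An [antenna_geometry()].
#'
#' @return List with `records` (list of [patient_record()]) and `manifest`
#'   (data frame).
#' @export
synthesize_cohort <- function(n_patients, cfg = sim_config(), seed = 1,
                              geom = antenna_geometry()) {
  stopifnot(n_patients >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  man <- cohort_manifest(n_patients, seed)
  records <- lapply(seq_len(n_patients), function(i) {
    synthesize_trial(trial_script(man$repetitions[i]), geom, cfg,
                     seed = man$seed[i], patient_id = man$patient_id[i],
                     gender = man$gender[i])
  })
  list(records = records, manifest = man)
}
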