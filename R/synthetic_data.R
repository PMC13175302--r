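# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes, each returning its ground truth alongside the
# data. All randomness flows from one explicit seed per call; no global
# state is left behind beyond the usual set.seed semantics.

#' Simulate a cyclic unconfined-compression recording
#'
#' Triangular displacement waveform at the protocol defaults (three cycles to
#' 15% strain at 0.01/s) around the analytic Ogden baseline stress. Loading
#' samples are scaled by `(1 + hysteresis)`, unloading samples by
#' `(1 - hysteresis)`; the turning-point samples carry the unscaled baseline
#' so the loop closes there, which makes loading/unloading averaging recover
#' the baseline exactly. Cycle 3 is softened by the multiplicative
#' `conditioning` factor (a minimal Mullins-like conditioning effect, not a
#' damage model). Multiplicative Gaussian noise is applied to the force
#' channel. Each loading/unloading phase is sampled on `points_per_phase`
#' uniformly spaced stretch values; with the default 100 this matches the
#' default averaging grid, so averaged curves are evaluated exactly at
#' sample points.
#'
#' @param mu,alpha True Ogden parameters (Pa, dimensionless).
#' @param height_mm Sample height (default 3 mm).
#' @param area_mm2 Cross-sectional area (default the 9 mm punch).
#' @param max_strain Maximum nominal strain (default 0.15).
#' @param strain_rate Nominal strain rate in 1/s (default 0.01).
#' @param cycles Number of cycles (default 3).
#' @param hysteresis Symmetric hysteresis factor eta in `[0, 0.5)`
#'   (default 0.1).
#' @param conditioning Multiplicative softening of cycle 3 in (0, 1]
#'   (default 0.85).
#' @param noise_sd Multiplicative Gaussian noise level on force (default 0).
#' @param points_per_phase Samples per loading/unloading phase (default 100).
#' @param seed Integer seed.
#' @return List with `recording` (a [compression_recording()]) and `truth`
#'   (list with the generating parameters, the turning-point indices and the
#'   baseline curve as a tibble `lambda`, `stress`).
#' @export
generate_cyclic_recording <- function(mu, alpha, height_mm = 3,
                                      area_mm2 = punch_area_mm2(9),
                                      max_strain = 0.15, strain_rate = 0.01,
                                      cycles = 3, hysteresis = 0.1,
                                      conditioning = 0.85, noise_sd = 0,
                                      points_per_phase = 100, seed = 1L) {
  params <- ogden_parameters(mu, alpha)
  if (hysteresis < 0 || hysteresis >= 0.5) {
    nq_abort("hysteresis must be in [0, 0.5)", field = "hysteresis")
  }
  if (conditioning <= 0 || conditioning > 1) {
    nq_abort("conditioning must be in (0, 1]", field = "conditioning")
  }
  if (noise_sd < 0) nq_abort("noise_sd must be >= 0", field = "noise_sd")
  m <- as.integer(points_per_phase)
  up <- seq(0, max_strain, length.out = m)
  down <- rev(up)
  strain <- 0
  phase <- 0L  # 0 top, +1 loading, -1 unloading
  cyc <- 0L
  for (k in seq_len(cycles)) {
    strain <- c(strain, up[-1], down[-1])
    phase <- c(phase, rep(1L, m - 1L), rep(-1L, m - 1L))
    cyc <- c(cyc, rep(k, 2L * (m - 1L)))
  }
  n <- length(strain)
  # turning samples (troughs and tops) carry the unscaled baseline
  troughs <- 1L + (seq_len(cycles) - 1L) * (2L * m - 2L) + (m - 1L)
  tops <- c(1L, 1L + seq_len(cycles) * (2L * m - 2L))
  turning <- sort(c(tops, troughs))
  factor_phase <- ifelse(phase > 0, 1 + hysteresis,
                         ifelse(phase < 0, 1 - hysteresis, 1))
  factor_phase[turning] <- 1
  factor_cond <- ifelse(cyc == 3L, conditioning, 1)
  dt <- (max_strain / strain_rate) / (m - 1)
  time <- (seq_len(n) - 1) * dt
  lambda <- 1 - strain
  baseline <- ogden_stress(lambda, params)
  stress <- baseline * factor_phase * factor_cond
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    stress <- stress * (1 + noise_sd * rnorm(n))
  }
  force <- stress * (area_mm2 * 1e-6)
  rec <- compression_recording(time = time, displacement = -height_mm * strain,
                               force = force, height_mm = height_mm,
                               area_mm2 = area_mm2,
                               metadata = list(source = "synthetic",
                                               strain_rate = strain_rate))
  list(recording = rec,
       truth = list(mu = mu, alpha = alpha, hysteresis = hysteresis,
                    conditioning = conditioning, noise_sd = noise_sd,
                    troughs = troughs, tops = tops,
                    baseline = tibble(lambda = lambda, stress = baseline)))
}

random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Simulate a filament scene with puncta at known shell membership
#'
#' Builds a random-walk polyline filament inside a box and places puncta
#' either inside the capsule shell (surface distance at most `threshold`) or
#' strictly outside a safety margin (`> margin`), so the near-filament count
#' is known exactly by construction.
#'
#' @param n_nodes Filament node count (>= 2).
#' @param box Box dimensions in micrometres (length-3).
#' @param radius Filament radius in micrometres.
#' @param step_um Random-walk step length (default 8).
#' @param n_inside,n_outside Puncta placed inside / outside the shell.
#' @param threshold Shell distance in micrometres (default 2.5).
#' @param margin Exclusion margin for outside puncta (default 2.6).
#' @param seed Integer seed.
#' @return List with `filament` ([filament_model()]), `puncta`
#'   ([puncta_set()]) and `truth` (list with `n_inside`, `n_outside`,
#'   `threshold`).
#' @export
generate_scene <- function(n_nodes = 8, box = c(60, 60, 30), radius = 0.5,
                           step_um = 8, n_inside = 30, n_outside = 70,
                           threshold = 2.5, margin = 2.6, seed = 1L) {
  if (n_nodes < 2) nq_abort("need >= 2 nodes", field = "n_nodes")
  set.seed(as.integer(seed))
  pos <- matrix(NA_real_, n_nodes, 3)
  pos[1, ] <- box * runif(3, 0.3, 0.7)
  for (i in 2:n_nodes) {
    repeat {
      cand <- pos[i - 1, ] + step_um * random_unit_vectors(1)[1, ]
      if (all(cand > 0) && all(cand < box)) break
    }
    pos[i, ] <- cand
  }
  fil <- filament_model(tibble(id = seq_len(n_nodes), type = 3L,
                               x = pos[, 1], y = pos[, 2], z = pos[, 3],
                               radius = radius,
                               parent = c(-1L, seq_len(n_nodes - 1L))))
  segs <- filament_segments(fil)
  pts <- matrix(NA_real_, 0, 3)
  if (n_inside > 0) {
    si <- sample(nrow(segs), n_inside, replace = TRUE, prob = segs$length)
    tt <- runif(n_inside)
    ax <- cbind(segs$ax[si] + tt * (segs$bx[si] - segs$ax[si]),
                segs$ay[si] + tt * (segs$by[si] - segs$ay[si]),
                segs$az[si] + tt * (segs$bz[si] - segs$az[si]))
    rr <- segs$r0[si] + tt * (segs$r1[si] - segs$r0[si])
    d_t <- runif(n_inside, 0, threshold)
    pts <- rbind(pts, ax + random_unit_vectors(n_inside) * (rr + d_t))
  }
  if (n_outside > 0) {
    out <- matrix(NA_real_, 0, 3)
    attempts <- 0L
    while (nrow(out) < n_outside) {
      attempts <- attempts + 1L
      if (attempts > 2000L) {
        nq_abort("box too small to place puncta outside the margin",
                 class = "nq_generation_error")
      }
      cand <- matrix(runif(3 * 200) * rep(box, each = 200), ncol = 3)
      d <- distance_to_filament_surface(
        tibble(x = cand[, 1], y = cand[, 2], z = cand[, 3]), fil)
      out <- rbind(out, cand[d > margin, , drop = FALSE])
    }
    pts <- rbind(pts, out[seq_len(n_outside), , drop = FALSE])
  }
  list(filament = fil,
       puncta = puncta_set(tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])),
       truth = list(n_inside = as.integer(n_inside),
                    n_outside = as.integer(n_outside), threshold = threshold))
}

#' Simulate ROI calcium traces with Poisson-timed transients
#'
#' Each ROI gets a constant baseline, Poisson event times over the recording,
#' and per-event exponentially decaying transients `A * exp(-t/tau)` added in
#' dF/F0 units, plus Gaussian noise; the raw trace is
#' `F0 * (1 + signal + noise)`. Defaults mirror a 300 s recording at 10 Hz
#' with transients of 6-10 times the noise level. The truth bundle lists
#' every event time, amplitude and analytic AUC (`A * tau`).
#'
#' @param n_roi Number of ROIs (default 50).
#' @param duration_s Recording length in seconds (default 300).
#' @param rate Sampling rate in Hz (default 10).
#' @param event_rate Poisson event rate per second (default 0.02).
#' @param amplitude_range Transient amplitudes in dF/F0 units (default
#'   `c(0.3, 0.5)`, i.e. 6-10x the default noise).
#' @param tau_s Exponential decay constant in seconds (default 2).
#' @param noise_sd Gaussian noise in dF/F0 units (default 0.05).
#' @param f0_range Baseline range in arbitrary units (default `c(80, 120)`).
#' @param seed Integer seed.
#' @return List with `traces` (a [trace_set()]) and `truth` (tibble `roi`,
#'   `time_s`, `amplitude`, `auc`).
#' @export
generate_calcium_traces <- function(n_roi = 50, duration_s = 300, rate = 10,
                                    event_rate = 0.02,
                                    amplitude_range = c(0.3, 0.5),
                                    tau_s = 2, noise_sd = 0.05,
                                    f0_range = c(80, 120), seed = 1L) {
  check_number(rate, "rate", positive = TRUE)
  check_number(duration_s, "duration_s", positive = TRUE)
  if (event_rate < 0) nq_abort("event_rate must be >= 0", field = "event_rate")
  set.seed(as.integer(seed))
  n_frames <- round(duration_s * rate)
  t_grid <- (seq_len(n_frames) - 1) / rate
  mat <- matrix(NA_real_, n_roi, n_frames)
  truth <- list()
  for (i in seq_len(n_roi)) {
    f0 <- runif(1, f0_range[1], f0_range[2])
    n_ev <- rpois(1, event_rate * duration_s)
    times <- sort(runif(n_ev, 0, duration_s))
    amps <- runif(n_ev, amplitude_range[1], amplitude_range[2])
    signal <- numeric(n_frames)
    for (j in seq_len(n_ev)) {
      active <- t_grid >= times[j]
      signal[active] <- signal[active] + amps[j] * exp(-(t_grid[active] - times[j]) / tau_s)
    }
    noise <- if (noise_sd > 0) noise_sd * rnorm(n_frames) else 0
    mat[i, ] <- f0 * (1 + signal + noise)
    truth[[i]] <- tibble(roi = paste0("roi_", i), time_s = times,
                         amplitude = amps, auc = amps * tau_s)
  }
  list(traces = trace_set(mat, rate = rate,
                          roi_ids = paste0("roi_", seq_len(n_roi))),
       truth = list_rbind(truth))
}

#' Simulate labeled group data with known distribution and effects
#'
#' @param specs A named list; each element a list with `n` and `dist`
#'   (`"normal"`, `"exponential"`, `"lognormal"` or `"uniform"`) plus
#'   distribution parameters (`mean`, `sd`, `rate`, `min`, `max`,
#'   `meanlog`, `sdlog`).
#' @param seed Integer seed.
#' @return List with `data` (tibble `value`, `group`) and `truth` (tibble of
#'   per-group family and parameters).
#' @export
generate_group_data <- function(specs, seed = 1L) {
  if (length(specs) < 2) nq_abort("need >= 2 groups", field = "specs")
  if (is.null(names(specs)) || any(names(specs) == "")) {
    nq_abort("`specs` must be a named list", field = "specs")
  }
  set.seed(as.integer(seed))
  draws <- purrr::imap(specs, function(sp, nm) {
    v <- switch(sp$dist %||% "normal",
                normal = rnorm(sp$n, sp$mean %||% 0, sp$sd %||% 1),
                exponential = rexp(sp$n, sp$rate %||% 1),
                lognormal = stats::rlnorm(sp$n, sp$meanlog %||% 0, sp$sdlog %||% 1),
                uniform = runif(sp$n, sp$min %||% 0, sp$max %||% 1),
                nq_abort(sprintf("unknown distribution: %s", sp$dist), field = "dist"))
    tibble(value = v, group = nm)
  })
  truth <- purrr::imap(specs, function(sp, nm) {
    tibble(group = nm, dist = sp$dist %||% "normal", n = sp$n)
  })
  list(data = list_rbind(draws), truth = list_rbind(truth))
}
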