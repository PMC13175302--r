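# From raw cyclic compression recordings to averaged hyperelastic
# stress-stretch curves. Curves are averaged in (lambda, Pzz) space after the
# kinematic conversion, loading and unloading phases are interpolated onto a
# shared uniform stretch grid, and the first (unconditioned) and third
# (conditioned) cycles are the fitting targets downstream.

#' Axial stretch from displacement and initial height
#'
#' `lambda = 1 + dz / h` with compressive displacement negative, so 15%
#' compression of a 3 mm sample (`dz = -0.45` mm) gives `lambda = 0.85`.
#'
#' @param dz Axial displacement in mm (vectorized; compression negative).
#' @param h Initial sample height in mm, > 0.
#' @return Dimensionless stretch, same length as `dz`.
#' @export
compute_stretch <- function(dz, h) {
  check_number(h, "h", positive = TRUE)
  lambda <- 1 + dz / h
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    nq_abort("non-physical compression: stretch <= 0", field = "dz",
             row = which(lambda <= 0)[1])
  }
  lambda
}

#' Nominal (Piola) stress from force and initial area
#'
#' Load per undeformed cross-sectional area, converted from N/mm^2 to Pa.
#' Sign is preserved: compressive force (negative) gives negative stress.
#'
#' @param f_z Axial force in N (vectorized).
#' @param A Initial cross-sectional area in mm^2, > 0.
#' @return Nominal stress in Pa.
#' @export
compute_nominal_stress <- function(f_z, A) {
  check_number(A, "A", positive = TRUE)
  f_z / (A * 1e-6)
}

#' Hyperelastic stress-stretch curve
#'
#' Paired (stretch, nominal stress) samples with cycle and phase tags; the
#' object every fitting routine consumes. Stretch must be strictly monotone
#' within a phase (decreasing along loading in time order is accepted).
#'
#' @param lambda Stretch values in (0, 1.5).
#' @param stress Nominal stress in Pa, same length.
#' @param cycle Cycle index (1-based) or NA for synthetic curves.
#' @param phase One of "loading", "unloading", "averaged".
#' @param label One of "unconditioned", "conditioned", "none".
#' @return A tibble of class `hyperelastic_curve` with columns `lambda`,
#'   `stress` and attributes `cycle`, `phase`, `label`.
#' @export
hyperelastic_curve <- function(lambda, stress, cycle = NA_integer_,
                               phase = c("averaged", "loading", "unloading"),
                               label = c("none", "unconditioned", "conditioned")) {
  phase <- match.arg(phase)
  label <- match.arg(label)
  if (length(lambda) != length(stress)) {
    nq_abort("`lambda` and `stress` lengths differ", field = "stress")
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0) || any(lambda >= 1.5)) {
    nq_abort("`lambda` must lie in (0, 1.5)", field = "lambda")
  }
  # averaged curves live on a strictly monotone grid; raw loading/unloading
  # phases are time-ordered and may carry sensor jitter
  d <- diff(lambda)
  if (phase == "averaged" && length(d) && !(all(d > 0) || all(d < 0))) {
    nq_abort("`lambda` must be strictly monotone within an averaged phase",
             field = "lambda")
  }
  out <- tibble(lambda = as.numeric(lambda), stress = as.numeric(stress))
  structure(out, cycle = as.integer(cycle), phase = phase, label = label,
            class = c("hyperelastic_curve", class(out)))
}

#' @export
print.hyperelastic_curve <- function(x, ...) {
  cat(sprintf("<hyperelastic_curve> cycle %s, %s, %s, %d points\n",
              attr(x, "cycle"), attr(x, "phase"), attr(x, "label"), nrow(x)))
  NextMethod()
}

curve_phase <- function(curve) attr(curve, "phase")
curve_cycle <- function(curve) attr(curve, "cycle")

#' Segment a cyclic recording into per-cycle loading/unloading curves
#'
#' Turning points are located on a moving-median-smoothed displacement signal
#' (window 5 samples) as alternating tops (near zero displacement) and
#' troughs (maximum compression); each cycle contributes a loading curve
#' (top to trough) and an unloading curve (trough to next top), both already
#' converted to (stretch, nominal stress) using the recording geometry. The
#' trough sample is shared by both phases of its cycle.
#'
#' @param recording A [compression_recording()].
#' @param cycles Expected number of cycles (default 3).
#' @return A list of [hyperelastic_curve()] objects of length `2 * cycles`,
#'   ordered loading/unloading per cycle, with attribute `turning_points`
#'   (indices of tops and troughs).
#' @export
segment_cycles <- function(recording, cycles = 3) {
  stopifnot(inherits(recording, "compression_recording"))
  d <- recording$displacement
  n <- length(d)
  s <- runmed(d, k = min(5L, n - (1 - n %% 2)), endrule = "median")
  depth <- min(s)
  if (depth >= 0) {
    nq_abort("no compressive excursion found; 0 complete cycles detected",
             class = "nq_cycle_error")
  }
  half <- depth / 2
  # classify each sample as top-region (above half depth) or trough-region
  region <- ifelse(s > half, 1L, -1L)
  # representative index per contiguous region: argmax of d for tops,
  # argmin of d for troughs (raw signal, so turning points land on samples)
  r <- rle(region)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- integer(0)
  kind <- integer(0)
  for (j in seq_along(r$values)) {
    seg <- starts[j]:ends[j]
    if (r$values[j] > 0) {
      idx <- c(idx, seg[which.max(d[seg])]); kind <- c(kind, 1L)
    } else {
      idx <- c(idx, seg[which.min(d[seg])]); kind <- c(kind, -1L)
    }
  }
  troughs <- idx[kind < 0]
  tops <- idx[kind > 0]
  # a cycle is complete only when the trough is followed by a return top
  troughs <- troughs[vapply(troughs, function(t) any(tops > t), logical(1))]
  detected <- length(troughs)
  if (detected != cycles) {
    nq_abort(sprintf("detected %d complete cycle(s), expected %d; turning points at %s",
                     detected, cycles, paste(sort(idx), collapse = ", ")),
             class = "nq_cycle_error")
  }
  h <- attr(recording, "height_mm")
  A <- attr(recording, "area_mm2")
  curves <- list()
  for (k in seq_len(cycles)) {
    t_k <- troughs[k]
    start_k <- max(tops[tops < t_k], 1L)
    after <- tops[tops > t_k]
    end_k <- if (length(after)) after[1] else n
    li <- start_k:t_k
    ui <- t_k:end_k
    curves[[2 * k - 1]] <- hyperelastic_curve(
      compute_stretch(d[li], h), compute_nominal_stress(recording$force[li], A),
      cycle = k, phase = "loading")
    curves[[2 * k]] <- hyperelastic_curve(
      compute_stretch(d[ui], h), compute_nominal_stress(recording$force[ui], A),
      cycle = k, phase = "unloading")
  }
  attr(curves, "turning_points") <- sort(idx)
  curves
}

#' Average a loading/unloading pair onto a uniform stretch grid
#'
#' Both phases are linearly interpolated onto a uniform stretch grid spanning
#' their common range and averaged pointwise — the standard approximation of
#' the hyperelastic response from a hysteretic cycle. The result is labeled
#' `unconditioned` for cycle 1 and `conditioned` for cycle 3.
#'
#' @param loading,unloading [hyperelastic_curve()] objects with phases
#'   "loading" and "unloading" (order-insensitive: arguments may be swapped).
#' @param grid_size Number of grid points (default 100).
#' @return An averaged [hyperelastic_curve()].
#' @export
average_load_unload <- function(loading, unloading, grid_size = 100) {
  stopifnot(inherits(loading, "hyperelastic_curve"),
            inherits(unloading, "hyperelastic_curve"))
  lo <- range(loading$lambda)
  uo <- range(unloading$lambda)
  common <- c(max(lo[1], uo[1]), min(lo[2], uo[2]))
  if (common[1] >= common[2]) {
    nq_abort("loading and unloading curves have no overlapping stretch range",
             field = "lambda")
  }
  grid <- seq(common[1], common[2], length.out = grid_size)
  ol <- order(loading$lambda)
  ou <- order(unloading$lambda)
  p_load <- approx(loading$lambda[ol], loading$stress[ol], xout = grid,
                   ties = "ordered")$y
  p_unload <- approx(unloading$lambda[ou], unloading$stress[ou], xout = grid,
                     ties = "ordered")$y
  cyc <- curve_cycle(loading)
  if (is.na(cyc)) cyc <- curve_cycle(unloading)
  label <- if (isTRUE(cyc == 1L)) "unconditioned" else if (isTRUE(cyc == 3L)) "conditioned" else "none"
  hyperelastic_curve(grid, (p_load + p_unload) / 2, cycle = cyc,
                     phase = "averaged", label = label)
}

#' Maximum nominal stress magnitude of a first-cycle loading curve
#'
#' The per-sample summary reported next to the apparent Young's modulus:
#' the largest stress magnitude reached during the first loading ramp.
#'
#' @param curve A [hyperelastic_curve()] tagged phase "loading", cycle 1.
#' @return Stress magnitude in Pa.
#' @export
max_nominal_stress <- function(curve) {
  stopifnot(inherits(curve, "hyperelastic_curve"))
  if (!identical(curve_phase(curve), "loading") || !isTRUE(curve_cycle(curve) == 1L)) {
    nq_abort("expected the loading curve of cycle 1", field = "phase/cycle")
  }
  max(abs(curve$stress))
}

#' Preprocess a cyclic recording end to end
#'
#' Segments the recording, averages cycle-1 (unconditioned) and, when
#' present, cycle-3 (conditioned) loading/unloading pairs, and extracts the
#' first-cycle maximum nominal stress.
#'
#' @param recording A [compression_recording()].
#' @param cycles Expected cycle count (default 3).
#' @param grid_size Averaging grid size (default 100).
#' @return A list with elements `unconditioned`, `conditioned` (averaged
#'   curves; `conditioned` is NULL when fewer than 3 cycles), `phases` (the
#'   raw segmented curves) and `max_stress_Pa` (first-cycle magnitude).
#' @export
preprocess_recording <- function(recording, cycles = 3, grid_size = 100) {
  phases <- segment_cycles(recording, cycles = cycles)
  uncond <- average_load_unload(phases[[1]], phases[[2]], grid_size = grid_size)
  cond <- if (cycles >= 3) {
    average_load_unload(phases[[5]], phases[[6]], grid_size = grid_size)
  }
  list(unconditioned = uncond, conditioned = cond, phases = phases,
       max_stress_Pa = max_nominal_stress(phases[[1]]))
}

#' Plot segmented or averaged stress-stretch curves
#'
#' @param object A [hyperelastic_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hyperelastic_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$lambda, y = .data$stress)) +
    ggplot2::geom_line(color = "#2C7FB8") +
    ggplot2::labs(x = expression(lambda), y = expression(P[zz] ~ "(Pa)"),
                  title = sprintf("cycle %s, %s", attr(object, "cycle"),
                                  attr(object, "phase"))) +
    ggplot2::theme_minimal()
}
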