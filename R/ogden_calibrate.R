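# Calibration of (mu, alpha) to an averaged stress-stretch curve by bounded
# multi-start nonlinear least squares (Levenberg-Marquardt via minpack.lm).
# The alpha singularity at 0 is handled by splitting the parameter space into
# a negative and a positive branch; each alpha start is optimized within its
# own sign branch.

ogden_residuals <- function(par, lambda, stress) {
  stress - ogden_stress(lambda, list(mu = par[1], alpha = par[2]))
}

# Small-strain secant slope of the curve, used to seed mu = slope / 3.
secant_mu_start <- function(lambda, stress) {
  i <- order(abs(lambda - 1))[1:2]
  dl <- diff(lambda[i])
  if (abs(dl) < .Machine$double.eps) return(NA_real_)
  slope <- diff(stress[i]) / dl
  slope / 3
}

#' Fit quality metrics for an Ogden model against a curve
#'
#' Chi-squared is the plain sum of squared stress residuals (Pa^2); RMSE is
#' `sqrt(chisq / n)`; R^2 is one minus chi-squared over the total sum of
#' squares about the mean stress. Constant data makes R^2 undefined and is
#' reported as `NA` with a warning.
#'
#' @param curve A [hyperelastic_curve()] (any phase) with columns `lambda`,
#'   `stress`.
#' @param params An [ogden_parameters()] object (or list with mu, alpha).
#' @return A tibble with columns `chisq`, `rmse`, `r_squared`, `n`.
#' @export
goodness_of_fit <- function(curve, params) {
  if (!nrow(curve)) nq_abort("empty curve", field = "curve")
  params <- as_ogden_parameters(params)
  res <- curve$stress - ogden_stress(curve$lambda, params)
  chisq <- sum(res^2)
  n <- length(res)
  ss_tot <- sum((curve$stress - mean(curve$stress))^2)
  r2 <- if (ss_tot <= 0) {
    warn("constant stress data: R^2 undefined, reported as NA")
    NA_real_
  } else 1 - chisq / ss_tot
  tibble(chisq = chisq, rmse = sqrt(chisq / n), r_squared = r2, n = n)
}

#' Calibrate the one-term modified Ogden model to a stress-stretch curve
#'
#' Minimizes the sum of squared nominal-stress residuals over `(mu, alpha)`
#' with `mu > 0` enforced by box bounds and the `alpha` singularity at zero
#' excluded by optimizing the negative and positive `alpha` branches as
#' separate bounded sub-problems. Multi-start: each `alpha` start magnitude
#' in the config is run in both sign branches, paired with a `mu` start from
#' the small-strain secant slope (clipped to bounds); the best converged run
#' wins. The apparent Young's
#' modulus `E_app = 3 mu` is attached to the result.
#'
#' @param curve An averaged [hyperelastic_curve()] with at least 5 points and
#'   stretches in (0, 1.5).
#' @param config A [run_config()] (controls starts, bounds, tolerance).
#' @return An object of class `ogden_fit`: list with `mu`, `alpha`, `E_app`,
#'   `chisq`, `rmse`, `r_squared`, `n`, `converged`, `starts` (audit tibble
#'   of every start and its final objective), `curve`, `label`.
#' @examples
#' curve <- hyperelastic_curve(seq(0.85, 1, length.out = 50),
#'                             ogden_stress(seq(0.85, 1, length.out = 50),
#'                                          ogden_parameters(200, -15)))
#' fit <- fit_ogden(curve)
#' glance(fit)
#' @export
fit_ogden <- function(curve, config = run_config()) {
  stopifnot(inherits(curve, "hyperelastic_curve"))
  if (nrow(curve) < 5) nq_abort("need at least 5 points to calibrate", field = "curve")
  if (any(curve$lambda <= 0) || any(curve$lambda >= 1.5)) {
    nq_abort("`lambda` outside (0, 1.5)", field = "lambda")
  }
  if (all(curve$stress == 0)) {
    nq_abort("degenerate all-zero stress curve: mu > 0 cannot produce zero stress",
             class = "nq_degenerate_error")
  }
  mu_lo <- config$mu_bounds[1]; mu_hi <- config$mu_bounds[2]
  a_min <- config$alpha_bounds[1]; a_max <- config$alpha_bounds[2]
  mu0 <- secant_mu_start(curve$lambda, curve$stress)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- 100
  mu0 <- min(max(mu0, mu_lo), mu_hi)
  ctrl <- minpack.lm::nls.lm.control(ftol = config$fit_tol, ptol = config$fit_tol,
                                     maxiter = 500)
  # each alpha start explores both sign branches as separate bounded
  # sub-problems (the alpha axis is split around the singular band at 0)
  runs <- purrr::imap(config$alpha_starts, function(a0, start_id) {
    a0 <- max(abs(a0), a_min)
    branch <- purrr::map(c(-1, 1), function(sgn) {
      lower <- c(mu_lo, if (sgn < 0) -a_max else a_min)
      upper <- c(mu_hi, if (sgn < 0) -a_min else a_max)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(mu0, sgn * a0), lower = lower, upper = upper,
                           fn = ogden_residuals, lambda = curve$lambda,
                           stress = curve$stress, control = ctrl),
        error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble(start_id = start_id, mu0 = mu0, alpha0 = sgn * a0,
                      mu = NA_real_, alpha = NA_real_,
                      objective = Inf, converged = FALSE))
      }
      tibble(start_id = start_id, mu0 = mu0, alpha0 = sgn * a0,
             mu = fit$par[1], alpha = fit$par[2],
             objective = sum(fit$fvec^2), converged = fit$info %in% 1:4)
    })
    list_rbind(branch)
  })
  starts <- list_rbind(runs)
  ok <- starts[starts$converged & is.finite(starts$objective), , drop = FALSE]
  if (!nrow(ok)) nq_abort("no start converged", class = "nq_fit_error")
  best <- ok[which.min(ok$objective), ]
  params <- ogden_parameters(best$mu, best$alpha)
  gof <- goodness_of_fit(curve, params)
  structure(list(mu = best$mu, alpha = best$alpha, E_app = 3 * best$mu,
                 chisq = gof$chisq, rmse = gof$rmse, r_squared = gof$r_squared,
                 n = gof$n, converged = TRUE, starts = starts,
                 curve = curve, label = attr(curve, "label")),
            class = "ogden_fit")
}

#' @export
print.ogden_fit <- function(x, ...) {
  cat(sprintf(paste0("<ogden_fit> (%s curve, n = %d)\n",
                     "  mu    = %.4g Pa\n  alpha = %.4g\n  E_app = %.4g Pa\n",
                     "  RMSE  = %.4g Pa, R^2 = %.6f\n"),
              x$label, x$n, x$mu, x$alpha, x$E_app, x$rmse, x$r_squared))
  invisible(x)
}

#' Tidy an Ogden fit into a parameter table
#'
#' @param x An `ogden_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`mu`, `alpha`, `E_app`).
#' @export
tidy.ogden_fit <- function(x, ...) {
  tibble(term = c("mu", "alpha", "E_app"),
         estimate = c(x$mu, x$alpha, x$E_app),
         unit = c("Pa", "1", "Pa"))
}

#' One-row fit summary
#'
#' @param x An `ogden_fit`.
#' @param ... Unused.
#' @return A tibble with `mu`, `alpha`, `E_app`, `chisq`, `rmse`,
#'   `r_squared`, `n`, `converged`.
#' @export
glance.ogden_fit <- function(x, ...) {
  tibble(mu = x$mu, alpha = x$alpha, E_app = x$E_app, chisq = x$chisq,
         rmse = x$rmse, r_squared = x$r_squared, n = x$n,
         converged = x$converged)
}

#' Plot data and fitted Ogden curve
#'
#' @param object An `ogden_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ogden_fit <- function(object, ...) {
  grid <- seq(min(object$curve$lambda), max(object$curve$lambda), length.out = 200)
  pred <- tibble(lambda = grid,
                 stress = ogden_stress(grid, list(mu = object$mu, alpha = object$alpha)))
  ggplot2::ggplot(as_tibble(object$curve),
                  ggplot2::aes(x = .data$lambda, y = .data$stress)) +
    ggplot2::geom_point(size = 0.8, color = "grey40") +
    ggplot2::geom_line(data = pred, color = "#D95F02") +
    ggplot2::labs(x = expression(lambda), y = expression(P[zz] ~ "(Pa)"),
                  subtitle = sprintf("mu = %.3g Pa, alpha = %.3g, E_app = %.3g Pa",
                                     object$mu, object$alpha, object$E_app)) +
    ggplot2::theme_minimal()
}
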