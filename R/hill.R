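#' Hill (sigmoidal) monotherapy dose-response curve
#'
#' A four-parameter Hill model of cell viability (% of untreated control)
#' as a function of drug concentration:
#' \deqn{E(d) = E_{inf} + (E_0 - E_{inf}) / (1 + (d/EC_{50})^h)}
#' with baseline `e0` at zero dose, asymptote `e_inf` at infinite dose,
#' half-effect concentration `ec50` (uM) and slope `h`. Viability is
#' non-increasing in dose (`e0 >= e_inf`).
#'
#' @param e0 viability at zero dose (% control).
#' @param e_inf asymptotic viability (% control).
#' @param ec50 half-effect concentration (uM), > 0.
#' @param h Hill slope, > 0.
#' @param no_effect logical flag marking a degenerate flat curve.
#' @param rmse root-mean-square error of the fit, if fitted.
#' @return object of class `hill_curve`.
#' @export
hill_curve <- function(e0, e_inf, ec50, h, no_effect = FALSE, rmse = NA_real_) {
  assert_that(is.finite(e0) && is.finite(e_inf), "e0 and e_inf must be finite")
  assert_that(ec50 > 0, "ec50 must be positive")
  assert_that(h > 0, "Hill slope h must be positive")
  assert_that(e0 >= e_inf, "e0 must be >= e_inf (viability non-increasing)")
  structure(list(e0 = e0, e_inf = e_inf, ec50 = ec50, h = h,
                 no_effect = isTRUE(no_effect), rmse = rmse),
            class = "hill_curve")
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("Hill curve: e0=%.2f e_inf=%.2f ec50=%.4g h=%.3f%s\n",
              x$e0, x$e_inf, x$ec50, x$h,
              if (x$no_effect) " [no-effect]" else ""))
  invisible(x)
}

#' Evaluate a Hill curve
#'
#' @param curve a [hill_curve()].
#' @param dose concentration(s), uM, >= 0.
#' @return viability in % control; `E(0) = e0`.
#' @export
hill_response <- function(curve, dose) {
  assert_that(all(dose >= 0), "dose must be non-negative")
  if (curve$no_effect || curve$e0 == curve$e_inf) {
    return(rep(curve$e0, length(dose)))
  }
  curve$e_inf + (curve$e0 - curve$e_inf) / (1 + (dose / curve$ec50)^curve$h)
}

#' Invert a Hill curve
#'
#' Closed-form dose at which the curve attains a given effect:
#' `d = ec50 * ((e0 - effect) / (effect - e_inf))^(1/h)`.
#' Effects at or beyond the asymptotes are unreachable at finite dose.
#'
#' @param curve a [hill_curve()].
#' @param effect target viability, must lie strictly in `(e_inf, e0)`.
#' @return concentration (uM), or `NA_real_` with attribute
#'   `unreachable = TRUE` when no finite dose exists.
#' @export
inverse_hill <- function(curve, effect) {
  if (curve$no_effect || curve$e0 == curve$e_inf ||
      effect <= curve$e_inf || effect >= curve$e0) {
    return(structure(NA_real_, unreachable = TRUE))
  }
  curve$ec50 * ((curve$e0 - effect) / (effect - curve$e_inf))^(1 / curve$h)
}

#' Fit a Hill curve to monotherapy data
#'
#' Bounded least squares with multiple starting points
#' (box constraints: `e0` in \[80, 120\], `e_inf` in \[0, 110\],
#' `h` in \[0.1, 10\], `ec50` in \[min positive dose / 100, max dose x 100\]).
#' A response indistinguishable from constant returns a flat curve flagged
#' `no_effect`.
#'
#' @param doses concentration vector including 0 (uM).
#' @param viability matching % control values.
#' @param n_starts number of multi-start points per axis combination.
#' @return a [hill_curve()] with `rmse` filled in.
#' @export
fit_hill <- function(doses, viability, n_starts = 4L) {
  assert_that(length(doses) == length(viability),
              "doses and viability must have equal length")
  assert_that(length(unique(doses)) >= 4 && any(doses == 0),
              "need >= 4 distinct doses including 0")
  assert_that(all(is.finite(viability)), "viabilities must be finite")
  assert_that(all(doses >= 0), "doses must be non-negative")

  pos <- sort(unique(doses[doses > 0]))
  lo <- c(e0 = 80, e_inf = 0, lec50 = log(min(pos) / 100), h = 0.1)
  hi <- c(e0 = 120, e_inf = 110, lec50 = log(max(pos) * 100), h = 10)

  if (diff(range(viability)) < 1e-8) {
    m <- mean(viability)
    return(hill_curve(e0 = m, e_inf = m, ec50 = max(pos), h = 1,
                      no_effect = TRUE, rmse = 0))
  }

  sse <- function(par) {
    e0 <- par[1]; einf <- par[2]; ec50 <- exp(par[3]); h <- par[4]
    if (e0 < einf) return(1e12)
    pred <- einf + (e0 - einf) / (1 + (doses / ec50)^h)
    sum((pred - viability)^2)
  }

  v0 <- viability[doses == 0][1]
  # ec50 initial guess: dose at which the response crosses halfway between
  # its extremes (log-linear interpolation), refined from a slope grid
  vmin <- min(viability); vmax <- max(viability)
  half <- (vmin + vmax) / 2
  ord <- order(doses)
  dv <- viability[ord][doses[ord] > 0]
  dd <- doses[ord][doses[ord] > 0]
  cross <- which(dv <= half)[1]
  ec_guess <- if (is.na(cross)) max(pos)
              else if (cross == 1) dd[1]
              else exp(stats::approx(dv[c(cross - 1, cross)],
                                     log(dd[c(cross - 1, cross)]),
                                     xout = half, ties = "ordered")$y)
  if (!is.finite(ec_guess) || ec_guess <= 0) ec_guess <- stats::median(pos)
  starts <- lapply(c(0.5, 1, 2, 4)[seq_len(min(4L, n_starts))], function(hh) {
    c(min(max(v0, 80), 120), min(max(vmin, 0), 110),
      min(max(log(ec_guess), lo[3]), hi[3]), hh)
  })

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, sse, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  assert_that(!is.null(best), "Hill fit failed for all starting points")
  p <- best$par
  rmse <- sqrt(best$value / length(viability))
  e0 <- p[1]; einf <- min(p[2], p[1])
  no_eff <- (e0 - einf) < 1e-6
  hill_curve(e0 = e0, e_inf = if (no_eff) e0 else einf,
             ec50 = exp(p[3]), h = p[4], no_effect = no_eff, rmse = rmse)
}
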