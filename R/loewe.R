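#' A single 6x6 dose-matrix combination experiment
#'
#' Container for one combination experiment: dose vectors for the two drugs
#' (index 1 is the zero dose) and a 6x6 viability matrix in % of untreated
#' control. Row 1 holds the drug-B monotherapy (dose_a = 0), column 1 the
#' drug-A monotherapy (dose_b = 0), and entry \[1, 1\] the untreated control.
#'
#' @param combo_id combination identifier.
#' @param cell_id cell line identifier.
#' @param doses_a,doses_b length-6 concentration vectors (uM), first entry 0,
#'   strictly increasing thereafter.
#' @param viability 6x6 numeric matrix, rows indexed by `doses_a`, columns by
#'   `doses_b`.
#' @return object of class `dose_response_matrix`.
#' @export
dose_response_matrix <- function(combo_id, cell_id, doses_a, doses_b,
                                 viability) {
  assert_that(length(doses_a) == 6 && length(doses_b) == 6,
              "dose vectors must have length 6")
  assert_that(doses_a[1] == 0 && doses_b[1] == 0,
              "first dose on each axis must be 0")
  assert_that(all(diff(doses_a[-1]) > 0) && all(doses_a[-1] > 0) &&
              all(diff(doses_b[-1]) > 0) && all(doses_b[-1] > 0),
              "positive doses must be strictly increasing")
  viability <- as.matrix(viability)
  assert_that(all(dim(viability) == c(6, 6)), "viability must be 6x6")
  assert_that(all(is.finite(viability)), "viabilities must be finite")
  structure(list(combo_id = combo_id, cell_id = cell_id,
                 doses_a = as.numeric(doses_a), doses_b = as.numeric(doses_b),
                 viability = unname(viability)),
            class = "dose_response_matrix")
}

#' @export
print.dose_response_matrix <- function(x, ...) {
  cat(sprintf("6x6 combination experiment %s in %s\n", x$combo_id, x$cell_id))
  invisible(x)
}

#' Loewe-additive reference surface
#'
#' For each pair of positive doses (a, b) the Loewe-additive effect E solves
#' \deqn{a / D_A(E) + b / D_B(E) = 1}
#' where \eqn{D_X(E)} is the inverse of drug X's Hill curve. The equation is
#' solved by bisection over the common reachable effect interval
#' `(max(e_inf), min(e0))` to |residual| < 1e-8 (<= 200 iterations).
#' When the interval is empty or one drug cannot reach the required effect
#' (e.g. a flat no-effect curve), the cell falls back to the
#' highest-single-agent effect `min(E_A(a), E_B(b))` and is flagged.
#' Monotherapy row/column hold the fitted single-drug curves and \[1, 1\]
#' holds `min(e0_a, e0_b)`.
#'
#' @param curve_a,curve_b fitted [hill_curve()]s for drugs A and B.
#' @param doses_a,doses_b length-6 dose vectors (first entry 0).
#' @return 6x6 % viability matrix with logical attribute `fallback`
#'   (6x6, TRUE where the highest-single-agent fallback was used).
#' @export
loewe_surface <- function(curve_a, curve_b, doses_a, doses_b) {
  assert_that(length(doses_a) == 6 && length(doses_b) == 6,
              "dose vectors must have length 6")
  E <- matrix(NA_real_, 6, 6)
  fallback <- matrix(FALSE, 6, 6)
  E[1, 1] <- min(curve_a$e0, curve_b$e0)
  E[, 1] <- hill_response(curve_a, doses_a)
  E[1, ] <- hill_response(curve_b, doses_b)
  E[1, 1] <- min(curve_a$e0, curve_b$e0)

  lo_eff <- max(curve_a$e_inf, curve_b$e_inf)
  hi_eff <- min(curve_a$e0, curve_b$e0)
  degenerate <- curve_a$no_effect || curve_b$no_effect ||
    (hi_eff - lo_eff) < 1e-9

  A <- rep(doses_a[2:6], times = 5)
  B <- rep(doses_b[2:6], each = 5)
  hsa <- pmin(hill_response(curve_a, A), hill_response(curve_b, B))

  if (degenerate) {
    E[2:6, 2:6] <- matrix(hsa, 5, 5)
    fallback[2:6, 2:6] <- TRUE
    attr(E, "fallback") <- fallback
    return(E)
  }

  # residual of the Loewe equation, vectorised over all 25 combination
  # cells; increasing in eff (-> -1 at the lower effect bound, -> +Inf at
  # the upper), so plain bisection applies
  resid <- function(eff) {
    da <- curve_a$ec50 *
      ((curve_a$e0 - eff) / (eff - curve_a$e_inf))^(1 / curve_a$h)
    db <- curve_b$ec50 *
      ((curve_b$e0 - eff) / (eff - curve_b$e_inf))^(1 / curve_b$h)
    A / da + B / db - 1
  }
  eps <- (hi_eff - lo_eff) * 1e-12
  lo <- rep(lo_eff + eps, 25); hi <- rep(hi_eff - eps, 25)
  flo <- resid(lo); fhi <- resid(hi)
  bad <- !is.finite(flo) | !is.finite(fhi) | flo > 0 | fhi < 0
  sol <- hsa
  act <- which(!bad)
  if (length(act)) {
    for (it in seq_len(200)) {
      mid <- (lo[act] + hi[act]) / 2
      da <- curve_a$ec50 *
        ((curve_a$e0 - mid) / (mid - curve_a$e_inf))^(1 / curve_a$h)
      db <- curve_b$ec50 *
        ((curve_b$e0 - mid) / (mid - curve_b$e_inf))^(1 / curve_b$h)
      fm <- A[act] / da + B[act] / db - 1
      up <- !is.finite(fm) | fm > 0
      hi[act[up]] <- mid[up]
      lo[act[!up]] <- mid[!up]
      if (all(is.finite(fm) & abs(fm) < 1e-8)) break
    }
    sol[act] <- (lo[act] + hi[act]) / 2
  }
  E[2:6, 2:6] <- matrix(sol, 5, 5)
  fallback[2:6, 2:6] <- matrix(bad, 5, 5)
  attr(E, "fallback") <- fallback
  E
}

#' Synergy distribution over the combination grid
#'
#' Difference between the Loewe-additive reference and the observed surface
#' over the 25 true-combination cells: `D(a, b) = E_additive - E_observed`.
#' Positive values mean the observed viability falls below the additive
#' expectation, i.e. synergy.
#'
#' @param observed a [dose_response_matrix()] or its 6x6 viability matrix.
#' @param additive 6x6 Loewe reference matrix from [loewe_surface()].
#' @return 5x5 matrix of % viability differences.
#' @export
synergy_distribution <- function(observed, additive) {
  obs <- if (inherits(observed, "dose_response_matrix"))
    observed$viability else as.matrix(observed)
  additive <- as.matrix(additive)
  assert_that(all(dim(obs) == c(6, 6)) && all(dim(additive) == c(6, 6)),
              "observed and additive must both be 6x6")
  additive[2:6, 2:6] - obs[2:6, 2:6]
}

#' Integrate the synergy distribution to a single capped score
#'
#' Trapezoidal integration of the 5x5 synergy distribution over
#' (log10 dose A, log10 dose B), normalised by the integration rectangle's
#' area (an area-weighted mean, so a constant distribution of +10 scores 10),
#' then capped to \[-100, 100\].
#'
#' @param dist 5x5 synergy distribution from [synergy_distribution()].
#' @param doses_a,doses_b the experiment's dose vectors (length 6 with the
#'   leading 0, or the 5 positive doses).
#' @param cap cap magnitude (default 100).
#' @return single synergy score.
#' @export
synergy_score <- function(dist, doses_a, doses_b, cap = 100) {
  dist <- as.matrix(dist)
  pa <- doses_a[doses_a > 0]; pb <- doses_b[doses_b > 0]
  assert_that(length(pa) >= 2 && length(pb) >= 2,
              "need >= 2 positive doses on each axis")
  assert_that(all(dim(dist) == c(length(pa), length(pb))),
              "distribution shape must match positive dose grid")
  la <- log10(pa); lb <- log10(pb)
  wa <- trapezoid_weights(la); wb <- trapezoid_weights(lb)
  raw <- as.numeric(t(wa) %*% dist %*% wb) /
    (diff(range(la)) * diff(range(lb)))
  max(min(raw, cap), -cap)
}

trapezoid_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

#' Classify an in vitro synergy score
#'
#' Scores >= 20 are synergistic, <= -20 antagonistic, the rest additive.
#'
#' @param score numeric synergy score(s).
#' @return character vector of classes.
#' @export
classify_in_vitro <- function(score) {
  assert_that(all(is.finite(score)), "score must be finite")
  ifelse(score >= 20, "synergistic",
         ifelse(score <= -20, "antagonistic", "additive"))
}

#' Score one combination experiment
#'
#' Full per-experiment pipeline: re-fit both monotherapy Hill curves from
#' the matrix's first row/column (monotherapies are rescreened within every
#' experiment), build the Loewe reference, form the synergy distribution and
#' integrate it to the capped score.
#'
#' @param drm a [dose_response_matrix()].
#' @return list with `score`, `class`, fitted `curve_a`/`curve_b`,
#'   `additive` surface, `distribution`, `n_fallback` (Loewe fallback cells)
#'   and per-curve `rmse`.
#' @export
score_experiment <- function(drm) {
  assert_that(inherits(drm, "dose_response_matrix"),
              "drm must be a dose_response_matrix")
  curve_a <- fit_hill(drm$doses_a, drm$viability[, 1])
  curve_b <- fit_hill(drm$doses_b, drm$viability[1, ])
  additive <- loewe_surface(curve_a, curve_b, drm$doses_a, drm$doses_b)
  dist <- synergy_distribution(drm, additive)
  s <- synergy_score(dist, drm$doses_a, drm$doses_b)
  list(combo_id = drm$combo_id, cell_id = drm$cell_id,
       score = s, class = classify_in_vitro(s),
       curve_a = curve_a, curve_b = curve_b,
       additive = additive, distribution = dist,
       n_fallback = sum(attr(additive, "fallback")),
       rmse_a = curve_a$rmse, rmse_b = curve_b$rmse)
}

#' Score a whole screen
#'
#' @param screen list of [dose_response_matrix()] objects.
#' @return data.frame of synergy records: `combo_id`, `cell_id`, `score`,
#'   `class`, `rmse_a`, `rmse_b`, `n_fallback`.
#' @export
score_screen <- function(screen) {
  assert_that(length(screen) > 0, "screen must contain experiments")
  rows <- lapply(screen, function(drm) {
    r <- score_experiment(drm)
    data.frame(combo_id = r$combo_id, cell_id = r$cell_id,
               score = r$score, class = r$class,
               rmse_a = r$rmse_a, rmse_b = r$rmse_b,
               n_fallback = r$n_fallback, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
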