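## ---------------------------------------------------------------------------
## Clonogenic module: plating efficiency, surviving fractions and the
## single-hit multi-target fit  S(D) = 1 - (1 - exp(-D/D0))^n.
## D0 is the reciprocal of the ln-survival slope in the linear range, n the
## back-extrapolated intercept, Dq = D0 * ln(n) the shoulder width (the dose
## at which the extrapolated linear tail crosses 100% survival).
## ---------------------------------------------------------------------------

#' Plating efficiency from 0 Gy dishes
#'
#' @param table a `colony_counts` data.frame (`dose_gy`, `dish_id`,
#'   `cells_seeded`, `colonies`).
#' @return list with `pe` (mean colonies/cells over 0 Gy dishes), `se`
#'   (`NA` with a single dish) and `n_dishes`.
#' @export
plating_efficiency <- function(table) {
  z <- table[table$dose_gy == 0, , drop = FALSE]
  if (nrow(z) == 0) stopf("no 0 Gy dishes: plating efficiency undefined")
  ratios <- z$colonies / z$cells_seeded
  list(pe = mean(ratios),
       se = if (length(ratios) >= 2) stats::sd(ratios) / sqrt(length(ratios)) else NA_real_,
       n_dishes = length(ratios))
}

#' Surviving fractions per dose
#'
#' `SF(D)` is the mean over dishes of `colonies / (cells_seeded * pe)`; the
#' SE comes from the replicate spread.  Dishes with zero colonies enter the
#' mean (they carry information) but a dose whose mean SF is zero cannot
#' enter the ln-regression and is flagged.
#'
#' @param table a `colony_counts` data.frame.
#' @param pe plating efficiency in (0, 1]; default recomputed from the 0 Gy
#'   dishes of `table` (so SF(0) = 1 by construction).
#' @return data.frame of class `survival_points` with columns `dose_gy`,
#'   `surviving_fraction`, `se`, `n_dishes`, `n_zero_dishes`.
#' @export
survival_fraction <- function(table, pe = NULL) {
  if (is.null(pe)) pe <- plating_efficiency(table)$pe
  if (!is.numeric(pe) || pe <= 0 || pe > 1) stopf("pe must be in (0, 1]")
  doses <- sort(unique(table$dose_gy))
  out <- do.call(rbind, lapply(doses, function(d) {
    sub <- table[table$dose_gy == d, , drop = FALSE]
    sf <- sub$colonies / (sub$cells_seeded * pe)
    data.frame(dose_gy = d, surviving_fraction = mean(sf),
               se = if (nrow(sub) >= 2) stats::sd(sf) / sqrt(nrow(sub)) else NA_real_,
               n_dishes = nrow(sub), n_zero_dishes = sum(sub$colonies == 0))
  }))
  class(out) <- c("survival_points", "data.frame")
  out
}

#' Fit the single-hit multi-target model to survival points
#'
#' Primary (linear) stage: unweighted least squares of `ln(SF)` on dose over
#' irradiated doses; `D0 = -1/slope`, `n = exp(intercept)` (clamped at 1),
#' `Dq = D0 * ln(n)`.  By default the regression is restricted to the linear
#' range, taken as doses at least twice the shoulder estimate `Dq` from an
#' initial all-dose fit (one iteration); `all_doses = TRUE` regresses on all
#' irradiated doses.  A secondary nonlinear refinement of the full
#' `S(D) = 1 - (1 - exp(-D/D0))^n` on all points (including 0 Gy) is
#' attempted from the linear estimates and stored under `refined`; the
#' linear parameters remain primary.
#'
#' @param points a [survival_fraction()] result (or data.frame with
#'   `dose_gy`, `surviving_fraction`).
#' @param all_doses regress on all irradiated doses instead of the
#'   iterated linear range.
#' @return object of class `multitarget_fit` with `d0`, `n_extrap`, `dq`,
#'   `slope_se`, `r_squared`, `linear_range_doses`, `refined` (list or
#'   NULL), `points`.
#' @export
fit_multitarget <- function(points, all_doses = FALSE) {
  pts <- points[points$dose_gy > 0 & points$surviving_fraction > 0, , drop = FALSE]
  dropped <- points$dose_gy[points$dose_gy > 0 & points$surviving_fraction <= 0]
  if (length(dropped))
    message(sprintf("fit_multitarget: dropping dose(s) %s with SF <= 0 from ln-regression",
                    paste(dropped, collapse = ", ")))
  if (length(unique(pts$dose_gy)) < 3)
    stopf("need >= 3 distinct irradiated doses with SF > 0 (got %d)",
          length(unique(pts$dose_gy)))
  do_lm <- function(sub) stats::lm(log(surviving_fraction) ~ dose_gy, data = sub)
  fit0 <- do_lm(pts)
  slope <- stats::coef(fit0)[["dose_gy"]]
  if (slope >= 0) stopf("no killing detected: ln(SF) slope is non-negative")
  range_used <- pts
  if (!all_doses) {
    d0_hat <- -1 / slope
    n_hat <- max(exp(stats::coef(fit0)[["(Intercept)"]]), 1)
    dq_hat <- d0_hat * log(n_hat)
    keep <- pts$dose_gy >= 2 * dq_hat
    if (length(unique(pts$dose_gy[keep])) >= 3) range_used <- pts[keep, , drop = FALSE]
  }
  fit <- do_lm(range_used)
  slope <- stats::coef(fit)[["dose_gy"]]
  if (slope >= 0) stopf("no killing detected in the linear range")
  d0 <- -1 / slope
  n_extrap <- max(exp(stats::coef(fit)[["(Intercept)"]]), 1)
  dq <- d0 * log(n_extrap)
  sm <- summary(fit)
  refined <- tryCatch({
    nl <- stats::nls(surviving_fraction ~ 1 - (1 - exp(-dose_gy / d0))^n,
                     data = points,
                     start = list(d0 = d0, n = n_extrap),
                     algorithm = "port", lower = c(1e-3, 1))
    co <- stats::coef(nl)
    list(d0 = unname(co["d0"]), n_extrap = unname(co["n"]),
         dq = unname(co["d0"] * log(co["n"])))
  }, error = function(e) NULL)
  structure(list(d0 = d0, n_extrap = n_extrap, dq = dq,
                 slope_se = sm$coefficients["dose_gy", "Std. Error"],
                 r_squared = sm$r.squared,
                 linear_range_doses = sort(unique(range_used$dose_gy)),
                 refined = refined, primary = "linear",
                 points = as.data.frame(points)),
            class = "multitarget_fit")
}

#' @export
print.multitarget_fit <- function(x, ...) {
  cat(sprintf("Single-hit multi-target fit (linear stage primary)\n"))
  cat(sprintf("  D0 = %.3f Gy, n = %.3f, Dq = %.3f Gy (R^2 = %.4f)\n",
              x$d0, x$n_extrap, x$dq, x$r_squared))
  cat(sprintf("  linear range: %s Gy\n",
              paste(x$linear_range_doses, collapse = ", ")))
  if (!is.null(x$refined))
    cat(sprintf("  nonlinear refinement: D0 = %.3f Gy, n = %.3f, Dq = %.3f Gy\n",
                x$refined$d0, x$refined$n_extrap, x$refined$dq))
  invisible(x)
}

#' Predict survival from a multi-target fit
#'
#' Evaluates `S(D) = 1 - (1 - exp(-D/D0))^n` with `n = exp(Dq/D0)`.
#'
#' @param fit a [fit_multitarget()] result, or any list with `d0` and either
#'   `n_extrap` or `dq`.
#' @param dose dose(s) in Gy, >= 0.
#' @return surviving fraction(s).
#' @export
predict_survival <- function(fit, dose) {
  if (any(dose < 0)) stopf("dose must be >= 0")
  n <- if (!is.null(fit$n_extrap)) fit$n_extrap else exp(fit$dq / fit$d0)
  multitarget_survival(dose, fit$d0, n)
}
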