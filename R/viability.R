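## ---------------------------------------------------------------------------
## MTT viability module.  Viability per dose is
##   (mean OD_treated - mean OD_blank) / (mean OD_untreated - mean OD_blank) * 100,
## the standard normalisation against the killed-blank and untreated strips
## of the plate.  Below ~20% the formazan signal stops tracking dose (the
## assay's limit of quantification), so doses whose viability cannot be
## distinguished from that floor are flagged, never truncated.
## ---------------------------------------------------------------------------

## flag rule: a dose is at the LOQ when its viability minus a one-sided
## normal 97.5% margin does not clear the floor (strict <= when SE unknown)
.at_loq <- function(v, se, loq) {
  m <- ifelse(is.na(se), 0, stats::qnorm(0.975) * se)
  v - m <= loq
}

#' Compute per-dose viability from an OD plate
#'
#' Per-well viabilities are formed against the plate-mean blank and
#' untreated ODs, then averaged per dose; the SE comes from the well
#' replicates.
#'
#' @param plate an `od_table` data.frame with columns `condition`
#'   (`treated`, `untreated`, `blank`, `positive_control`), `dose_gy`,
#'   `od562`.
#' @param loq_pct limit of quantification in percent (default 20).
#' @return data.frame of class `viability_table` with columns `dose_gy`,
#'   `viability_pct`, `se`, `n_wells`, `at_loq`; attribute `loq_pct`.
#' @export
compute_viability <- function(plate, loq_pct = 20) {
  if (!all(c("condition", "od562") %in% names(plate)))
    stopf("plate needs columns condition and od562")
  blank <- mean(plate$od562[plate$condition == "blank"])
  untr <- mean(plate$od562[plate$condition == "untreated"])
  if (!is.finite(blank) || !is.finite(untr))
    stopf("plate needs >= 1 blank and >= 1 untreated well")
  if (untr <= blank)
    stopf("assay window collapsed: mean untreated OD (%.3f) <= mean blank OD (%.3f)",
          untr, blank)
  tr <- plate[plate$condition == "treated", , drop = FALSE]
  if (nrow(tr) == 0) stopf("plate has no treated wells")
  doses <- sort(unique(tr$dose_gy))
  out <- do.call(rbind, lapply(doses, function(d) {
    v <- (tr$od562[tr$dose_gy == d] - blank) / (untr - blank) * 100
    se <- if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    data.frame(dose_gy = d, viability_pct = mean(v), se = se,
               n_wells = length(v),
               at_loq = .at_loq(mean(v), se, loq_pct))
  }))
  attr(out, "loq_pct") <- loq_pct
  class(out) <- c("viability_table", "data.frame")
  out
}

#' Pool viability tables across independent experiments
#'
#' Pools wells across experiments on a matching dose grid: the pooled mean
#' weights experiment means by their well counts, and the pooled SE uses the
#' within-experiment pooled standard deviation over the total number of
#' wells (the "SE of N wells" convention for combined repeats).
#'
#' @param tables list of [compute_viability()] results on identical dose
#'   grids.
#' @param loq_pct limit of quantification for flagging the pooled values.
#' @return a pooled `viability_table`.
#' @export
dose_response_summary <- function(tables, loq_pct = 20) {
  if (length(tables) == 1) return(tables[[1]])
  grids <- lapply(tables, function(t) sort(t$dose_gy))
  for (i in seq_along(grids)[-1]) {
    if (!isTRUE(all.equal(grids[[1]], grids[[i]]))) {
      only1 <- setdiff(grids[[1]], grids[[i]])
      only2 <- setdiff(grids[[i]], grids[[1]])
      stopf("mismatched dose grids between experiments 1 and %d: only in 1 {%s}, only in %d {%s}",
            i, paste(only1, collapse = ","), i, paste(only2, collapse = ","))
    }
  }
  doses <- grids[[1]]
  out <- do.call(rbind, lapply(doses, function(d) {
    rows <- lapply(tables, function(t) t[t$dose_gy == d, ])
    n_i <- vapply(rows, function(r) r$n_wells, numeric(1))
    m_i <- vapply(rows, function(r) r$viability_pct, numeric(1))
    s_i <- vapply(rows, function(r) ifelse(is.na(r$se), 0, r$se * sqrt(r$n_wells)),
                  numeric(1))
    N <- sum(n_i)
    m <- sum(n_i * m_i) / N
    df <- sum(n_i - 1)
    sd_p <- if (df > 0) sqrt(sum((n_i - 1) * s_i^2) / df) else NA_real_
    se <- if (is.na(sd_p)) NA_real_ else sd_p / sqrt(N)
    data.frame(dose_gy = d, viability_pct = m, se = se, n_wells = N,
               at_loq = .at_loq(m, se, loq_pct))
  }))
  attr(out, "loq_pct") <- loq_pct
  class(out) <- c("viability_table", "data.frame")
  out
}
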