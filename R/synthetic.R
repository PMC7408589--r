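## ---------------------------------------------------------------------------
## Synthetic-data module: seeded generators for flow events, colony counts,
## OD plates and G2-arrest time courses.  Defaults encode the experimental
## design the analysis stages assume: ~2e4 events per cytometry sample, six
## dishes per dose repeated in three independent experiments with ~50
## colonies per dish at a plating efficiency of 0.64, and 96-well MTT plates
## with blank and untreated strips and a ~20% viability floor.
## ---------------------------------------------------------------------------

#' Ground truth for a DNA-content (cell-cycle) population mixture
#'
#' Describes the five subpopulations of a propidium-iodide DNA-content
#' distribution: sub-G1 (fragmented DNA), G1, S, G2 and polyploid cells.
#' Fluorescence area scales with DNA content, so G2 sits at twice the G1
#' channel, S in between, sub-G1 below G1 and polyploid at twice G2.
#'
#' @param fractions named numeric vector of population fractions over a
#'   subset of `subG1, G1, S, G2, polyploid`; must be non-negative and sum
#'   to 1.
#' @param g1_mean G1 peak position in fluorescence channels.
#' @param g1_cv coefficient of variation of the peaks (sd_k = g1_cv * mu_k,
#'   except S, see `s_sigma_factor`).
#' @param relative_means named multiples of `g1_mean` per population;
#'   must be strictly increasing in the order subG1 < G1 < S < G2 <
#'   polyploid.
#' @param doublet_fraction fraction of recorded events that are G1-G1
#'   doublets (two cells in one droplet: summed area, widened pulse).
#' @param s_sigma_factor S-phase sd as a multiple of the G1 sd; S cells span
#'   the G1-to-G2 content range so their single Gaussian is broader.
#' @param width_mean mean pulse width of a singlet event (a.u.).
#' @param width_cv coefficient of variation of singlet pulse width.
#' @param doublet_width_factor doublet pulse width as a multiple of the mean
#'   singlet width.
#' @return an object of class `cellcycle_truth`.
#' @export
#' @examples
#' cellcycle_truth(c(G1 = 0.34, S = 0.25, G2 = 0.36, subG1 = 0.03, polyploid = 0.02))
cellcycle_truth <- function(fractions,
                            g1_mean = 200,
                            g1_cv = 0.05,
                            relative_means = c(subG1 = 0.5, G1 = 1, S = 1.5,
                                               G2 = 2, polyploid = 4),
                            doublet_fraction = 0,
                            s_sigma_factor = 2,
                            width_mean = 100,
                            width_cv = 0.05,
                            doublet_width_factor = 1.6) {
  f <- as_fractions(fractions)
  rm_ <- stats::setNames(numeric(5), .pop_levels)
  if (is.null(names(relative_means)) || !all(.pop_levels %in% names(relative_means)))
    stopf("relative_means must name all of {%s}", paste(.pop_levels, collapse = ", "))
  rm_[] <- as.numeric(relative_means[.pop_levels])
  if (any(diff(rm_) <= 0))
    stopf("relative_means must be strictly increasing in order %s",
          paste(.pop_levels, collapse = " < "))
  if (!is.numeric(g1_cv) || g1_cv <= 0) stopf("g1_cv must be > 0")
  if (doublet_fraction < 0 || doublet_fraction >= 1)
    stopf("doublet_fraction must be in [0, 1)")
  if (g1_mean <= 0) stopf("g1_mean must be > 0")
  if (doublet_width_factor <= 1)
    stopf("doublet_width_factor must exceed 1 (doublets are wider than singlets)")
  structure(list(fractions = f, g1_mean = g1_mean, g1_cv = g1_cv,
                 relative_means = rm_, doublet_fraction = doublet_fraction,
                 s_sigma_factor = s_sigma_factor, width_mean = width_mean,
                 width_cv = width_cv,
                 doublet_width_factor = doublet_width_factor),
            class = "cellcycle_truth")
}

## per-population area mean and sd implied by a truth object
.pop_moments <- function(truth) {
  mu <- truth$relative_means * truth$g1_mean
  sd <- truth$g1_cv * mu
  sd["S"] <- truth$s_sigma_factor * truth$g1_cv * truth$g1_mean
  list(mu = mu, sd = sd)
}

#' Ground truth for a clonogenic survival experiment
#'
#' Parameters of the single-hit multi-target survival model
#' `S(D) = 1 - (1 - exp(-D/d0))^n` together with the experimental design of a
#' colony-forming-ability assay.  When `cells_seeded` is `NULL` the number of
#' cells plated at each dose is adjusted so that roughly `target_colonies`
#' colonies grow per dish, the standard design choice.
#'
#' @param d0 dose (Gy) reducing survival by 1/e in the exponential region.
#' @param n_extrap extrapolation number (>= 1); `dq = d0 * log(n_extrap)`.
#' @param plating_efficiency fraction of unirradiated cells forming colonies.
#' @param doses irradiation doses in Gy (0 Gy is added if absent; it anchors
#'   the plating efficiency).
#' @param replicates dishes per dose within one experiment.
#' @param experiments number of independent experiment repeats.
#' @param cells_seeded cells plated per dish (scalar), or `NULL` for
#'   dose-adjusted seeding.
#' @param target_colonies expected colonies per dish under dose-adjusted
#'   seeding.
#' @return an object of class `survival_truth`.
#' @export
survival_truth <- function(d0 = 1.45, n_extrap = 1.327,
                           plating_efficiency = 0.64,
                           doses = c(0, 1, 2, 4, 6, 8, 10),
                           replicates = 6, experiments = 3,
                           cells_seeded = NULL, target_colonies = 50) {
  if (d0 <= 0) stopf("d0 must be > 0")
  if (n_extrap < 1) stopf("n_extrap must be >= 1")
  if (plating_efficiency <= 0 || plating_efficiency > 1)
    stopf("plating_efficiency must be in (0, 1]")
  if (any(doses < 0)) stopf("doses must be >= 0")
  if (!0 %in% doses) doses <- c(0, doses)
  structure(list(d0 = d0, n_extrap = n_extrap,
                 plating_efficiency = plating_efficiency,
                 doses = sort(unique(doses)), replicates = replicates,
                 experiments = experiments, cells_seeded = cells_seeded,
                 target_colonies = target_colonies),
            class = "survival_truth")
}

#' Ground truth for an MTT viability dose-response
#'
#' @param dose_to_viability named numeric vector mapping dose in Gy
#'   (names) to true viability in percent. The default traces a
#'   dose-dependent decline reaching the assay floor beyond 8 Gy.
#' @param od_untreated_mean mean optical density of untreated wells.
#' @param od_blank_mean mean optical density of blank (killed) wells.
#' @param noise_sd Gaussian OD noise per well.
#' @param floor_pct viability floor in percent below which the formazan
#'   signal no longer decreases (the MTT limit of quantification).
#' @return an object of class `viability_truth`.
#' @export
viability_truth <- function(dose_to_viability = c("0" = 100, "1" = 92,
                                                  "2" = 75, "4" = 55,
                                                  "6" = 38, "8" = 20,
                                                  "10" = 14, "12" = 10),
                            od_untreated_mean = 0.9,
                            od_blank_mean = 0.1,
                            noise_sd = 0.02,
                            floor_pct = 20) {
  v <- as.numeric(dose_to_viability)
  if (any(v < 0 | v > 100)) stopf("viabilities must be in [0, 100]")
  if (is.null(names(dose_to_viability)))
    stopf("dose_to_viability must be named by dose (Gy)")
  if (od_untreated_mean <= od_blank_mean)
    stopf("od_untreated_mean must exceed od_blank_mean")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(dose_to_viability = dose_to_viability,
                 od_untreated_mean = od_untreated_mean,
                 od_blank_mean = od_blank_mean, noise_sd = noise_sd,
                 floor_pct = floor_pct),
            class = "viability_truth")
}

#' Simulate event-level flow-cytometry data
#'
#' Draws events multinomially over the five populations; each population's
#' fluorescence area is Gaussian around `relative_mean * g1_mean` with a
#' CV-scaled sd.  A `doublet_fraction` of events are G1-G1 doublets: the sum
#' of two independent G1 area draws with a pulse width around
#' `doublet_width_factor` times the mean singlet width, which is what the
#' width-vs-area gate later exploits.
#'
#' @param truth a [cellcycle_truth()] object.
#' @param n_events number of events to record (> 0).
#' @param seed integer seed; identical seed and truth give an identical
#'   table.
#' @return a `data.frame` of class `flow_events` with columns `event_id`,
#'   `area`, `width` and (simulation bookkeeping, dropped on CSV export)
#'   `population`.
#' @export
simulate_flow_events <- function(truth, n_events, seed = 1L) {
  if (!inherits(truth, "cellcycle_truth")) stopf("truth must be a cellcycle_truth")
  if (n_events <= 0) stopf("n_events must be > 0")
  set.seed(child_seed(seed, 1L))
  n_doub <- stats::rbinom(1L, n_events, truth$doublet_fraction)
  n_sing <- n_events - n_doub
  mom <- .pop_moments(truth)
  counts <- as.vector(stats::rmultinom(1L, n_sing, truth$fractions))
  pop <- rep(.pop_levels, counts)
  area <- stats::rnorm(n_sing, mean = mom$mu[pop], sd = mom$sd[pop])
  width <- stats::rnorm(n_sing, truth$width_mean,
                        truth$width_cv * truth$width_mean)
  if (n_doub > 0) {
    a2 <- stats::rnorm(n_doub, mom$mu["G1"], mom$sd["G1"]) +
      stats::rnorm(n_doub, mom$mu["G1"], mom$sd["G1"])
    w2 <- stats::rnorm(n_doub,
                       truth$doublet_width_factor * truth$width_mean,
                       truth$width_cv * truth$width_mean)
    pop <- c(pop, rep("doublet", n_doub))
    area <- c(area, a2)
    width <- c(width, w2)
  }
  ord <- sample.int(length(area))
  out <- data.frame(event_id = sprintf("ev%07d", seq_along(area)),
                    area = pmax(area[ord], 0),
                    width = pmax(width[ord], 0),
                    population = pop[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("flow_events", "data.frame")
  out
}

#' Single-hit multi-target surviving fraction
#'
#' `S(D) = 1 - (1 - exp(-D/d0))^n`.
#'
#' @param dose dose in Gy (vectorised, >= 0).
#' @param d0 characteristic dose (Gy).
#' @param n extrapolation number.
#' @return surviving fraction in (0, 1].
#' @export
multitarget_survival <- function(dose, d0, n) {
  if (any(dose < 0)) stopf("dose must be >= 0")
  if (d0 <= 0) stopf("d0 must be > 0")
  1 - (1 - exp(-dose / d0))^n
}

#' Simulate a colony-count table for a clonogenic assay
#'
#' Colonies per dish are Poisson around
#' `cells_seeded * plating_efficiency * S(D)` under the single-hit
#' multi-target model. Dishes at 0 Gy are always included; they carry the
#' plating-efficiency information.
#'
#' @param truth a [survival_truth()] object.
#' @param seed integer seed.
#' @return a `data.frame` of class `colony_counts` with columns `dose_gy`,
#'   `dish_id`, `cells_seeded`, `colonies`.
#' @export
simulate_colony_counts <- function(truth, seed = 1L) {
  if (!inherits(truth, "survival_truth")) stopf("truth must be a survival_truth")
  set.seed(child_seed(seed, 2L))
  sf <- multitarget_survival(truth$doses, truth$d0, truth$n_extrap)
  seeded <- if (is.null(truth$cells_seeded)) {
    pmax(round(truth$target_colonies / (truth$plating_efficiency * sf)), 1)
  } else rep(truth$cells_seeded, length(truth$doses))
  rows <- expand.grid(dish = seq_len(truth$replicates),
                      exp = seq_len(truth$experiments),
                      idose = seq_along(truth$doses))
  lambda <- seeded[rows$idose] * truth$plating_efficiency * sf[rows$idose]
  out <- data.frame(dose_gy = truth$doses[rows$idose],
                    dish_id = sprintf("e%d_d%d", rows$exp, rows$dish),
                    cells_seeded = seeded[rows$idose],
                    colonies = stats::rpois(nrow(rows), lambda),
                    stringsAsFactors = FALSE)
  class(out) <- c("colony_counts", "data.frame")
  out
}

#' Simulate a 96-well MTT optical-density plate
#'
#' Treated wells read
#' `OD = od_blank_mean + (od_untreated_mean - od_blank_mean) *
#' max(viability, floor_pct)/100 + noise`; the floor reproduces the
#' saturation of the formazan signal at the assay's limit of quantification.
#' Blank and untreated strips are generated with the same noise model; an
#' ethanol positive-control strip sits at `positive_viability`.
#'
#' @param truth a [viability_truth()] object.
#' @param wells_per_condition replicate wells per condition (>= 1).
#' @param seed integer seed.
#' @param positive_viability true viability (%) of the cytotoxic positive
#'   control, or `NULL` to omit the strip.
#' @return a `data.frame` of class `od_table` with columns `well`, `row`,
#'   `col`, `condition`, `dose_gy`, `od562`.
#' @export
simulate_mtt_plate <- function(truth, wells_per_condition = 4, seed = 1L,
                               positive_viability = 5) {
  if (!inherits(truth, "viability_truth")) stopf("truth must be a viability_truth")
  if (wells_per_condition < 1) stopf("wells_per_condition must be >= 1")
  set.seed(child_seed(seed, 3L))
  doses <- as.numeric(names(truth$dose_to_viability))
  window <- truth$od_untreated_mean - truth$od_blank_mean
  cond <- c("blank", "untreated",
            if (!is.null(positive_viability)) "positive_control",
            rep("treated", length(doses)))
  dose_of <- c(NA, NA, if (!is.null(positive_viability)) NA, doses)
  viab <- c(0, 100,
            if (!is.null(positive_viability)) positive_viability,
            as.numeric(truth$dose_to_viability))
  n <- length(cond) * wells_per_condition
  if (n > 96) stopf("plate layout exceeds 96 wells (%d needed)", n)
  idx <- seq_len(n)
  row_id <- LETTERS[(idx - 1) %/% 12 + 1]
  col_id <- (idx - 1) %% 12 + 1
  ci <- rep(seq_along(cond), each = wells_per_condition)
  od_mean <- ifelse(cond[ci] == "blank", truth$od_blank_mean,
                    truth$od_blank_mean +
                      window * pmax(viab[ci], truth$floor_pct) / 100)
  out <- data.frame(well = paste0(row_id, col_id), row = row_id,
                    col = col_id, condition = cond[ci],
                    dose_gy = dose_of[ci],
                    od562 = pmax(od_mean + stats::rnorm(n, 0, truth$noise_sd), 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("od_table", "data.frame")
  out
}

#' Simulate a G2-arrest time course as event tables
#'
#' The true G2 fraction rises piecewise-linearly from the baseline to
#' `peak_g2` at `peak_time`, then falls back to baseline at `resolve_time`
#' and stays there; G1 and S are rescaled so fractions keep summing to 1
#' (sub-G1 and polyploid are left untouched).  One event table is generated
#' per timepoint.
#'
#' @param baseline a [cellcycle_truth()] giving the unperturbed mixture.
#' @param peak_g2 G2 fraction at the arrest peak (> baseline G2).
#' @param peak_time time of the arrest peak (h).
#' @param resolve_time time at which the arrest has fully resolved (h,
#'   > `peak_time`).
#' @param timepoints sampling times (h), non-empty.
#' @param events_per_point events recorded per sample.
#' @param seed integer seed; each timepoint consumes its own child stream.
#' @return a named list of `flow_events` tables, one per timepoint, with a
#'   `time_h` attribute on each; the list carries the true fractions as
#'   attribute `truth_fractions`.
#' @export
simulate_g2_kinetics <- function(baseline, peak_g2, peak_time, resolve_time,
                                 timepoints, events_per_point = 20000,
                                 seed = 1L) {
  if (!inherits(baseline, "cellcycle_truth")) stopf("baseline must be a cellcycle_truth")
  g2_base <- baseline$fractions[["G2"]]
  if (peak_g2 <= g2_base) stopf("peak_g2 must exceed the baseline G2 fraction")
  if (resolve_time <= peak_time) stopf("resolve_time must exceed peak_time")
  if (length(timepoints) == 0) stopf("timepoints must be non-empty")
  g2_at <- function(t) {
    if (t <= 0) g2_base
    else if (t <= peak_time) g2_base + (peak_g2 - g2_base) * t / peak_time
    else if (t < resolve_time)
      peak_g2 + (g2_base - peak_g2) * (t - peak_time) / (resolve_time - peak_time)
    else g2_base
  }
  fixed <- baseline$fractions[["subG1"]] + baseline$fractions[["polyploid"]]
  g1s_base <- baseline$fractions[["G1"]] + baseline$fractions[["S"]]
  truth_tab <- NULL
  out <- lapply(seq_along(timepoints), function(i) {
    t <- timepoints[i]
    g2 <- g2_at(t)
    scale <- (1 - g2 - fixed) / g1s_base
    if (scale < 0) stopf("peak_g2 too large: G1+S would be negative at t=%g", t)
    f <- baseline$fractions
    f["G2"] <- g2
    f["G1"] <- baseline$fractions[["G1"]] * scale
    f["S"] <- baseline$fractions[["S"]] * scale
    tr <- baseline
    tr$fractions <- f / sum(f)
    truth_tab <<- rbind(truth_tab, c(time_h = t, tr$fractions))
    ev <- simulate_flow_events(tr, events_per_point,
                               seed = child_seed(seed, 100L + i))
    attr(ev, "time_h") <- t
    ev
  })
  names(out) <- sprintf("t%g", timepoints)
  attr(out, "truth_fractions") <- as.data.frame(truth_tab)
  out
}
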