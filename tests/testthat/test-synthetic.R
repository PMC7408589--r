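test_that("truth constructors reject invariant violations by name", {
  expect_error(cellcycle_truth(c(G1 = 0.5, S = 0.4)), "sum to 1")
  expect_error(cellcycle_truth(c(G1 = 1.2, S = -0.2)), ">= 0")
  expect_error(cellcycle_truth(c(G1 = 1),
                               relative_means = c(subG1 = 1.1, G1 = 1, S = 1.5,
                                                  G2 = 2, polyploid = 4)),
               "strictly increasing")
  expect_error(cellcycle_truth(c(G1 = 1), g1_cv = 0), "g1_cv")
  expect_error(cellcycle_truth(c(G1 = 1), doublet_fraction = 1),
               "doublet_fraction")
  expect_error(survival_truth(d0 = -1), "d0")
  expect_error(survival_truth(plating_efficiency = 1.2), "plating_efficiency")
  expect_error(viability_truth(od_untreated_mean = 0.1, od_blank_mean = 0.2),
               "exceed")
})

test_that("generators are deterministic for a fixed seed", {
  tr <- baseline_truth(doublet_fraction = 0.05)
  expect_identical(simulate_flow_events(tr, 5000, seed = 11),
                   simulate_flow_events(tr, 5000, seed = 11))
  st <- survival_truth()
  expect_identical(simulate_colony_counts(st, seed = 4),
                   simulate_colony_counts(st, seed = 4))
  vt <- viability_truth()
  expect_identical(simulate_mtt_plate(vt, seed = 9),
                   simulate_mtt_plate(vt, seed = 9))
  # different seeds differ
  expect_false(identical(simulate_flow_events(tr, 5000, seed = 11),
                         simulate_flow_events(tr, 5000, seed = 12)))
})

test_that("single-population events are Gaussian around g1_mean", {
  tr <- cellcycle_truth(c(G1 = 1), g1_mean = 200, g1_cv = 0.05)
  ev <- simulate_flow_events(tr, 10000, seed = 3)
  se <- 0.05 * 200 / sqrt(10000)
  expect_lt(abs(mean(ev$area) - 200), 3 * se)
  expect_true(all(ev$population == "G1"))
})

test_that("per-population counts respect multinomial sampling", {
  tr <- baseline_truth()
  ev <- simulate_flow_events(tr, 20000, seed = 5)
  tab <- table(factor(ev$population, levels = names(tr$fractions)))
  # binomial 99% bounds per population (oracle: qbinom)
  for (p in names(tr$fractions)) {
    lo <- qbinom(0.005, 20000, tr$fractions[[p]])
    hi <- qbinom(0.995, 20000, tr$fractions[[p]])
    expect_gte(tab[[p]], lo)
    expect_lte(tab[[p]], hi)
  }
  # chi-square goodness of fit across 20 seeds at alpha = 0.01;
  # allow for the expected false-failure rate (P[>=3 of 20] ~ 1e-3)
  fails <- sum(vapply(1:20, function(s) {
    e <- simulate_flow_events(tr, 10000, seed = s)
    o <- table(factor(e$population, levels = names(tr$fractions)))
    suppressWarnings(chisq.test(as.vector(o), p = tr$fractions)$p.value) < 0.01
  }, logical(1)))
  expect_lte(fails, 2)
})

test_that("colony counts follow the multi-target forward model", {
  # dose 0: mean count ~ cells_seeded * PE within Poisson 99% bounds
  st <- survival_truth(doses = c(0, 4), replicates = 10, experiments = 2,
                       cells_seeded = 1000)
  cc <- simulate_colony_counts(st, seed = 8)
  z <- cc$colonies[cc$dose_gy == 0]
  lam0 <- 1000 * st$plating_efficiency
  expect_gte(sum(z), qpois(0.005, length(z) * lam0))
  expect_lte(sum(z), qpois(0.995, length(z) * lam0))
  # closed-form oracle at D = 4 Gy, D0 = 1.45, n = 1.327
  s4 <- 1 - (1 - exp(-4 / 1.45))^1.327
  z4 <- cc$colonies[cc$dose_gy == 4]
  lam4 <- 1000 * 0.64 * s4
  expect_gte(sum(z4), qpois(0.005, length(z4) * lam4))
  expect_lte(sum(z4), qpois(0.995, length(z4) * lam4))
})

test_that("n = 1 collapses to the pure single-hit exponential", {
  st <- survival_truth(d0 = 1.5, n_extrap = 1, doses = c(0, 2, 4, 6, 8),
                       replicates = 6, experiments = 3,
                       cells_seeded = 500000, target_colonies = NULL)
  cc <- simulate_colony_counts(st, seed = 2)
  m <- tapply(cc$colonies, cc$dose_gy, mean)
  d <- as.numeric(names(m))
  fit <- lm(log(m[d > 0]) ~ d[d > 0])
  expect_equal(unname(coef(fit)[2]), -1 / 1.5, tolerance = 0.01)
  expect_gt(summary(fit)$r.squared, 0.9999)
})

test_that("noiseless MTT plate reproduces the OD identities", {
  vt <- viability_truth(dose_to_viability = c("0" = 100, "4" = 50, "8" = 0),
                        od_blank_mean = 0.1, od_untreated_mean = 0.9,
                        noise_sd = 0, floor_pct = 0)
  pl <- simulate_mtt_plate(vt, wells_per_condition = 2, seed = 1)
  od <- function(cond, dose = NULL) {
    r <- pl[pl$condition == cond & (is.null(dose) | pl$dose_gy %in% dose), ]
    unique(round(r$od562, 12))
  }
  expect_equal(od("treated", 0), 0.9)   # viability 100 -> untreated OD
  expect_equal(od("treated", 8), 0.1)   # viability 0, floor 0 -> blank OD
  expect_equal(od("treated", 4), 0.5)   # midpoint
  expect_equal(od("untreated"), 0.9)
  expect_equal(od("blank"), 0.1)
})

test_that("G2-arrest time course interpolates baseline -> peak -> baseline", {
  base <- baseline_truth()
  sims <- simulate_g2_kinetics(base, peak_g2 = 0.65, peak_time = 7,
                               resolve_time = 41,
                               timepoints = c(0, 7, 41, 72),
                               events_per_point = 50000, seed = 6)
  emp_g2 <- vapply(sims, function(ev) mean(ev$population == "G2"), numeric(1))
  se <- function(p) sqrt(p * (1 - p) / 50000)
  expect_lt(abs(emp_g2[["t0"]] - 0.36), 3 * se(0.36))   # baseline at t = 0
  expect_lt(abs(emp_g2[["t7"]] - 0.65), 3 * se(0.65))   # peak at peak_time
  expect_lt(abs(emp_g2[["t41"]] - 0.36), 3 * se(0.36))  # resolved
  expect_lt(abs(emp_g2[["t72"]] - 0.36), 3 * se(0.36))
  # stated truth fractions sum to 1 at every timepoint
  tf <- attr(sims, "truth_fractions")
  expect_equal(rowSums(tf[, -1]), rep(1, nrow(tf)), tolerance = 1e-9)
  expect_error(simulate_g2_kinetics(base, peak_g2 = 0.2, peak_time = 7,
                                    resolve_time = 41, timepoints = 0),
               "peak_g2")
  expect_error(simulate_g2_kinetics(base, peak_g2 = 0.65, peak_time = 7,
                                    resolve_time = 41,
                                    timepoints = numeric(0)),
               "timepoints")
})
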