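# Fixtures are built in code; nothing is read from disk.

# canonical mid-range truth used across recovery tests
baseline_truth <- function(doublet_fraction = 0) {
  cellcycle_truth(c(subG1 = 0.03, G1 = 0.34, S = 0.25, G2 = 0.36,
                    polyploid = 0.02),
                  doublet_fraction = doublet_fraction)
}

# Independent forward render of a Gaussian mixture into a pi_histogram.
# Deliberately written from the density formula, not via package internals.
render_hist <- function(mu, sigma, amp, n_bins = 256, range_max = 1024) {
  edges <- seq(0, range_max, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  counts <- rep(0, n_bins)
  for (k in seq_along(mu))
    counts <- counts + amp[k] * exp(-0.5 * ((centers - mu[k]) / sigma[k])^2)
  structure(list(bin_edges = edges, counts = counts, n_bins = n_bins,
                 n_overflow = 0L),
            class = "pi_histogram")
}

# Exhaustive coarse-grid minimum SSE for a 2-component problem:
# 10 values per parameter (mu1, mu2, sigma1, sigma2, a1, a2).  Expands
# SSE(i,j) = |y|^2 + |P1_i|^2 + |P2_j|^2 - 2 y.P1_i - 2 y.P2_j + 2 P1_i.P2_j
# so the full 10^6 grid reduces to one 1000 x 1000 cross-product.
grid2_min_sse <- function(centers, y, mu1s, mu2s, s1s, s2s, a1s, a2s) {
  profiles <- function(mus, sgs, amps) {
    g <- expand.grid(m = mus, s = sgs, a = amps)
    E <- exp(-0.5 * (outer(centers, g$m, "-") / rep(g$s, each = length(centers)))^2)
    sweep(E, 2, g$a, "*")
  }
  P1 <- profiles(mu1s, s1s, a1s)
  P2 <- profiles(mu2s, s2s, a2s)
  yy <- sum(y * y)
  q1 <- colSums(P1 * P1) - 2 * colSums(y * P1)
  q2 <- colSums(P2 * P2) - 2 * colSums(y * P2)
  cross <- crossprod(P1, P2)                 # P1_i . P2_j
  min(yy + outer(q1, q2, "+") + 2 * cross)
}

# Phase-fraction series (irradiated + flat control) through the full
# event -> gate -> histogram -> fit chain; events_per_point kept modest so
# multi-seed loops stay fast.
sim_phase_series <- function(seed, reps = 3, events_per_point = 4000,
                             peak_g2 = 0.65, peak_time = 7, resolve_time = 41,
                             timepoints = c(0, 7, 12, 16, 24, 41, 72)) {
  base <- baseline_truth()
  one_arm <- function(arm) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      s <- child_seed(seed, 1000L + 10L * r + (arm == "ctrl"))
      if (arm == "irr") {
        sims <- simulate_g2_kinetics(base, peak_g2 = peak_g2,
                                     peak_time = peak_time,
                                     resolve_time = resolve_time,
                                     timepoints = timepoints,
                                     events_per_point = events_per_point,
                                     seed = s)
        do.call(rbind, lapply(sims, function(ev) {
          f <- events_to_fractions(ev, g1_estimate = base$g1_mean)
          data.frame(time_h = attr(ev, "time_h"), rep = r, t(f))
        }))
      } else {
        do.call(rbind, lapply(seq_along(timepoints), function(i) {
          ev <- simulate_flow_events(base, events_per_point,
                                     seed = child_seed(s, i))
          f <- events_to_fractions(ev, g1_estimate = base$g1_mean)
          data.frame(time_h = timepoints[i], rep = r, t(f))
        }))
      }
    }))
  }
  list(irr = one_arm("irr"), ctrl = one_arm("ctrl"))
}

# small hand-built OD plate
make_plate <- function(treated, blank = 0.1, untreated = 0.9, doses = NULL) {
  if (is.null(doses)) doses <- seq_along(treated)
  data.frame(
    well = sprintf("A%d", seq_len(length(treated) + 2)),
    condition = c("blank", "untreated", rep("treated", length(treated))),
    dose_gy = c(NA, NA, doses),
    od562 = c(blank, untreated, treated))
}
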