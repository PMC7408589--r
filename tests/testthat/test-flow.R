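test_that("doublet gate keeps singlets and removes doublets", {
  # all widths 0 and positive intercept: identity
  ev <- data.frame(event_id = c("a", "b"), area = c(100, 200), width = c(0, 0))
  out <- suppressMessages(gate_doublets(ev, doublet_gate(0, 10)))
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 0)

  # 10% doublets at 1.6x width: removed fraction within binomial 99% bounds
  tr <- baseline_truth(doublet_fraction = 0.10)
  evs <- simulate_flow_events(tr, 20000, seed = 21)
  gated <- suppressMessages(gate_doublets(evs))
  removed <- attr(gated, "n_removed")
  expect_gte(removed, qbinom(0.005, 20000, 0.10))
  expect_lte(removed, qbinom(0.995, 20000, 0.10))

  # impossibly strict gate: rejection once nothing remains
  expect_error(suppressMessages(gate_doublets(evs, doublet_gate(0, -1e9))),
               "degenerate gate")
  expect_error(gate_doublets(evs[0, ]), "empty")
})

test_that("histogram binning conserves events and is linear", {
  ev <- data.frame(event_id = sprintf("e%d", 1:100), area = rep(10, 100),
                   width = 0)
  h <- build_histogram(ev, n_bins = 64, range_max = 64)
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$counts[findInterval(10, h$bin_edges)], 100)

  # conservation over random inputs, including overflow
  for (s in 1:5) {
    set.seed(s)
    n <- sample(50:500, 1)
    ev <- data.frame(event_id = seq_len(n), area = runif(n, 0, 1500),
                     width = 0)
    h <- suppressMessages(build_histogram(ev, 256, 1024))
    expect_equal(sum(h$counts), n)
  }

  # uniform events: chi-square uniformity at alpha = 0.01 for 1e5 events
  set.seed(99)
  ev <- data.frame(event_id = 1:100000, area = runif(100000, 0, 1024),
                   width = 0)
  h <- build_histogram(ev, 256, 1024)
  expect_gt(chisq.test(h$counts)$p.value, 0.01)

  expect_error(build_histogram(ev, 256, -1), "range_max")
  expect_error(build_histogram(ev, 32, 1024), "n_bins")
})

test_that("G1 peak estimation follows the mode rules", {
  h1 <- render_hist(200, 10, 1000)
  expect_lt(abs(estimate_g1_peak(h1) - 200), 4 + 1e-9)  # within one 4-channel bin

  bim <- render_hist(c(200, 400), c(10, 10), c(1000, 600))
  expect_lt(abs(estimate_g1_peak(bim) - 200), 4 + 1e-9)        # lower-half rule
  expect_lt(abs(estimate_g1_peak(bim, 410) - 400), 4 + 1e-9)   # nearest mode

  empty <- render_hist(200, 10, 0)
  expect_error(estimate_g1_peak(empty), "empty")
})

test_that("component initialization is stoichiometric and safe", {
  h <- render_hist(c(100, 200, 300, 400, 800), c(5, 10, 20, 20, 40),
                   c(150, 1000, 380, 550, 20))
  init <- initialize_components(h, 200)
  expect_equal(init$mu, c(100, 200, 300, 400, 800), tolerance = 0.01)
  expect_true(all(init$amplitude > 0))
  expect_true(all(init$sigma > 0))
  # flat-zero histogram regions still give a positive amplitude floor
  h0 <- render_hist(200, 10, 1000)
  init0 <- initialize_components(h0, 200)
  expect_true(all(init0$amplitude > 0))
  sse <- sum((h0$counts - 0)^2)
  expect_true(is.finite(sse))
  expect_error(initialize_components(h, 5000), "outside")
})

test_that("mixture fit recovers a noiseless 5-Gaussian render", {
  mu <- c(100, 200, 300, 400, 800)
  sg <- c(5, 10, 20, 20, 40)
  am <- c(150, 1000, 380, 550, 20)
  h <- render_hist(mu, sg, am)
  fit <- fit_mixture(h, initialize_components(h, 200))
  expect_lt(max(abs(fit$components$mu - mu) / mu), 0.005)
  expect_lt(max(abs(fit$components$sigma - sg) / sg), 0.005)
  expect_lt(max(abs(fit$components$amplitude - am) / am), 0.005)
  expect_lte(fit$sse, fit$sse_init)
})

test_that("degenerate single-component histogram zeroes the others", {
  h <- render_hist(200, 10, 1000)
  fit <- fit_mixture(h, initialize_components(h, 200))
  a <- fit$components$amplitude
  expect_true(all(a[-2] <= 0.01 * a[2]))
})

test_that("fit never increases SSE and is event-order invariant", {
  tr <- baseline_truth(doublet_fraction = 0.05)
  for (s in 1:5) {
    ev <- simulate_flow_events(tr, 8000, seed = s)
    fr <- events_to_fractions(ev)
    fit <- attr(fr, "fit")
    expect_lte(fit$sse, fit$sse_init)
    expect_true(fit$converged)
  }
  ev <- simulate_flow_events(tr, 8000, seed = 77)
  set.seed(1)
  shuffled <- ev[sample.int(nrow(ev)), ]
  expect_equal(as.numeric(events_to_fractions(ev)),
               as.numeric(events_to_fractions(shuffled)), tolerance = 1e-8)
})

test_that("phase fractions are normalized Gaussian areas", {
  comp <- data.frame(name = c("subG1", "G1", "S", "G2", "polyploid"),
                     mu = c(100, 200, 300, 400, 800),
                     sigma = c(1, 10, 1, 20, 1),
                     amplitude = c(0, 500, 0, 250, 0))
  fit <- structure(list(components = comp), class = "mixture_fit")
  fr <- phase_fractions(fit)
  expect_equal(unname(fr[["G1"]]), 0.5)    # equal areas: 500*10 = 250*20
  expect_equal(unname(fr[["G2"]]), 0.5)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  comp$amplitude <- 0
  expect_error(phase_fractions(structure(list(components = comp),
                                         class = "mixture_fit")), "zero")
})

test_that("kinetics: identical arms resolve at the peak", {
  tp <- c(0, 7, 16)
  df <- data.frame(time_h = rep(tp, each = 3), rep = rep(1:3, 3),
                   G2 = c(0.30, 0.31, 0.29, 0.50, 0.52, 0.48, 0.33, 0.35, 0.31))
  res <- g2_kinetics(df, df)
  expect_equal(res$peak_time, 7)
  expect_equal(res$resolution_time, 7)
})

test_that("kinetics: resolution time is monotone in alpha", {
  set.seed(42)
  tp <- c(0, 7, 16, 24, 41)
  g2_irr <- c(0.30, 0.60, 0.45, 0.36, 0.31)
  irr <- data.frame(time_h = rep(tp, each = 4), rep = rep(1:4, 5),
                    G2 = rep(g2_irr, each = 4) + rnorm(20, 0, 0.01))
  ctrl <- data.frame(time_h = rep(tp, each = 4), rep = rep(1:4, 5),
                     G2 = 0.30 + rnorm(20, 0, 0.01))
  alphas <- c(0.2, 0.05, 0.01, 0.001)
  res <- vapply(alphas, function(a) {
    r <- g2_kinetics(irr, ctrl, alpha = a)$resolution_time
    if (is.na(r)) Inf else r
  }, numeric(1))
  # stricter alpha can only call resolution earlier (or at the same time):
  # {p >= alpha} grows as alpha shrinks, so its minimum is non-increasing
  expect_true(all(diff(res) <= 0))
  expect_error(g2_kinetics(irr, ctrl[ctrl$time_h != 24, ]), "unmatched")
  expect_error(g2_kinetics(irr[irr$time_h < 8, ], ctrl[ctrl$time_h < 8, ]),
               ">= 3 timepoints")
})
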