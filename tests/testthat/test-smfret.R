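test_that("burst search segments constructed and random streams correctly", {
  expect_identical(burst_search(NULL), list())
  empty <- structure(data.frame(timestamp_ns = numeric(0), channel = character(0),
                                excitation_slot = character(0)),
                     class = c("photon_stream", "data.frame"))
  expect_identical(burst_search(empty), list())

  # 60 photons at 1 us spacing, a 1 ms gap, then 49 photons at 1 us spacing:
  # only the first cluster survives the 50-photon minimum
  t_ns <- c(seq(0, by = 1e3, length.out = 60),
            60e3 + 1e6 + seq(0, by = 1e3, length.out = 49))
  stream <- make_burst(t_ns, rep(0, length(t_ns)))
  class(stream) <- c("photon_stream", "data.frame")
  bursts <- burst_search(stream)
  expect_length(bursts, 1L)
  expect_gte(nrow(bursts[[1]]), 50L)
  expect_lt(max(bursts[[1]]$timestamp_ns), 1e6)   # it is the first cluster

  # sparse Poisson background alone produces no bursts
  set.seed(1)
  bg <- sort(runif(10000, 0, 10)) * 1e9   # 1 kHz over 10 s
  bg_stream <- make_burst(round(bg), rep(0, 10000))
  class(bg_stream) <- c("photon_stream", "data.frame")
  expect_length(burst_search(bg_stream), 0L)

  # brute-force segmentation oracle on a mixed stream
  sim <- simulate_photon_stream(fret_sim_config(n_bursts = 40, seed = 99,
                                                bg_donor_hz = 500,
                                                bg_acceptor_hz = 500))
  got <- burst_search(sim$stream)
  want <- brute_force_bursts(sim$stream$timestamp_ns)
  expect_length(got, length(want))
  for (i in seq_along(got))
    expect_equal(got[[i]]$timestamp_ns, want[[i]])
})

test_that("burst search is invariant to stream chunking through the reader", {
  sim <- simulate_photon_stream(fret_sim_config(n_bursts = 30, seed = 7))
  whole <- file.path(tempdir(), "whole.tsv")
  part1 <- file.path(tempdir(), "part1.tsv")
  part2 <- file.path(tempdir(), "part2.tsv")
  write_photons(sim$stream, whole)
  cut <- nrow(sim$stream) %/% 2
  write_photons(sim$stream[1:cut, ], part1)
  write_photons(sim$stream[(cut + 1):nrow(sim$stream), ], part2)
  b1 <- burst_search(read_photons(whole))
  b2 <- burst_search(read_photons(c(part1, part2)))
  expect_length(b2, length(b1))
  for (i in seq_along(b1))
    expect_equal(b2[[i]]$timestamp_ns, b1[[i]]$timestamp_ns)
})

test_that("correction factors are recovered from singly labeled populations", {
  # 5% leakage, 8% direct excitation, static mixed population
  cfg <- fret_sim_config(n_bursts = 600, E_open = 0.399, E_closed = 0.4,
                         k_open = 1000, k_close = 1000,
                         photon_rate_hz = 4e5, aex_rate_hz = 4e5,
                         leakage = 0.05, direct_exc = 0.08,
                         frac_donor_only = 0.25, frac_acceptor_only = 0.25,
                         seed = 3)
  bursts <- burst_search(simulate_photon_stream(cfg)$stream)
  cf <- estimate_corrections(bursts)
  expect_equal(cf$leakage, 0.05, tolerance = 0.1)       # +/- 0.005 absolute
  expect_lt(abs(cf$leakage - 0.05), 0.005)
  expect_lt(abs(cf$direct_exc - 0.08), 0.01)

  # corrected FRET of the double-labeled population recovers the true E
  dl <- select_double_labeled(bursts, cf)
  tab <- burst_summary(dl, cf)
  expect_lt(abs(mean(tab$E) - 0.4), 0.01)

  # distortion-free simulation yields near-zero factors
  cfg0 <- fret_sim_config(n_bursts = 300, E_open = 0.399, E_closed = 0.4,
                          k_open = 1000, k_close = 1000,
                          photon_rate_hz = 4e5, aex_rate_hz = 4e5,
                          frac_donor_only = 0.3, frac_acceptor_only = 0.3,
                          seed = 4)
  cf0 <- estimate_corrections(burst_search(simulate_photon_stream(cfg0)$stream))
  expect_lt(cf0$leakage, 0.01)
  expect_lt(cf0$direct_exc, 0.01)
})

test_that("stoichiometry selection keeps the double-labeled fraction", {
  cfg <- fret_sim_config(n_bursts = 800, frac_donor_only = 0.25,
                         frac_acceptor_only = 0.25,
                         photon_rate_hz = 4e5, aex_rate_hz = 4e5, seed = 5)
  bursts <- burst_search(simulate_photon_stream(cfg)$stream)
  kept <- select_double_labeled(bursts, correction_factors())
  expect_equal(length(kept) / length(bursts), 0.5, tolerance = 0.15)
  # window [0,1] is the identity; donor-only input yields nothing
  expect_length(select_double_labeled(bursts, window = c(0, 1)), length(bursts))
  cfg_do <- fret_sim_config(n_bursts = 50, frac_donor_only = 1, seed = 6)
  b_do <- burst_search(simulate_photon_stream(cfg_do)$stream)
  expect_length(select_double_labeled(b_do, correction_factors()), 0L)
})

test_that("FRET histogram is unit-area and localizes static populations", {
  b <- make_burst(seq(0, by = 2e3, length.out = 500),
                  rep(c(1, 1, 0, 0, 0), 100))   # E = 0.4 exactly
  h <- fret_histogram(list(b))
  expect_equal(sum(h$density * diff(seq(0, 1, by = 0.025))[1]), 1, tolerance = 1e-9)
  expect_lt(abs(h$mid[which.max(h$count)] - 0.4), 0.03)
  expect_equal(sum(h$count), 1)
})

test_that("forward likelihood matches brute-force path enumeration", {
  set.seed(42)
  for (case in 1:40) {
    n <- sample(2:10, 1)
    t_s <- cumsum(c(0, rexp(n - 1, 5000)))
    acc <- rbinom(n, 1, 0.5)
    E <- sort(runif(2, 0.05, 0.95))
    ko <- exp(runif(1, log(100), log(2e4)))
    kc <- exp(runif(1, log(100), log(2e4)))
    m <- ak_hmm(E[1], E[2] + 1e-6, ko, kc)
    b <- make_burst(t_s * 1e9, acc)
    expect_equal(hmm_likelihood(m, b),
                 brute_force_loglik(t_s, acc, m$E_open, m$E_closed, ko, kc),
                 tolerance = 1e-6)
  }
})

test_that("likelihood limiting cases: frozen states and time-shift invariance", {
  # near-zero exchange: the likelihood approaches the equilibrium-weighted
  # mixture of the two static binomial path likelihoods
  t_s <- cumsum(c(0, rexp(19, 1e5)))
  set.seed(8); acc <- rbinom(20, 1, 0.5)
  ko <- 1e-6; kc <- 2e-6
  m <- ak_hmm(0.3, 0.8, ko, kc)
  ll <- hmm_likelihood(m, make_burst(t_s * 1e9, acc))
  k <- sum(acc)
  mix <- (ko / (ko + kc)) * 0.3^k * 0.7^(20 - k) +
         (kc / (ko + kc)) * 0.8^k * 0.2^(20 - k)
  expect_equal(ll, log(mix), tolerance = 1e-6)

  # only inter-photon intervals matter
  m2 <- ak_hmm(0.37, 0.72, 3000, 2000)
  b0 <- make_burst(t_s * 1e9, acc)
  b_shift <- make_burst(t_s * 1e9 + 1e9, acc)
  expect_equal(hmm_likelihood(m2, b0), hmm_likelihood(m2, b_shift),
               tolerance = 1e-8)
})

test_that("rate fitting recovers K_C from simulated bursts", {
  bursts <- sim_bursts_at_kc(1.65, 800, seed = 21)
  fit <- hmm_fit(bursts, fix_E = c(0.37, 0.72))
  expect_true(fit$convergence)
  expect_equal(kc_from_model(fit), 1.65, tolerance = 0.15)
  # free-E fit on the same data also locates the efficiencies
  fit_free <- hmm_fit(bursts, n_restarts = 2)
  expect_equal(fit_free$E_open, 0.37, tolerance = 0.05)
  expect_equal(fit_free$E_closed, 0.72, tolerance = 0.05)
  expect_false(fit_free$degenerate)
})

test_that("single-state data is flagged degenerate", {
  cfg <- fret_sim_config(n_bursts = 150, E_open = 0.499, E_closed = 0.5,
                         k_open = 1000, k_close = 1000, seed = 31)
  bursts <- burst_search(simulate_photon_stream(cfg)$stream)
  fit <- hmm_fit(bursts, n_restarts = 2)
  expect_true(fit$degenerate)
})

test_that("Viterbi decoding finds dwells and change points", {
  m <- ak_hmm(0.37, 0.72, k_open = 20, k_close = 20)
  # static high-E burst: one closed dwell covering the burst
  b_hi <- make_burst(seq(0, by = 5e3, length.out = 200),
                     rbinom(200, 1, 0.72))
  dw <- viterbi(m, b_hi)
  expect_equal(nrow(dw$dwells), 1L)
  expect_equal(dw$dwells$state, 2L)
  expect_true(all(dw$states == 2L))

  # constructed change point: 5000 low-E then 5000 high-E photons
  set.seed(9)
  acc <- c(rbinom(5000, 1, 0.37), rbinom(5000, 1, 0.72))
  b_cp <- make_burst(seq(0, by = 5e3, length.out = 10000), acc)
  dw2 <- viterbi(m, b_cp)
  chg <- which(diff(dw2$states) != 0)
  expect_length(chg, 1L)
  expect_lt(abs(chg - 5000), 20)
  # dwells tile the photon span
  expect_equal(dw2$dwells$start_ns[-1], dw2$dwells$end_ns[-nrow(dw2$dwells)])
  expect_true(all(dw2$dwells$duration_us > 0))
})

test_that("Viterbi dwell statistics reflect the generating rates", {
  kc_true <- 1
  bursts <- sim_bursts_at_kc(kc_true, 300, seed = 41, relaxation = 3000)
  m <- ak_hmm(0.37, 0.72, k_open = 1500, k_close = 1500)
  recs <- lapply(bursts, viterbi, model = m)
  dw <- do.call(rbind, lapply(recs, `[[`, "dwells"))
  # interior dwells only (edge dwells are censored by the burst span)
  frac_closed <- sum(dw$duration_us[dw$state == 2]) / sum(dw$duration_us)
  expect_equal(frac_closed, kc_true / (1 + kc_true), tolerance = 0.1)
  # mean interior closed dwell ~ 1/k_open
  int_closed <- dw$duration_us[dw$state == 2]
  expect_equal(mean(int_closed) * 1e-6, 1 / 1500, tolerance = 0.5)
})

test_that("recoloring validates a matched model and rejects a mismatched one", {
  bursts <- sim_bursts_at_kc(1.0, 250, seed = 51, relaxation = 4000)
  m_fit <- hmm_fit(bursts, fix_E = c(0.37, 0.72))$models[[1]]
  res <- recoloring_test(m_fit, bursts, n_draws = 60, seed = 2)
  expect_true(res$pass)

  # three well-separated static populations cannot be recolored by a
  # two-state model fitted to them
  mk_static <- function(E, seed, n = 80) {
    cfg <- fret_sim_config(n_bursts = n, E_open = E, E_closed = E + 1e-4,
                           k_open = 1000, k_close = 1000, seed = seed)
    burst_search(simulate_photon_stream(cfg)$stream)
  }
  b3 <- c(mk_static(0.08, 61), mk_static(0.5, 62), mk_static(0.92, 63))
  fit3 <- hmm_fit(b3, n_restarts = 2)
  res3 <- recoloring_test(fit3$models[[1]], b3, n_draws = 60, seed = 3)
  expect_false(res3$pass)

  expect_error(recoloring_test(m_fit, bursts, n_draws = 0), "n_draws")
})

test_that("burst variance analysis separates static from dynamic bursts", {
  static <- sim_bursts_at_kc(1e-4, 150, seed = 71)   # essentially always open
  dynamic <- sim_bursts_at_kc(1.0, 150, seed = 72, relaxation = 2000)
  bva_s <- burst_variance_analysis(static, window = 50)
  bva_d <- burst_variance_analysis(dynamic, window = 50)
  # static: observed spread within ~ the shot-noise envelope
  expect_lt(median(bva_s$sd_E / bva_s$shot_sd), 1.15)
  # dynamic at exchange ~ window duration: spread above shot noise
  expect_gt(median(bva_d$sd_E / bva_d$shot_sd), 1.3)
  # windows longer than the burst are skipped and counted
  bva_skip <- burst_variance_analysis(static, window = 10000)
  expect_equal(nrow(bva_skip), 0L)
  expect_equal(attr(bva_skip, "skipped"), length(static))
})
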