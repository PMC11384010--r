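# shared fixtures and independent oracles, built in code at test time

# random but physically sensible parameter set
random_params <- function(seed) {
  set.seed(seed)
  kc <- exp(runif(6, log(0.05), log(5)))
  names(kc) <- ak_ligation_states()
  ak_params(k_cat = exp(runif(1, log(10), log(1e4))),
            k_r_T = exp(runif(1, log(10), log(1e4))),
            k_r_M = exp(runif(1, log(10), log(1e4))),
            Kd_ATP = exp(runif(1, log(1e-6), log(1e-3))),
            Kd_AMP = exp(runif(1, log(1e-6), log(1e-3))),
            k_on = 1e8,
            conf_rates = ak_conf_rates(kc, relaxation = exp(runif(1, log(1e3), log(1e5)))))
}

random_conditions <- function(seed) {
  set.seed(seed + 5000)
  ak_conditions(atp = exp(runif(1, log(1e-5), log(1e-2))),
                amp = exp(runif(1, log(1e-5), log(1e-2))))
}

# build a photon_burst from explicit donor-excitation photons
make_burst <- function(t_ns, acceptor) {
  structure(data.frame(timestamp_ns = t_ns,
                       channel = ifelse(acceptor == 1, "acceptor", "donor"),
                       excitation_slot = "donor_exc"),
            class = c("photon_burst", "data.frame"))
}

# brute-force photon-HMM likelihood: exhaustive sum over all 2^n hidden
# state paths, with per-interval transition matrices from Matrix::expm
# (independent of the analytic 2-state propagation in the package)
brute_force_loglik <- function(t_s, acceptor, E_open, E_closed, k_open, k_close) {
  n <- length(t_s)
  lam <- k_open + k_close
  pi0 <- c(k_open, k_close) / lam
  Q <- matrix(c(-k_close, k_open, k_close, -k_open), 2, 2)  # row convention
  Ts <- lapply(diff(t_s), function(dt) as.matrix(Matrix::expm(Q * dt)))
  em <- rbind(ifelse(acceptor == 1, E_open, 1 - E_open),
              ifelse(acceptor == 1, E_closed, 1 - E_closed))
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- pi0[s[1]] * em[s[1], 1]
    if (n > 1) for (i in 2:n) pr <- pr * Ts[[i - 1]][s[i - 1], s[i]] * em[s[i], i]
    tot <- tot + pr
  }
  log(tot)
}

# brute-force burst segmentation: direct O(n*w) smoothing and scanning
brute_force_bursts <- function(t_ns, window = 15, cutoff_us = 5, min_size = 50) {
  n <- length(t_ns)
  if (n < 2) return(list())
  d <- diff(t_ns)
  half <- (window - 1) %/% 2
  sm <- sapply(seq_along(d), function(i) {
    lo <- max(1, i - half); hi <- min(length(d), i + (window - 1 - half))
    mean(d[lo:hi])
  })
  below <- sm < cutoff_us * 1e3
  out <- list(); i <- 1
  while (i <= length(below)) {
    if (below[i]) {
      j <- i
      while (j < length(below) && below[j + 1]) j <- j + 1
      if (j - i + 2 >= min_size) out[[length(out) + 1]] <- t_ns[i:(j + 1)]
      i <- j + 1
    }
    i <- i + 1
  }
  out
}

# default simulation of a two-state burst set at a given K_C
sim_bursts_at_kc <- function(kc, n_bursts, seed, relaxation = 5000, ...) {
  cfg <- fret_sim_config(n_bursts = n_bursts,
                         k_open = relaxation / (1 + kc),
                         k_close = relaxation * kc / (1 + kc),
                         seed = seed, ...)
  sim <- simulate_photon_stream(cfg)
  burst_search(sim$stream)
}
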