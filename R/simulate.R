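#' Configuration for the single-molecule FRET photon generator
#'
#' Describes the generative stand-in for a diffusion-based smFRET
#' measurement: molecules transit the focus in bursts whose durations are
#' exponential (mean 1 ms by default), emit photons as a constant-rate
#' Poisson process while in the focus (200 kHz by default, matching bright
#' transits), and switch between the open and closed conformation as a
#' two-state continuous-time Markov process. Each donor-excitation photon
#' is colored acceptor with probability equal to the current state's FRET
#' efficiency; leakage, acceptor direct excitation and channel backgrounds
#' then distort the record. Donor-only and acceptor-only labeled species
#' can be mixed in for stoichiometry-based selection tests.
#'
#' @param n_bursts number of molecule transits to simulate
#' @param E_open,E_closed state FRET efficiencies
#' @param k_open,k_close conformational rates (s^-1); defaults give the
#'   apo equilibrium `K_C = k_close/k_open = 0.16` at total relaxation
#'   5000 s^-1
#' @param photon_rate_hz in-burst donor-excitation photon rate (Hz)
#' @param aex_rate_hz in-burst acceptor-excitation photon rate (Hz) for
#'   acceptor-carrying species (pulsed interleaved excitation)
#' @param burst_mean_ms mean burst duration (ms), exponential
#' @param gap_mean_ms mean inter-burst gap (ms), exponential
#' @param leakage leakage coefficient l (leaked acceptor counts per
#'   detected donor count)
#' @param direct_exc direct-excitation coefficient d
#' @param bg_donor_hz,bg_acceptor_hz background rates (Hz) filling the
#'   whole trace
#' @param frac_donor_only,frac_acceptor_only fractions of singly labeled
#'   molecules
#' @param seed RNG seed (mandatory: generators are deterministic given it)
#' @return list of class `fret_sim_config`
#' @export
fret_sim_config <- function(n_bursts = 1000,
                            E_open = 0.37, E_closed = 0.72,
                            k_open = 5000 / 1.16, k_close = 5000 * 0.16 / 1.16,
                            photon_rate_hz = 2e5, aex_rate_hz = 2e5,
                            burst_mean_ms = 1, gap_mean_ms = 10,
                            leakage = 0, direct_exc = 0,
                            bg_donor_hz = 0, bg_acceptor_hz = 0,
                            frac_donor_only = 0, frac_acceptor_only = 0,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(n_bursts = n_bursts, E_open = E_open, E_closed = E_closed,
              k_open = k_open, k_close = k_close,
              photon_rate_hz = photon_rate_hz, aex_rate_hz = aex_rate_hz,
              burst_mean_ms = burst_mean_ms, gap_mean_ms = gap_mean_ms,
              leakage = leakage, direct_exc = direct_exc,
              bg_donor_hz = bg_donor_hz, bg_acceptor_hz = bg_acceptor_hz,
              frac_donor_only = frac_donor_only,
              frac_acceptor_only = frac_acceptor_only, seed = seed)
  with(cfg, {
    stopifnot(E_open >= 0, E_open <= 1, E_closed >= 0, E_closed <= 1,
              k_open > 0, k_close > 0, photon_rate_hz > 0,
              leakage >= 0, leakage < 1, direct_exc >= 0, direct_exc < 1,
              frac_donor_only + frac_acceptor_only <= 1)
  })
  structure(cfg, class = "fret_sim_config")
}

# Gillespie path of the 2-state open/closed process over [0, dur]:
# returns switch times and the state occupied in each inter-switch segment
sample_state_path <- function(dur, k_open, k_close) {
  p_closed <- k_close / (k_open + k_close)
  state <- if (runif(1) < p_closed) 2L else 1L    # 1 = open, 2 = closed
  t <- 0
  times <- numeric(0); states <- state
  repeat {
    rate <- if (state == 1L) k_close else k_open
    t <- t + rexp(1, rate)
    if (t >= dur) break
    state <- 3L - state
    times <- c(times, t); states <- c(states, state)
  }
  list(switch_times = times, states = states)
}

#' Simulate a photon stream with two-state conformational dynamics
#'
#' Generates the full photon record the burst analysis consumes (sorted
#' arrival times in ns, detection channel, excitation slot), plus the
#' ground truth needed for recovery tests: the span and hidden state path
#' of every simulated burst. See [fret_sim_config] for the generative
#' model.
#'
#' @param cfg a [fret_sim_config]
#' @return list with `stream` (a `photon_stream` data.frame with columns
#'   `timestamp_ns`, `channel`, `excitation_slot`), `truth` (per-burst list:
#'   `start_ns`, `end_ns`, `species`, `switch_times_ns`, `states`), and
#'   `config`
#' @export
simulate_photon_stream <- function(cfg) {
  stopifnot(inherits(cfg, "fret_sim_config"))
  set.seed(cfg$seed)
  slots <- c("donor_exc", "acceptor_exc")
  chans <- c("donor", "acceptor")
  l_p <- cfg$leakage / (1 + cfg$leakage)   # per-photon reclassification prob
  t_cursor <- 0
  all <- vector("list", cfg$n_bursts * 2L)
  truth <- vector("list", cfg$n_bursts)
  u_species <- runif(cfg$n_bursts)
  for (b in seq_len(cfg$n_bursts)) {
    gap <- rexp(1, 1 / (cfg$gap_mean_ms * 1e-3))
    start <- t_cursor + gap
    dur <- rexp(1, 1 / (cfg$burst_mean_ms * 1e-3))
    species <- if (u_species[b] < cfg$frac_donor_only) "DO"
               else if (u_species[b] < cfg$frac_donor_only + cfg$frac_acceptor_only) "AO"
               else "DA"
    path <- sample_state_path(dur, cfg$k_open, cfg$k_close)
    # donor-excitation photons (FRET pair or donor-only dye)
    tdex <- cdex <- numeric(0)
    if (species != "AO") {
      n <- rpois(1, cfg$photon_rate_hz * dur)
      tdex <- sort(runif(n, 0, dur))
      st <- path$states[findInterval(tdex, path$switch_times) + 1L]
      E <- if (species == "DO") rep(0, n)
           else c(cfg$E_open, cfg$E_closed)[st]
      acc <- runif(n) < E
      # donor photons may leak into the acceptor channel
      leak <- !acc & (runif(n) < l_p)
      cdex <- ifelse(acc | leak, 2L, 1L)
    }
    # acceptor-excitation photons and direct excitation (acceptor dye present)
    taex <- numeric(0); tdir <- numeric(0)
    if (species != "DO") {
      n_a <- rpois(1, cfg$aex_rate_hz * dur)
      taex <- sort(runif(n_a, 0, dur))
      n_d <- rpois(1, cfg$direct_exc * cfg$aex_rate_hz * dur)
      tdir <- sort(runif(n_d, 0, dur))
    }
    ts <- c(tdex, tdir, taex)
    ch <- c(cdex, rep(2L, length(tdir)), rep(2L, length(taex)))
    sl <- c(rep(1L, length(tdex) + length(tdir)), rep(2L, length(taex)))
    o <- order(ts)
    all[[b]] <- data.frame(timestamp_ns = round((start + ts[o]) * 1e9),
                           channel = chans[ch[o]],
                           excitation_slot = slots[sl[o]])
    truth[[b]] <- list(start_ns = start * 1e9, end_ns = (start + dur) * 1e9,
                       species = species,
                       switch_times_ns = (start + path$switch_times) * 1e9,
                       states = path$states)
    t_cursor <- start + dur
  }
  stream <- do.call(rbind, all[seq_len(cfg$n_bursts)])
  # background photons over the full span
  span <- t_cursor + rexp(1, 1 / (cfg$gap_mean_ms * 1e-3))
  bg <- lapply(c(donor = cfg$bg_donor_hz, acceptor = cfg$bg_acceptor_hz),
               function(r) if (r > 0) sort(runif(rpois(1, r * span), 0, span)) else numeric(0))
  if (length(bg$donor) + length(bg$acceptor)) {
    bg_df <- data.frame(
      timestamp_ns = round(c(bg$donor, bg$acceptor) * 1e9),
      channel = c(rep("donor", length(bg$donor)),
                  rep("acceptor", length(bg$acceptor))),
      excitation_slot = "donor_exc")
    stream <- rbind(stream, bg_df)
  }
  stream <- stream[order(stream$timestamp_ns), , drop = FALSE]
  rownames(stream) <- NULL
  class(stream) <- c("photon_stream", "data.frame")
  list(stream = stream, truth = truth, config = cfg)
}

#' Simulate noisy steady-state activity datasets
#'
#' Wraps the kinetic model: for each concentration in the scan the
#' steady-state turnover is computed with [steady_state_turnover] and
#' multiplied by `(1 + sigma_rel * N(0,1))`; the per-point standard error
#' is `sigma_rel * v`.
#'
#' @param params an [ak_params] object
#' @param base_cond an [ak_conditions] giving the fixed co-substrate
#' @param scan concentrations (M)
#' @param axis `"AMP"` or `"ATP"`
#' @param sigma_rel relative Gaussian noise level (>= 0)
#' @param seed RNG seed
#' @return an activity dataset: data.frame `conc_M, v0_per_s, sem` with
#'   attributes `axis`, `cosubstrate_M`, `urea`
#' @export
simulate_activity_curve <- function(params, base_cond, scan, axis = "AMP",
                                    sigma_rel = 0.05, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (sigma_rel < 0) stop("sigma_rel must be >= 0")
  set.seed(seed)
  curve <- velocity_curve(params, base_cond, scan, axis)
  v <- curve$velocity_per_s * (1 + sigma_rel * rnorm(nrow(curve)))
  sem <- if (sigma_rel > 0) sigma_rel * curve$velocity_per_s
         else rep(max(curve$velocity_per_s) * 1e-4, nrow(curve))
  structure(data.frame(conc_M = curve$conc_M, v0_per_s = v, sem = sem),
            class = c("ak_activity_dataset", "data.frame"),
            axis = axis,
            cosubstrate_M = if (axis == "AMP") base_cond$atp else base_cond$amp,
            urea = base_cond$urea)
}

#' Simulate a product-inhibited reverse time course
#'
#' Evaluates `[P](t) = (v0/eta) * (1 - exp(-eta t))` on a time grid (the
#' `eta = 0` limit is the line `v0 * t`) and adds Gaussian noise.
#'
#' @param v0 initial velocity (M s^-1, >= 0)
#' @param eta non-linearity factor (s^-1, >= 0)
#' @param times time grid (s)
#' @param noise_sd absolute Gaussian noise on `[P]` (M)
#' @param seed RNG seed (only needed when `noise_sd > 0`)
#' @return an [ak_timecourse]
#' @export
simulate_reverse_timecourse <- function(v0, eta, times, noise_sd = 0,
                                        seed = NULL) {
  if (v0 < 0 || eta < 0) stop("v0 and eta must be >= 0")
  P <- if (eta == 0) v0 * times else (v0 / eta) * (1 - exp(-eta * times))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is mandatory for noisy simulation")
    set.seed(seed)
    P <- P + rnorm(length(times), sd = noise_sd)
  }
  ak_timecourse(times, P, direction = "reverse")
}

#' Simulate a binding titration
#'
#' `f(L) = baseline + amplitude * L / (L + Kd) + noise`, the generative
#' twin of a thermophoresis fraction-bound measurement.
#'
#' @param Kd dissociation constant (M, > 0)
#' @param L ligand concentrations (M)
#' @param amplitude,baseline signal scale and offset
#' @param noise_sd absolute Gaussian noise
#' @param seed RNG seed (only needed when `noise_sd > 0`)
#' @return data.frame with columns `L`, `f`
#' @export
simulate_titration <- function(Kd, L, amplitude = 1, baseline = 0,
                               noise_sd = 0, seed = NULL) {
  if (Kd <= 0) stop("Kd must be positive")
  f <- baseline + amplitude * L / (L + Kd)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is mandatory for noisy simulation")
    set.seed(seed)
    f <- f + rnorm(length(L), sd = noise_sd)
  }
  data.frame(L = L, f = f)
}
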