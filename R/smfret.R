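#' Burst search configuration
#'
#' Photon bursts from single molecules transiting the confocal focus are
#' identified on the inter-photon interval trace: intervals are smoothed
#' with a running average over a fixed photon window (15 photons), stretches
#' whose smoothed interval falls below a cut-off time (5 us) define burst
#' boundaries, and bursts below a minimum photon count (50) are discarded.
#'
#' @param window smoothing window (photons, >= 1)
#' @param cutoff_us inter-photon cut-off time (us, > 0)
#' @param min_size minimum photons per burst (>= window)
#' @export
burst_search_config <- function(window = 15, cutoff_us = 5, min_size = 50) {
  if (window < 1 || cutoff_us <= 0 || min_size < window)
    stop("invalid burst search configuration")
  structure(list(window = as.integer(window), cutoff_us = cutoff_us,
                 min_size = as.integer(min_size)),
            class = "burst_search_config")
}

# centered running mean with shrinking windows at the edges
running_mean <- function(x, w) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Find photon bursts in a stream
#'
#' @param stream a `photon_stream` data.frame (columns `timestamp_ns`,
#'   `channel`, `excitation_slot`), sorted by timestamp
#' @param cfg a [burst_search_config]
#' @return list of `photon_burst` objects (data.frame slices of the stream)
#' @export
burst_search <- function(stream, cfg = burst_search_config()) {
  if (is.null(stream) || nrow(stream) == 0L) return(list())
  t <- stream$timestamp_ns
  if (is.unsorted(t)) stop("photon stream must be sorted by timestamp")
  if (nrow(stream) < cfg$min_size) return(list())
  d <- diff(t)
  sm <- running_mean(d, cfg$window)
  below <- sm < cfg$cutoff_us * 1e3
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k] + 1L   # intervals i0..ends[k] -> photons i0..ends[k]+1
    if (i1 - i0 + 1L >= cfg$min_size) {
      b <- stream[i0:i1, , drop = FALSE]
      rownames(b) <- NULL
      class(b) <- c("photon_burst", "data.frame")
      out[[length(out) + 1L]] <- b
    }
  }
  out
}

# photon counts of one burst: DD = donor channel under donor excitation,
# DA = acceptor channel under donor excitation, AA = acceptor excitation
burst_counts <- function(burst) {
  dex <- burst$excitation_slot == "donor_exc"
  acc <- burst$channel == "acceptor"
  c(DD = sum(dex & !acc), DA = sum(dex & acc), AA = sum(!dex))
}

#' Per-burst FRET efficiency and stoichiometry table
#'
#' Computes, for every burst, the photon counts, the (optionally corrected)
#' FRET efficiency and the stoichiometry. Raw values use detected counts
#' directly: `E = DA / (DD + DA)` over donor-excitation photons and
#' `S = (DD + DA) / (DD + DA + AA)`. With correction factors the leaked
#' donor signal and the directly excited acceptor signal are subtracted
#' from the acceptor channel, `DA' = DA - l * DD - d * AA`, and the donor
#' emission is restored photon-conservingly to `(1 + l) * DD` (the leaked
#' photons were donor emission detected in the wrong channel), so a static
#' distorted population inverts exactly to its true efficiency.
#'
#' @param bursts list of `photon_burst` objects
#' @param corrections optional [correction_factors]
#' @return data.frame with columns `n`, `DD`, `DA`, `AA`, `E`, `S`
#' @export
burst_summary <- function(bursts, corrections = NULL) {
  cnt <- t(vapply(bursts, burst_counts, numeric(3)))
  l <- if (is.null(corrections)) 0 else corrections$leakage
  d <- if (is.null(corrections)) 0 else corrections$direct_exc
  DA <- pmax(cnt[, "DA"] - l * cnt[, "DD"] - d * cnt[, "AA"], 0)
  DD <- (1 + l) * cnt[, "DD"]
  E <- ifelse(DD + DA > 0, DA / (DD + DA), NA_real_)
  S <- (DD + DA) / (DD + DA + cnt[, "AA"])
  data.frame(n = rowSums(cnt), DD = cnt[, "DD"], DA = cnt[, "DA"],
             AA = cnt[, "AA"], E = pmin(pmax(E, 0), 1), S = pmin(pmax(S, 0), 1))
}

#' Leakage and direct-excitation factors
#'
#' @param leakage leakage coefficient `l`: leaked acceptor-channel counts
#'   per detected donor count (`0 <= l < 1`)
#' @param direct_exc direct-excitation coefficient `d` (`0 <= d < 1`)
#' @export
correction_factors <- function(leakage = 0, direct_exc = 0) {
  if (leakage < 0 || leakage >= 1 || direct_exc < 0 || direct_exc >= 1)
    stop("correction factors must lie in [0, 1)")
  structure(list(leakage = leakage, direct_exc = direct_exc),
            class = "correction_factors")
}

#' Estimate correction factors from singly labeled populations
#'
#' Donor-only molecules (raw stoichiometry above `s_donor_only`) report
#' leakage: their apparent FRET comes entirely from donor photons detected
#' in the acceptor channel, so `l = E_DO / (1 - E_DO)`. Acceptor-only
#' molecules (raw stoichiometry below `s_acceptor_only`) report direct
#' excitation: `d = S_AO / (1 - S_AO)`. A missing population yields a
#' factor of 0 with a warning.
#'
#' @param bursts list of `photon_burst` objects (uncorrected)
#' @param s_donor_only,s_acceptor_only stoichiometry windows selecting the
#'   singly labeled populations
#' @return a [correction_factors] object
#' @export
estimate_corrections <- function(bursts, s_donor_only = 0.85,
                                 s_acceptor_only = 0.15) {
  tab <- burst_summary(bursts)
  do <- tab$S > s_donor_only
  ao <- tab$S < s_acceptor_only
  if (!any(do)) { warning("no donor-only population found; leakage set to 0") }
  if (!any(ao)) { warning("no acceptor-only population found; direct excitation set to 0") }
  l <- if (any(do)) { e <- mean(tab$E[do], na.rm = TRUE); e / (1 - e) } else 0
  d <- if (any(ao)) { s <- mean(tab$S[ao]); s / (1 - s) } else 0
  correction_factors(leakage = max(l, 0), direct_exc = max(d, 0))
}

#' Select double-labeled bursts by corrected stoichiometry
#'
#' @param bursts list of `photon_burst` objects
#' @param corrections a [correction_factors]
#' @param window corrected-stoichiometry acceptance window
#' @return the retained subset of `bursts`
#' @export
select_double_labeled <- function(bursts, corrections = correction_factors(),
                                  window = c(0.3, 0.7)) {
  if (length(bursts) == 0L) return(bursts)
  tab <- burst_summary(bursts, corrections)
  bursts[!is.na(tab$S) & tab$S >= window[1] & tab$S <= window[2]]
}

#' FRET efficiency histogram
#'
#' Per-burst (corrected) FRET efficiencies binned into a density-normalized
#' histogram (unit area).
#'
#' @param bursts list of `photon_burst` objects
#' @param breaks bin breaks on the efficiency axis
#' @param corrections optional [correction_factors]
#' @return data.frame with columns `mid`, `count`, `density`
#' @export
fret_histogram <- function(bursts, breaks = seq(0, 1, by = 0.025),
                           corrections = NULL) {
  E <- burst_summary(bursts, corrections)$E
  E <- E[!is.na(E)]
  h <- hist(E, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts, density = h$density)
}

#' Two-state photon HMM model
#'
#' @param E_open,E_closed state FRET efficiencies; by labeling convention
#'   `E_closed > E_open` (the closed conformation brings the dyes closer)
#' @param k_open opening rate, closed -> open (s^-1)
#' @param k_close closing rate, open -> closed (s^-1)
#' @return object of class `ak_hmm` with equilibrium populations attached
#' @export
ak_hmm <- function(E_open, E_closed, k_open, k_close) {
  stopifnot(E_open >= 0, E_open <= 1, E_closed >= 0, E_closed <= 1,
            k_open > 0, k_close > 0)
  if (E_closed <= E_open) stop("labeling convention requires E_closed > E_open")
  lam <- k_open + k_close
  structure(list(E_open = E_open, E_closed = E_closed,
                 k_open = k_open, k_close = k_close,
                 P_open = k_open / lam, P_closed = k_close / lam),
            class = "ak_hmm")
}

# donor-excitation photons of a burst as (dt to previous photon in s,
# acceptor flag); the HMM sees only these
burst_dex_photons <- function(burst) {
  dex <- burst$excitation_slot == "donor_exc"
  t <- burst$timestamp_ns[dex] * 1e-9
  list(t_s = t, acceptor = as.integer(burst$channel[dex] == "acceptor"))
}

#' Photon-by-photon log-likelihood of a burst
#'
#' Forward algorithm over the donor-excitation photons of one burst: the
#' hidden open/closed state distribution is propagated between photons with
#' the analytic two-state transition matrix `exp(Q dt)` and reweighted at
#' each photon by the emission probability (acceptor photon: `E_state`;
#' donor photon: `1 - E_state`). Only inter-photon intervals enter, so the
#' likelihood is invariant under a global time shift.
#'
#' @param model an [ak_hmm]
#' @param burst a `photon_burst`
#' @return log-likelihood (natural log)
#' @export
hmm_likelihood <- function(model, burst) {
  stopifnot(inherits(model, "ak_hmm"))
  ph <- burst_dex_photons(burst)
  if (length(ph$t_s) == 0L) return(0)
  if (any(!is.finite(ph$t_s))) stop("non-finite photon timestamps")
  hmm_loglik_cpp(diff(ph$t_s), ph$acceptor,
                 model$E_open, model$E_closed, model$k_open, model$k_close)
}

# pack a burst set into flat vectors for the C++ likelihood
pack_bursts <- function(bursts) {
  ph <- lapply(bursts, burst_dex_photons)
  len <- vapply(ph, function(p) length(p$t_s), integer(1))
  keep <- len > 0L
  ph <- ph[keep]; len <- len[keep]
  dt <- unlist(lapply(ph, function(p) c(0, diff(p$t_s))), use.names = FALSE)
  acc <- unlist(lapply(ph, `[[`, "acceptor"), use.names = FALSE)
  start <- c(0L, cumsum(len))[seq_along(len)]
  list(dt = dt, acc = acc, start = as.integer(start), len = as.integer(len))
}

set_loglik <- function(pk, E1, E2, ko, kc) {
  hmm_loglik_multi_cpp(pk$dt, pk$acc, pk$start, pk$len, E1, E2, ko, kc)
}

#' Fit the two-state photon HMM by maximum likelihood
#'
#' Maximizes the summed photon-by-photon likelihood over one or several
#' burst sets (measurement conditions). With `global_E = TRUE` (the
#' default) the two state efficiencies are shared across all sets -- the
#' conformer structures do not change between conditions -- while the
#' opening and closing rates are free per set. Alternatively the
#' efficiencies can be fixed to previously determined values via `fix_E`,
#' in which case only the rates are optimized (the mode used when analysing
#' perturbation series against a reference global fit).
#'
#' Optimization is direct numerical maximum likelihood (Nelder-Mead on
#' logit-efficiency / log-rate coordinates) from `n_restarts` deterministic
#' starting points; the best likelihood wins. States are relabeled after
#' fitting so that the higher-efficiency state is "closed".
#'
#' @param burst_sets a list of burst lists (one per condition), or a single
#'   list of bursts
#' @param global_E share state efficiencies across sets
#' @param fix_E optional length-2 numeric `c(E_open, E_closed)` to hold the
#'   efficiencies fixed
#' @param init_relaxation initial guess for `k_open + k_close` (s^-1)
#' @param n_restarts number of deterministic multi-starts
#' @param seed RNG seed for the restart jitter schedule
#' @return object of class `ak_hmm_fit`: `models` (list of [ak_hmm], one
#'   per set), `E_open`, `E_closed`, `loglik`, `convergence`, `degenerate`
#' @export
hmm_fit <- function(burst_sets, global_E = TRUE, fix_E = NULL,
                    init_relaxation = 2000, n_restarts = 4, seed = 1234) {
  if (length(burst_sets) > 0L && inherits(burst_sets[[1]], "photon_burst"))
    burst_sets <- list(burst_sets)
  ns <- length(burst_sets)
  if (ns == 0L) stop("no burst sets supplied")
  packs <- lapply(burst_sets, pack_bursts)
  # moment-based efficiency guesses from the per-burst E distribution
  allE <- unlist(lapply(burst_sets, function(b) burst_summary(b)$E))
  allE <- allE[!is.na(allE)]
  Eg <- as.numeric(quantile(allE, c(0.2, 0.8)))
  Eg <- pmin(pmax(Eg, 0.02), 0.98)
  if (diff(Eg) < 0.1) Eg <- pmin(pmax(c(mean(Eg) - 0.1, mean(Eg) + 0.1), 0.02), 0.98)
  rate_g <- rep(init_relaxation / 2, 2L * ns)
  set.seed(seed)
  jitter_tab <- matrix(rnorm(n_restarts * (2L + 2L * ns), sd = 0.7),
                       nrow = n_restarts)
  jitter_tab[1, ] <- 0   # first start is the plain moment guess
  neg <- function(par) {
    if (is.null(fix_E)) {
      E1 <- plogis(par[1]); E2 <- plogis(par[2])
      rates <- exp(par[-(1:2)])
    } else {
      E1 <- fix_E[1]; E2 <- fix_E[2]
      rates <- exp(par)
    }
    if (any(!is.finite(rates)) || any(rates <= 0)) return(1e12)
    ll <- 0
    for (s in seq_len(ns))
      ll <- ll + set_loglik(packs[[s]], E1, E2,
                            rates[2 * s - 1], rates[2 * s])
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  par0 <- if (is.null(fix_E)) c(qlogis(Eg), log(rate_g)) else log(rate_g)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    jit <- jitter_tab[r, seq_along(par0)]
    fit <- optim(par0 + jit, neg, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- best$par
  if (is.null(fix_E)) {
    E1 <- plogis(par[1]); E2 <- plogis(par[2]); rates <- exp(par[-(1:2)])
  } else {
    E1 <- fix_E[1]; E2 <- fix_E[2]; rates <- exp(par)
  }
  models <- vector("list", ns)
  for (s in seq_len(ns)) {
    ko <- rates[2 * s - 1]; kc <- rates[2 * s]
    if (E1 <= E2) models[[s]] <- ak_hmm(E1, E2, ko, kc)
    else          models[[s]] <- ak_hmm(E2, E1, kc, ko)   # relabel: high E = closed
  }
  E_open <- models[[1]]$E_open; E_closed <- models[[1]]$E_closed
  kcs <- vapply(models, function(m) m$k_close / m$k_open, numeric(1))
  # rates are unidentifiable when a single static state explains the photons
  # almost as well as the two-state model (weak likelihood ratio), or when
  # the fit collapses the efficiencies or runs into an extreme population
  ll1 <- sum(vapply(packs, function(pk) {
    n_acc <- sum(pk$acc); n <- length(pk$acc)
    p_hat <- min(max(n_acc / n, 1e-12), 1 - 1e-12)
    n_acc * log(p_hat) + (n - n_acc) * log(1 - p_hat)
  }, numeric(1)))
  degenerate <- (-best$value - ll1) < 10 * ns ||
    (E_closed - E_open) < 0.05 || any(kcs < 1e-3 | kcs > 1e3)
  structure(list(models = models, E_open = E_open, E_closed = E_closed,
                 loglik = -best$value,
                 convergence = best$convergence == 0L,
                 degenerate = degenerate),
            class = "ak_hmm_fit")
}

#' Conformational equilibrium coefficient from a fitted model
#'
#' `K_C = P_closed / P_open = k_close / k_open`.
#'
#' @param model an [ak_hmm] (or an `ak_hmm_fit` with a single set)
#' @return K_C (dimensionless)
#' @export
kc_from_model <- function(model) {
  if (inherits(model, "ak_hmm_fit")) {
    if (length(model$models) != 1L)
      return(vapply(model$models, kc_from_model, numeric(1)))
    model <- model$models[[1]]
  }
  model$k_close / model$k_open
}

#' Viterbi state path and dwell times of a burst
#'
#' Decodes the most probable open/closed path over the donor-excitation
#' photons under the same transition/emission structure as
#' [hmm_likelihood], then tiles the burst into dwells: boundaries sit at
#' the midpoints between state-change photons, the first and last dwell
#' extend to the first and last photon.
#'
#' @param model an [ak_hmm]
#' @param burst a `photon_burst`
#' @return list of class `ak_dwell_record`: `states` (per photon, 1 = open,
#'   2 = closed) and `dwells` (data.frame `state`, `start_ns`, `end_ns`,
#'   `duration_us`)
#' @export
viterbi <- function(model, burst) {
  stopifnot(inherits(model, "ak_hmm"))
  ph <- burst_dex_photons(burst)
  n <- length(ph$t_s)
  if (n == 0L) stop("burst has no donor-excitation photons")
  st <- hmm_viterbi_cpp(c(0, diff(ph$t_s)), ph$acceptor,
                        model$E_open, model$E_closed,
                        model$k_open, model$k_close)
  chg <- which(diff(st) != 0)
  bounds_ns <- c(ph$t_s[1], (ph$t_s[chg] + ph$t_s[chg + 1]) / 2,
                 ph$t_s[n]) * 1e9
  dw <- data.frame(state = st[c(1, chg + 1)],
                   start_ns = bounds_ns[-length(bounds_ns)],
                   end_ns = bounds_ns[-1])
  dw$duration_us <- (dw$end_ns - dw$start_ns) * 1e-3
  structure(list(states = st, dwells = dw), class = "ak_dwell_record")
}

# two-sample Kolmogorov-Smirnov distance (statistic only, ties allowed)
ks_distance <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- findInterval(v, sort(x)) / length(x)
  Fy <- findInterval(v, sort(y)) / length(y)
  max(abs(Fx - Fy))
}

#' Recoloring validation of a fitted photon HMM
#'
#' Keeps the observed photon arrival times of every burst but re-draws the
#' photon colors from the fitted model (fresh hidden state path per burst,
#' acceptor probability given by the state efficiency). If the model
#' describes the data, the observed per-burst FRET histogram is
#' statistically indistinguishable from the recolored ones. The distance
#' is the two-sample Kolmogorov-Smirnov statistic between per-burst
#' efficiency samples; the test passes when the observed-vs-recolored
#' distance lies within the 95% envelope of recolored-vs-recolored
#' distances.
#'
#' @param model an [ak_hmm]
#' @param bursts list of `photon_burst` objects
#' @param n_draws number of recolorings (>= 2)
#' @param seed RNG seed
#' @return list: `distance`, `null_distances`, `threshold`, `pass`
#' @export
recoloring_test <- function(model, bursts, n_draws = 200, seed = 1) {
  stopifnot(inherits(model, "ak_hmm"))
  if (n_draws < 2) stop("n_draws must be at least 2")
  set.seed(seed)
  ph <- lapply(bursts, burst_dex_photons)
  obs_E <- vapply(ph, function(p) mean(p$acceptor), numeric(1))
  recolor_once <- function() {
    vapply(ph, function(p) {
      t0 <- p$t_s - p$t_s[1]
      dur <- max(t0)
      path <- sample_state_path(dur + 1e-12, model$k_open, model$k_close)
      st <- path$states[findInterval(t0, path$switch_times) + 1L]
      E <- c(model$E_open, model$E_closed)[st]
      mean(runif(length(t0)) < E)
    }, numeric(1))
  }
  draws <- replicate(n_draws, recolor_once(), simplify = FALSE)
  pooled <- unlist(draws)
  d_obs <- ks_distance(obs_E, pooled)
  d_null <- vapply(draws, ks_distance, numeric(1), y = pooled)
  thr <- as.numeric(quantile(d_null, 0.95))
  list(distance = d_obs, null_distances = d_null, threshold = thr,
       pass = d_obs <= thr)
}

#' Time-resolved burst variance analysis
#'
#' Splits each burst's donor-excitation photons into consecutive windows of
#' `window` photons, computes the FRET efficiency of every window, and
#' compares the observed standard deviation of the window efficiencies with
#' the binomial shot-noise expectation `sqrt(E (1 - E) / window)`. Bursts
#' whose efficiency fluctuates only by shot noise are static on the window
#' timescale; conformational dynamics push the observed spread above the
#' shot-noise curve.
#'
#' @param bursts list of `photon_burst` objects
#' @param window photons per window
#' @return data.frame with one row per analysed burst: `mean_E`,
#'   `sd_E`, `shot_sd`, `n_windows`; the number of skipped bursts (fewer
#'   than two windows) is attached as attribute `skipped`
#' @export
burst_variance_analysis <- function(bursts, window = 100) {
  rows <- list(); skipped <- 0L
  for (b in bursts) {
    ph <- burst_dex_photons(b)
    m <- length(ph$acceptor) %/% window
    if (m < 2L) { skipped <- skipped + 1L; next }
    idx <- seq_len(m * window)
    wE <- colMeans(matrix(ph$acceptor[idx], nrow = window))
    Ebar <- mean(ph$acceptor)
    rows[[length(rows) + 1L]] <-
      data.frame(mean_E = Ebar, sd_E = sd(wE),
                 shot_sd = sqrt(Ebar * (1 - Ebar) / window), n_windows = m)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(mean_E = numeric(0), sd_E = numeric(0),
                         shot_sd = numeric(0), n_windows = integer(0))
  attr(out, "skipped") <- skipped
  out
}
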