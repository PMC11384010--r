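#' State space of the conformational-kinetic model
#'
#' The reaction network tracks six ligation states of adenylate kinase --
#' apoenzyme `E`, binary complexes `ET` (ATP-bound) and `EM` (AMP-bound),
#' the two inactive ternary complexes `ETMi` ("ATP first" order) and
#' `EMTi` ("AMP first" order), and the catalytically competent ternary
#' complex `ETM`. Each ligation state exists as an open and a closed
#' conformer, giving twelve states in total. The enumeration below fixes
#' the matrix ordering used throughout the package: states are listed
#' ligation-major, open before closed, so state `2*(i-1)+1` is the open
#' conformer of ligation state `i` and `2*(i-1)+2` its closed conformer.
#'
#' @format `ak_ligation_states()` returns the six ligation-state labels in
#'   canonical order; `ak_state_labels()` returns the twelve conformer
#'   labels, e.g. `"ET.open"`.
#' @export
ak_ligation_states <- function() c("E", "ET", "EM", "ETMi", "EMTi", "ETM")

#' @rdname ak_ligation_states
#' @export
ak_state_labels <- function() {
  as.vector(t(outer(ak_ligation_states(), c("open", "closed"), paste, sep = ".")))
}

#' @rdname ak_ligation_states
#' @param ligation ligation-state label
#' @param conformation `"open"` or `"closed"`
#' @export
ak_state_index <- function(ligation, conformation = c("open", "closed")) {
  conformation <- match.arg(conformation)
  i <- match(ligation, ak_ligation_states())
  if (anyNA(i)) stop("unknown ligation state: ", ligation)
  2L * (i - 1L) + if (conformation == "open") 1L else 2L
}

#' Per-ligation-state conformational exchange rates
#'
#' Builds the table of domain opening and closing rates used by the kinetic
#' model. Rates may be given directly, or derived from an equilibrium
#' coefficient `K_C = k_close/k_open` together with a total relaxation rate
#' `lambda = k_open + k_close`. Single-molecule FRET measurements put the
#' LID-domain transitions of adenylate kinase in the tens-of-microseconds
#' range, two orders of magnitude faster than turnover, so the default
#' relaxation rate is 6e4 s^-1.
#'
#' @param K_C named numeric vector of closed/open equilibrium coefficients,
#'   one entry per ligation state (names from [ak_ligation_states()]).
#' @param relaxation total exchange rate `k_open + k_close` (s^-1); scalar
#'   or named per-ligation vector.
#' @param k_open,k_close alternatively, named vectors of explicit rates
#'   (s^-1); both must be supplied together and override `K_C`.
#' @return a data.frame with row names the ligation states and columns
#'   `k_open`, `k_close` (s^-1), of class `ak_conf_rates`.
#' @examples
#' ak_conf_rates(K_C = c(E = 0.16, ET = 1.28, EM = 0.16,
#'                       ETMi = 1.65, EMTi = 1.65, ETM = 1.65))
#' @export
ak_conf_rates <- function(K_C = NULL, relaxation = 6e4,
                          k_open = NULL, k_close = NULL) {
  lig <- ak_ligation_states()
  if (!is.null(k_open) || !is.null(k_close)) {
    if (is.null(k_open) || is.null(k_close))
      stop("supply both k_open and k_close, or neither")
    k_open <- k_open[lig]; k_close <- k_close[lig]
  } else {
    if (is.null(K_C)) stop("supply K_C or explicit rates")
    K_C <- K_C[lig]
    if (anyNA(K_C)) stop("K_C must be named for every ligation state")
    lam <- if (length(relaxation) == 1L) rep(relaxation, 6L) else relaxation[lig]
    k_close <- lam * K_C / (1 + K_C)
    k_open  <- lam / (1 + K_C)
  }
  if (anyNA(k_open) || anyNA(k_close) ||
      any(k_open <= 0) || any(k_close <= 0) ||
      any(!is.finite(k_open)) || any(!is.finite(k_close)))
    stop("conformational rates must be finite and > 0 for every ligation state")
  structure(data.frame(k_open = as.numeric(k_open),
                       k_close = as.numeric(k_close),
                       row.names = lig),
            class = c("ak_conf_rates", "data.frame"))
}

#' Kinetic model parameters
#'
#' Bundles the rate and equilibrium constants of the twelve-state model:
#' the phosphotransfer rate `k_cat` (from the closed active ternary
#' complex), the substrate-rearrangement rates `k_r_T` ("ATP first"
#' pathway) and `k_r_M` ("AMP first" pathway), the dissociation constants
#' for ATP and AMP, a common bimolecular association rate `k_on`
#' (diffusion-limited, 1e8 M^-1 s^-1 by default; dissociation rates follow
#' from `k_off = k_on * Kd`), and the per-ligation-state conformational
#' rates.
#'
#' @param k_cat phosphotransfer rate (s^-1)
#' @param k_r_T rearrangement rate in the "ATP first" pathway (s^-1)
#' @param k_r_M rearrangement rate in the "AMP first" pathway (s^-1)
#' @param Kd_ATP,Kd_AMP dissociation constants (M)
#' @param k_on association rate (M^-1 s^-1), shared by both ligands
#' @param conf_rates an [ak_conf_rates] table
#' @return an object of class `ak_params`
#' @seealso [ak_params_wt()] for the published wild-type parameter set
#' @export
ak_params <- function(k_cat, k_r_T, k_r_M, Kd_ATP, Kd_AMP,
                      k_on = 1e8, conf_rates = ak_conf_rates(default_kc())) {
  num <- c(k_cat = k_cat, k_r_T = k_r_T, k_r_M = k_r_M,
           Kd_ATP = Kd_ATP, Kd_AMP = Kd_AMP, k_on = k_on)
  if (any(!is.finite(num)) || any(num < 0))
    stop("all kinetic parameters must be finite and non-negative")
  if (Kd_ATP <= 0 || Kd_AMP <= 0 || k_on <= 0)
    stop("Kd and k_on must be strictly positive")
  if (!inherits(conf_rates, "ak_conf_rates"))
    stop("conf_rates must be an ak_conf_rates table")
  structure(list(k_cat = k_cat, k_r_T = k_r_T, k_r_M = k_r_M,
                 Kd_ATP = Kd_ATP, Kd_AMP = Kd_AMP, k_on = k_on,
                 conf_rates = conf_rates),
            class = "ak_params")
}

# conformational equilibria measured by smFRET: apo/AMP-only species open-
# dominated (K_C 0.16); ATP binary at 1.28; ternary species at the value
# measured with both substrates present (1.65). 0.8 M urea shifts the
# ATP-bound species towards open (0.85 and 1.10).
default_kc <- function(urea = 0) {
  if (urea == 0)
    c(E = 0.16, ET = 1.28, EM = 0.16, ETMi = 1.65, EMTi = 1.65, ETM = 1.65)
  else
    c(E = 0.16, ET = 0.85, EM = 0.16, ETMi = 1.10, EMTi = 1.10, ETM = 1.10)
}

#' Published wild-type parameter set
#'
#' The globally fitted wild-type constants (k_cat = 3.1e3 s^-1,
#' k_r_T = 4.2e3 s^-1, k_r_M = 370 s^-1, Kd(ATP) = 50 uM) combined with the
#' urea-dependent measured inputs: Kd(AMP) = 332 / 522 / 758 uM at
#' 0 / 0.4 / 0.8 M urea, and conformational equilibria from the
#' single-molecule measurements (see [ak_conf_rates]). Conformational rates
#' at 0.4 M urea were not measured; the 0 M values are used there.
#'
#' @param urea urea concentration label, one of 0, 0.4, 0.8 (mol/L)
#' @param relaxation total conformational relaxation rate (s^-1)
#' @return an `ak_params` object
#' @export
ak_params_wt <- function(urea = 0, relaxation = 6e4) {
  if (!urea %in% c(0, 0.4, 0.8)) stop("urea must be 0, 0.4 or 0.8")
  kd_amp <- c(`0` = 332e-6, `0.4` = 522e-6, `0.8` = 758e-6)[[as.character(urea)]]
  kc <- default_kc(if (urea == 0.8) 0.8 else 0)
  ak_params(k_cat = 3.1e3, k_r_T = 4.2e3, k_r_M = 370,
            Kd_ATP = 50e-6, Kd_AMP = kd_amp,
            conf_rates = ak_conf_rates(kc, relaxation = relaxation))
}

#' Experimental conditions for the kinetic model
#'
#' @param atp,amp substrate concentrations (M, >= 0); substrates are treated
#'   as undepleted reservoirs at steady state
#' @param enzyme total enzyme concentration (M, > 0); only used when
#'   converting per-enzyme turnover to bulk velocity
#' @param urea urea concentration (mol/L) -- metadata only, urea enters the
#'   model solely through the parameter values supplied
#' @return an object of class `ak_conditions`
#' @export
ak_conditions <- function(atp, amp, enzyme = 4e-9, urea = 0) {
  if (atp < 0 || amp < 0) stop("substrate concentrations must be non-negative")
  if (enzyme <= 0) stop("enzyme concentration must be positive")
  structure(list(atp = atp, amp = amp, enzyme = enzyme, urea = urea),
            class = "ak_conditions")
}

#' @export
print.ak_params <- function(x, ...) {
  cat("Kinetic model parameters (ak_params)\n")
  cat(sprintf("  k_cat  %10.3g s-1   k_r_T %10.3g s-1   k_r_M %10.3g s-1\n",
              x$k_cat, x$k_r_T, x$k_r_M))
  cat(sprintf("  Kd_ATP %10.3g M     Kd_AMP %9.3g M     k_on  %10.3g M-1 s-1\n",
              x$Kd_ATP, x$Kd_AMP, x$k_on))
  cat("  conformational exchange (s-1):\n")
  print(round(as.data.frame(x$conf_rates), 1))
  invisible(x)
}
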