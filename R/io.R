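#' Read and write the package's tabular file formats
#'
#' Plain-CSV readers/writers for the four tabular inputs/outputs: velocity
#' curves (`conc_M,velocity_per_s`), activity datasets
#' (`conc_M,v0_per_s,sem`), titrations (`conc_M,fraction_bound`), product
#' time courses (`time_s,product_M`); photon streams as tab-separated
#' columns (`timestamp_ns,channel,excitation_slot`). All units SI.
#' Readers raise precise errors on empty files and missing columns;
#' header-only files yield zero-row tables.
#'
#' @param path file path
#' @param x object to write
#' @name akdyn-io
NULL

read_checked_csv <- function(path, required, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty input file: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df
}

#' @rdname akdyn-io
#' @export
write_velocity_csv <- function(x, path) {
  stopifnot(all(c("conc_M", "velocity_per_s") %in% names(x)))
  write.csv(x[, c("conc_M", "velocity_per_s")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname akdyn-io
#' @export
read_velocity_csv <- function(path) read_checked_csv(path, c("conc_M", "velocity_per_s"))

#' @rdname akdyn-io
#' @param axis,cosubstrate_M,urea dataset metadata (see [activity_dataset])
#' @export
read_activity_csv <- function(path, axis = "AMP", cosubstrate_M = 1e-3, urea = 0) {
  df <- read_checked_csv(path, c("conc_M", "v0_per_s", "sem"))
  activity_dataset(df$conc_M, df$v0_per_s, df$sem, axis = axis,
                   cosubstrate_M = cosubstrate_M, urea = urea)
}

#' @rdname akdyn-io
#' @export
write_activity_csv <- function(x, path) {
  write.csv(data.frame(conc_M = x$conc_M, v0_per_s = x$v0_per_s, sem = x$sem),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname akdyn-io
#' @export
read_titration_csv <- function(path) {
  df <- read_checked_csv(path, c("conc_M", "fraction_bound"))
  data.frame(L = df$conc_M, f = df$fraction_bound)
}

#' @rdname akdyn-io
#' @export
write_titration_csv <- function(x, path) {
  write.csv(data.frame(conc_M = x$L, fraction_bound = x$f), path, row.names = FALSE)
  invisible(path)
}

#' @rdname akdyn-io
#' @export
read_timecourse_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "product_M"))
  ak_timecourse(df$time_s, df$product_M)
}

#' @rdname akdyn-io
#' @export
write_timecourse_csv <- function(x, path) {
  write.csv(data.frame(time_s = x$time_s, product_M = x$product_M),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname akdyn-io
#' @export
write_photons <- function(x, path) {
  stopifnot(all(c("timestamp_ns", "channel", "excitation_slot") %in% names(x)))
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname akdyn-io
#' @param paths one or several photon files; streams are concatenated and
#'   re-sorted, so chunked acquisitions read identically to a single file
#' @export
read_photons <- function(paths) {
  parts <- lapply(paths, function(p) {
    df <- read_checked_csv(p, c("timestamp_ns", "channel", "excitation_slot"),
                           sep = "\t")
    bad_ch <- setdiff(unique(df$channel), c("donor", "acceptor"))
    if (length(bad_ch)) stop(p, ": unknown channel value(s) ", paste(bad_ch, collapse = ", "))
    bad_sl <- setdiff(unique(df$excitation_slot), c("donor_exc", "acceptor_exc"))
    if (length(bad_sl)) stop(p, ": unknown excitation slot(s) ", paste(bad_sl, collapse = ", "))
    df
  })
  stream <- do.call(rbind, parts)
  stream <- stream[order(stream$timestamp_ns), , drop = FALSE]
  rownames(stream) <- NULL
  class(stream) <- c("photon_stream", "data.frame")
  stream
}

#' @rdname akdyn-io
#' @export
write_params_json <- function(x, path) {
  stopifnot(inherits(x, "ak_params"))
  obj <- list(k_cat = x$k_cat, k_r_T = x$k_r_T, k_r_M = x$k_r_M,
              Kd_ATP = x$Kd_ATP, Kd_AMP = x$Kd_AMP, k_on = x$k_on,
              conf_rates = list(ligation = rownames(x$conf_rates),
                                k_open = x$conf_rates$k_open,
                                k_close = x$conf_rates$k_close))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname akdyn-io
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k_cat", "k_r_T", "k_r_M", "Kd_ATP", "Kd_AMP", "k_on", "conf_rates")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop(path, ": missing field(s) ", paste(miss, collapse = ", "))
  cr <- ak_conf_rates(k_open = setNames(obj$conf_rates$k_open, obj$conf_rates$ligation),
                      k_close = setNames(obj$conf_rates$k_close, obj$conf_rates$ligation))
  ak_params(obj$k_cat, obj$k_r_T, obj$k_r_M, obj$Kd_ATP, obj$Kd_AMP,
            k_on = obj$k_on, conf_rates = cr)
}

#' Run the demonstration analysis pipeline
#'
#' End-to-end orchestration on synthetic inputs: simulate photon streams
#' for a set of smFRET conditions and recover their conformational
#' equilibria with the photon HMM; simulate urea-dependent activity curves
#' and globally re-fit the kinetic rate constants; compute the velocity
#' curves, the single-effect isolation curves and the conformational-rate
#' scan. All numeric tables are written as CSV/JSON into `out_dir`
#' together with a provenance record (configuration hash, seed, package
#' version). Reruns with identical configuration are byte-identical.
#'
#' @param config list (or path to a JSON file) with optional elements
#'   `seed` (default 1), `out_dir` (default `tempfile()`), `n_bursts`
#'   (default 400), `fret_conditions` (named list of K_C values; default
#'   the three reference conditions), `amp_scan` (M), `noise_rel`
#'   (default 0.05), `n_fit_starts` (default 4)
#' @return invisible list with all result tables and the output directory
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    seed = 1, out_dir = tempfile("akdyn_run_"), n_bursts = 400,
    fret_conditions = list(apo = 0.16, atp = 1.28, atp_amp = 1.65),
    amp_scan = 10^seq(-5, log10(0.05), length.out = 12),
    noise_rel = 0.05, n_fit_starts = 4), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # output location is not part of the scientific configuration, so it is
  # excluded from the recorded config (keeps provenance hashes comparable)
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                               auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(cfg$out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                     seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("akdyn")))

  # stage 1: smFRET twin -- simulate, burst-search, fit, K_C table
  message("[pipeline] smFRET simulation + HMM fits")
  kc_rows <- list()
  for (i in seq_along(cfg$fret_conditions)) {
    kc_true <- cfg$fret_conditions[[i]]
    sim <- simulate_photon_stream(fret_sim_config(
      n_bursts = cfg$n_bursts,
      k_open = 5000 / (1 + kc_true), k_close = 5000 * kc_true / (1 + kc_true),
      seed = cfg$seed + i))
    bursts <- burst_search(sim$stream)
    fit <- hmm_fit(bursts, fix_E = c(0.37, 0.72), seed = cfg$seed + i)
    kc_rows[[i]] <- data.frame(condition = names(cfg$fret_conditions)[i],
                               K_C_true = kc_true,
                               K_C_fit = kc_from_model(fit),
                               n_bursts = length(bursts))
  }
  kc_table <- do.call(rbind, kc_rows)
  write.csv(kc_table, file.path(cfg$out_dir, "kc_table.csv"), row.names = FALSE)

  # stage 2: activity twin -- simulate urea series, global re-fit
  message("[pipeline] activity simulation + global fit")
  p0 <- ak_params_wt(0); p8 <- ak_params_wt(0.8)
  ds <- list(
    simulate_activity_curve(p0, ak_conditions(1e-3, 0, urea = 0),
                            cfg$amp_scan, sigma_rel = cfg$noise_rel,
                            seed = cfg$seed + 101),
    simulate_activity_curve(p8, ak_conditions(1e-3, 0, urea = 0.8),
                            cfg$amp_scan, sigma_rel = cfg$noise_rel,
                            seed = cfg$seed + 102))
  inputs <- list(`0` = list(Kd_AMP = p0$Kd_AMP, conf_rates = p0$conf_rates),
                 `0.8` = list(Kd_AMP = p8$Kd_AMP, conf_rates = p8$conf_rates))
  fit <- global_fit(ds, p0, inputs = inputs, n_starts = cfg$n_fit_starts,
                    seed = 1234)
  jsonlite::write_json(
    list(estimate = as.list(fit$estimate), chi2_red = fit$chi2_red,
         converged = fit$converged, provenance = provenance),
    file.path(cfg$out_dir, "global_fit.json"), auto_unbox = TRUE, digits = NA)

  # stage 3: model reports -- velocity curves, effect isolation, rate scan
  message("[pipeline] model report tables")
  cond1 <- ak_conditions(1e-3, 0)
  vel0 <- velocity_curve(p0, cond1, cfg$amp_scan, "AMP")
  vel8 <- velocity_curve(p8, cond1, cfg$amp_scan, "AMP")
  write_velocity_csv(vel0, file.path(cfg$out_dir, "velocity_0M.csv"))
  write_velocity_csv(vel8, file.path(cfg$out_dir, "velocity_0p8M.csv"))
  iso_aff <- isolate_effect(p0, p8, "affinity_only", cond1, cfg$amp_scan)
  iso_dyn <- isolate_effect(p0, p8, "dynamics_only", cond1, cfg$amp_scan)
  write_velocity_csv(iso_aff, file.path(cfg$out_dir, "isolate_affinity.csv"))
  write_velocity_csv(iso_dyn, file.path(cfg$out_dir, "isolate_dynamics.csv"))
  scan <- kc_scan(p0, ak_conditions(1e-3, 10e-3), 10^seq(-2, 2, by = 0.25), "both")
  write.csv(scan, file.path(cfg$out_dir, "kc_scan.csv"), row.names = FALSE)

  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(kc_table = kc_table, fit = fit, velocity = list(vel0, vel8),
                 isolate = list(affinity = iso_aff, dynamics = iso_dyn),
                 kc_scan = scan, out_dir = cfg$out_dir,
                 provenance = provenance))
}
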