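# ---------------------------------------------------------------------------
# Synthetic-data generators: MID datasets with the statistical structure the
# MFA assumes (additive Gaussian noise on mass fractions, clipped and
# renormalized), and growth curves with lag + exponential/logistic structure
# sampled the way a plate reader samples (regular interval, multiplicative
# noise).
# ---------------------------------------------------------------------------

#' Noise model for synthetic MIDs
#' @param sd Additive Gaussian SD per mass fraction (default 0.004, a
#'   typical GC-MS MID repeatability).
#' @param renormalize Clip at zero and renormalize each MID after noising.
#' @param mode `"additive"` or `"multiplicative"` (`sd` then acts as a
#'   relative error).
#' @export
mid_noise_model <- function(sd = 0.004, renormalize = TRUE,
                            mode = c("additive", "multiplicative")) {
  if (sd < 0) stop("noise SD must be non-negative")
  list(sd = sd, renormalize = renormalize, mode = match.arg(mode))
}

#' Generate a synthetic MID dataset from a ground-truth flux distribution
#'
#' Forward-simulates the fragment MIDs under `truth` and the tracer, adds
#' measurement noise, and records the noise SD in the `sd` column.  With the
#' same seed the output is reproducible bit for bit.
#'
#' @param net An `amn` network.
#' @param truth Ground-truth `flux_distribution` (steady-state feasible).
#' @param tracer A `tracer_spec`.
#' @param spec A `measurement_spec`.
#' @param noise A [mid_noise_model()].
#' @param seed RNG seed.
#' @param truth_file Optional path: writes the ground truth as a flux-table
#'   TSV sidecar for later scoring.
#' @return A `mid_dataset`.
#' @export
generate_mid_dataset <- function(net, truth, tracer, spec,
                                 noise = mid_noise_model(), seed = 1,
                                 truth_file = NULL) {
  ss <- validate_steady_state(net, truth)
  if (!ss$pass)
    stop(sprintf("ground-truth fluxes are not steady-state feasible (residual %.3g at %s)",
                 ss$max_residual, ss$worst_metabolite))
  clean <- simulate_mids(net, truth, tracer, spec, check_steady = FALSE)
  ml <- mid_list(clean)
  set.seed(seed)
  noisy <- lapply(ml, function(m) {
    eps <- stats::rnorm(length(m), 0,
                        if (noise$mode == "additive") noise$sd else noise$sd * pmax(m, 1e-12))
    x <- m + eps
    if (noise$renormalize) {
      x <- pmax(x, 0)
      if (sum(x) <= 0) x <- m
      x <- x / sum(x)
    }
    x
  })
  ds <- mid_dataset(noisy, spec, sd = noise$sd, check = FALSE)
  if (!is.null(truth_file)) write_flux_table(truth, truth_file)
  ds
}

#' Specification for synthetic growth curves
#'
#' Emulates batch growth read by a plate reader: constant OD through the
#' lag, then logistic growth toward the carrying capacity, sampled at a
#' regular interval with multiplicative noise; optionally a substrate series
#' depleted through the biomass yield.
#'
#' @param od0 Inoculation OD600.
#' @param mu_max Maximum specific growth rate (h^-1).
#' @param lag Lag time (h).
#' @param capacity Carrying capacity (OD units).
#' @param noise_sd Multiplicative noise SD (0.01 = 1%).
#' @param interval Sampling interval (h); 0.25 mirrors 15-min plate reads.
#' @param duration Total time (h).
#' @param od_to_cdw OD-to-CDW factor (g/L per OD).
#' @param substrate0 Initial substrate (g/L); `NA` for no substrate series.
#' @param yield Biomass yield gCDW/gS used for substrate depletion.
#' @export
growth_generator_spec <- function(od0 = 0.05, mu_max = 0.21, lag = 3.4,
                                  capacity = 3.5, noise_sd = 0.01,
                                  interval = 0.25, duration = 30,
                                  od_to_cdw = 0.39, substrate0 = NA_real_,
                                  yield = 0.35) {
  stopifnot(od0 > 0, mu_max >= 0, lag >= 0, capacity > 0, noise_sd >= 0,
            interval > 0, duration > interval)
  as.list(environment())
}

# noise-free mean curve of the generator
.growth_mean_curve <- function(spec, t) {
  te <- pmax(t - spec$lag, 0)
  K <- spec$capacity; o <- spec$od0
  if (spec$mu_max == 0) return(rep(o, length(t)))
  K * o * exp(spec$mu_max * te) / (K + o * (exp(spec$mu_max * te) - 1))
}

#' Generate synthetic growth curves
#'
#' @param spec A [growth_generator_spec()].
#' @param n_replicates Number of replicate wells.
#' @param seed RNG seed (deterministic output per seed).
#' @param path Optional CSV output path (plate CSV of [read_growth_csv()]).
#' @return Named list of `growth_record`s (invisibly also written to
#'   `path` when given).
#' @export
generate_growth_curves <- function(spec, n_replicates = 6, seed = 1,
                                   path = NULL) {
  stopifnot(n_replicates >= 1)
  t <- seq(0, spec$duration, by = spec$interval)
  mean_od <- .growth_mean_curve(spec, t)
  set.seed(seed)
  out <- list()
  for (r in seq_len(n_replicates)) {
    od <- mean_od * (1 + stats::rnorm(length(t), 0, spec$noise_sd))
    od <- pmax(od, 1e-4)
    subs <- NULL
    if (!is.na(spec$substrate0)) {
      cdw <- od * spec$od_to_cdw
      subs <- pmax(spec$substrate0 - (cdw - cdw[[1L]]) / spec$yield, 0)
    }
    out[[paste0("rep", r)]] <- growth_record(t, od, substrate = subs,
                                             od_to_cdw = spec$od_to_cdw)
  }
  if (!is.null(path)) {
    rows <- do.call(rbind, lapply(names(out), function(w) {
      rec <- out[[w]]
      df <- data.frame(well_or_flask = w, t_h = rec$t, od600 = rec$od)
      if (!is.null(rec$substrate)) df$substrate_gL <- rec$substrate
      df
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  out
}
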