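# Shared test helpers: steady-state flux samplers for the toy networks and a
# cache for expensive fits reused across test files.

# random steady-state flux draw for a network with the given free choices
steady_fluxes <- function(net, fixed, exch = NULL) {
  ids <- reaction_ids(net)
  S <- stoich_matrix(net)
  A <- rbind(S, diag(length(ids))[match(names(fixed), ids), , drop = FALSE])
  v <- qr.solve(A, c(rep(0, nrow(S)), unname(fixed)))
  names(v) <- ids
  ex <- setNames(rep(0, length(ids)), ids)
  if (!is.null(exch)) ex[names(exch)] <- exch
  flux_distribution(ids, v, exch_pct = ex, uptake_id = net$uptake_id)
}

# random strictly-positive draw on the mini-PPP toy (1 net dof + exchanges)
random_mini_ppp_fluxes <- function() {
  net <- mini_ppp_network()
  r5p_out <- runif(1, 2, 30)
  rev <- vapply(net$rxns, `[[`, logical(1), "reversible")
  ex <- setNames(runif(sum(rev), 0, 25), reaction_ids(net)[rev])
  steady_fluxes(net, c(upt = 100, r5p_out = r5p_out), exch = ex)
}

random_tracer <- function(substrate_id, n_carbons) {
  k <- sample(0:n_carbons, 1)
  pos <- sort(sample(n_carbons, k))
  fr <- runif(1, 0.5, 1)
  sp <- list(list(positions = pos, fraction = fr))
  if (fr < 1) sp <- c(sp, list(list(positions = integer(), fraction = 1 - fr)))
  tracer_spec(substrate_id, n_carbons, sp, purity = runif(1, 0.9, 1))
}

# noisy replicate of the packaged ground truth; untruncated Gaussian noise
# so that the variance-weighted SSR really is chi-square distributed (the
# clip-and-renormalize mode stays the default for realistic-looking data)
noisy_edemp_dataset <- function(seed, sd = 0.004) {
  generate_mid_dataset(edemp_network(), edemp_fluxes(), tracer_xylose_12(),
                       edemp_fragments(),
                       noise = mid_noise_model(sd, renormalize = FALSE),
                       seed = seed)
}

# cache shared between test files (testthat sources helpers once per run)
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) assign(key, force(expr), envir = .test_cache)
  get(key, envir = .test_cache)
}

# the flagship noise-free recovery fit, shared across test files;
# 50 multi-starts, seed 1
recovery_fit <- function() cached("recovery_fit", {
  net <- edemp_network()
  truth <- edemp_fluxes()
  ds <- generate_mid_dataset(net, truth, tracer_xylose_12(), edemp_fragments(),
                             noise = mid_noise_model(0), seed = 1)
  ds$sd <- 0.004   # weighting scale for the noise-free fit
  fit_fluxes(net, ds, tracer_xylose_12(), edemp_fragments(),
             measured_rates = list(uptake = 1.45, growth = 0.08),
             n_starts = 50, seed = 1, fixed = c(pyc = 0),
             exch_rxns = c("pgi", "tkt1", "tkt2", "tal"))
})

# twenty noisy-replicate fits (warm-started from the recovery optimum plus
# two random starts each), shared by the calibration and GOF checks
replicate_fits <- function() cached("replicate_fits", {
  net <- edemp_network()
  warm <- recovery_fit()$par
  lapply(1:20, function(s) {
    ds <- noisy_edemp_dataset(seed = 100 + s)
    fit_fluxes(net, ds, tracer_xylose_12(), edemp_fragments(),
               measured_rates = list(uptake = 1.45, growth = 0.08),
               n_starts = 2, seed = s, fixed = c(pyc = 0),
               exch_rxns = c("pgi", "tkt1", "tkt2", "tal"),
               init = list(warm))
  })
})
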