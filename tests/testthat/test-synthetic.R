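test_that("zero noise reproduces the forward simulation exactly", {
  net <- edemp_network()
  ds <- generate_mid_dataset(net, edemp_fluxes(), tracer_xylose_12(),
                             edemp_fragments(), noise = mid_noise_model(0),
                             seed = 3)
  clean <- simulate_mids(net, edemp_fluxes(), tracer_xylose_12(), edemp_fragments())
  expect_equal(ds$fraction, clean$fraction, tolerance = 1e-12)
})

test_that("generated MID CSVs are byte-identical for a fixed seed", {
  net <- edemp_network()
  paths <- replicate(2, tempfile(fileext = ".csv"))
  for (p in paths) {
    ds <- generate_mid_dataset(net, edemp_fluxes(), tracer_xylose_12(),
                               edemp_fragments(), seed = 7)
    write_mid_csv(ds, p)
  }
  expect_identical(readLines(paths[[1]]), readLines(paths[[2]]))
})

test_that("different seeds perturb the same underlying mean", {
  net <- edemp_network()
  a <- generate_mid_dataset(net, edemp_fluxes(), tracer_xylose_12(),
                            edemp_fragments(), seed = 1)
  b <- generate_mid_dataset(net, edemp_fluxes(), tracer_xylose_12(),
                            edemp_fragments(), seed = 2)
  expect_false(identical(a$fraction, b$fraction))
  expect_lt(max(abs(a$fraction - b$fraction)), 0.05)
})

test_that("generated MIDs are valid distributions and carry the noise SD", {
  net <- edemp_network()
  ds <- generate_mid_dataset(net, edemp_fluxes(), tracer_xylose_12(),
                             edemp_fragments(), noise = mid_noise_model(0.01),
                             seed = 4)
  sums <- tapply(ds$fraction, ds$fragment_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_gte(min(ds$fraction), 0)
  expect_equal(unique(ds$sd), 0.01)
})

test_that("an infeasible ground truth is refused", {
  net <- edemp_network()
  bad <- edemp_fluxes()
  bad["gnd", "net_pct"] <- 80   # breaks the Ru5P balance
  expect_error(generate_mid_dataset(net, bad, tracer_xylose_12(),
                                    edemp_fragments()),
               "not steady-state feasible")
})

test_that("the truth sidecar is written in the core flux-table format", {
  net <- edemp_network()
  tmp <- tempfile(fileext = ".tsv")
  generate_mid_dataset(net, edemp_fluxes(), tracer_xylose_12(),
                       edemp_fragments(), seed = 5, truth_file = tmp)
  truth <- load_flux_table(tmp)
  expect_equal(truth$net_pct, edemp_fluxes()$net_pct, tolerance = 1e-9)
})

test_that("more measurement noise means a worse fit of the true model", {
  net <- edemp_network()
  warm <- recovery_fit()$par
  med_ssr <- vapply(c(0.002, 0.004, 0.008), function(sdn) {
    ssrs <- vapply(1:3, function(s) {
      ds <- generate_mid_dataset(net, edemp_fluxes(), tracer_xylose_12(),
                                 edemp_fragments(),
                                 noise = mid_noise_model(sdn), seed = 40 + s)
      ds$sd <- 0.004   # fixed weighting so the SSR tracks the noise level
      fit_fluxes(net, ds, tracer_xylose_12(), edemp_fragments(),
                 measured_rates = list(uptake = 1.45, growth = 0.08),
                 n_starts = 0, seed = s, fixed = c(pyc = 0),
                 exch_rxns = c("pgi", "tkt1", "tkt2", "tal"),
                 init = list(warm))$ssr
    }, numeric(1))
    stats::median(ssrs)
  }, numeric(1))
  expect_true(all(diff(med_ssr) > 0))
})

test_that("growth curves: zero rate gives a flat series; seeds only move the noise", {
  spec0 <- growth_generator_spec(mu_max = 0, noise_sd = 0)
  rec <- generate_growth_curves(spec0, 1, seed = 1)[[1]]
  expect_true(all(rec$od == rec$od[[1]]))

  spec <- growth_generator_spec()
  a <- generate_growth_curves(spec, 1, seed = 1)[[1]]
  b <- generate_growth_curves(spec, 1, seed = 2)[[1]]
  expect_false(identical(a$od, b$od))
  mean_curve <- edempflux:::.growth_mean_curve(spec, a$t)
  expect_lt(abs(mean(a$od / mean_curve) - 1), 0.01)
  expect_lt(abs(mean(b$od / mean_curve) - 1), 0.01)
})

test_that("generated growth curves recover the evolved-strain parameters", {
  # generator truth mirrors the fastest evolved strains: mu 0.21, lag 3.4
  spec <- growth_generator_spec(mu_max = 0.21, lag = 3.4, noise_sd = 0.01)
  recs <- generate_growth_curves(spec, 6, seed = 11)
  mus <- vapply(recs, function(r) fit_growth(r)$mu_max, numeric(1))
  expect_lt(abs(mean(mus) - 0.21) / 0.21, 0.05)
})
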