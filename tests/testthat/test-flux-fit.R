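test_that("the free-flux basis spans exactly the constrained steady states", {
  net <- edemp_network()
  basis <- free_flux_basis(net, c(upt = 100, bm = 5.517241, pyc = 0))
  expect_equal(basis$n_free, 4L)
  S <- stoich_matrix(net)
  set.seed(2)
  for (i in 1:20) {
    u <- runif(basis$n_free, -50, 120)
    v <- flux_from_free(basis, u)
    expect_lt(max(abs(S %*% v)), 1e-8)
    expect_equal(unname(v["upt"]), 100, tolerance = 1e-8)
    expect_equal(unname(v["pyc"]), 0, tolerance = 1e-8)
    expect_equal(unname(v[basis$free]), u, tolerance = 1e-8)
  }
  expect_error(free_flux_basis(net, c(upt = 100, nosuch = 1)), "nosuch")
})

test_that("noise-free synthetic data are recovered to the truth", {
  fit <- recovery_fit()
  truth <- flux_vector(edemp_fluxes(), edemp_network())
  v <- flux_vector(fit$flux, edemp_network())
  expect_lt(fit$ssr, 1e-6)
  major <- abs(truth) > 10
  expect_lt(max(abs(v[major] - truth[major])), 1)
  # the fitted distribution is a steady state with legal directionalities
  rep <- validate_steady_state(edemp_network(), fit$flux)
  expect_true(rep$pass)
  irrev <- !vapply(edemp_network()$rxns, `[[`, logical(1), "reversible")
  expect_gte(min(v[irrev]), -1e-6)
})

test_that("multi-start fitting is deterministic for a fixed seed", {
  net <- edemp_network()
  ds <- noisy_edemp_dataset(seed = 500)
  args <- list(net, ds, tracer_xylose_12(), edemp_fragments(),
               measured_rates = list(uptake = 1.45, growth = 0.08),
               n_starts = 2, seed = 9, fixed = c(pyc = 0),
               exch_rxns = c("pgi", "tkt1", "tkt2", "tal"))
  f1 <- do.call(fit_fluxes, args)
  f2 <- do.call(fit_fluxes, args)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$ssr, f2$ssr)
})

test_that("parameter recovery from noisy replicates stays within 3 points", {
  fits <- replicate_fits()
  truth <- flux_vector(edemp_fluxes(), edemp_network())
  major <- abs(truth) > 10
  errs <- vapply(fits[1:10], function(f) {
    v <- flux_vector(f$flux, edemp_network())
    stats::median(abs(v[major] - truth[major]))
  }, numeric(1))
  expect_lte(stats::median(errs), 3)
})

test_that("the chi-square verdict brackets the SSR correctly", {
  fake <- function(ssr, dof) structure(list(ssr = ssr, dof = dof), class = "flux_fit")
  expect_true(goodness_of_fit(fake(20, 20))$pass)        # SSR = dof = mean
  g <- goodness_of_fit(fake(0, 20))
  expect_false(g$pass)
  expect_equal(g$flag, "fail_low")
  expect_equal(goodness_of_fit(fake(1e3, 20))$flag, "fail_high")
  expect_error(goodness_of_fit(fake(1, 0)), "overparameterized")
})

test_that("noisy replicates mostly pass the chi-square acceptance band", {
  fits <- replicate_fits()
  passes <- vapply(fits, function(f) goodness_of_fit(f)$pass, logical(1))
  expect_gte(sum(passes), 17)
})

test_that("the continuation interval matches the curvature-based interval when the profile is quadratic", {
  fits <- replicate_fits()
  fit <- fits[[1L]]
  ci <- confidence_interval_continuation(fit, "gnd")
  se <- fit$flux["gnd", "sd_pct"]
  half_cont <- (ci$ub - ci$lb) / 2
  half_quad <- 1.96 * se
  # near the optimum the SSR profile is close to quadratic, so the two
  # half-widths agree; bisection stops at 0.1 flux units
  expect_equal(half_cont, half_quad, tolerance = 0.25)
  expect_true(ci$lb < ci$estimate && ci$estimate < ci$ub)
})

test_that("fluxes the data do not sense come back with open or huge intervals", {
  # restrict the measurements to the upper-pathway sugar phosphates: the
  # glyoxylate-shunt flux is then essentially unconstrained
  net <- edemp_network()
  spec <- edemp_fragments()
  spec <- spec[spec$metabolite %in% c("X5P", "R5P", "S7P", "F6P", "G6P", "6PG"), ]
  class(spec) <- c("measurement_spec", "data.frame")
  ds <- generate_mid_dataset(net, edemp_fluxes(), tracer_xylose_12(), spec,
                             noise = mid_noise_model(0.004), seed = 77)
  fit <- fit_fluxes(net, ds, tracer_xylose_12(), spec,
                    measured_rates = list(uptake = 1.45, growth = 0.08),
                    n_starts = 3, seed = 2, fixed = c(pyc = 0),
                    exch_rxns = c("tkt1", "tkt2", "tal"))
  ci <- confidence_interval_continuation(fit, "icl", range_cap = 60)
  width <- ci$ub - ci$lb
  expect_true(ci$open_ub || ci$open_lb || width > 20)
})

test_that("profiling a fixed flux is refused", {
  fit <- recovery_fit()
  expect_error(confidence_interval_continuation(fit, "pyc"), "fixed")
  expect_error(confidence_interval_continuation(fit, "nope"), "unknown reaction")
})
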