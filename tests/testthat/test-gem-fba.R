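toy_gem <- function() load_bigg_json(system.file("extdata", "toy_gem_synthetic.json",
                                                 package = "edempflux"))

micro_model <- function() load_bigg_json('{
  "id": "micro",
  "metabolites": [
    {"id": "a_e", "compartment": "e"}, {"id": "a_c", "compartment": "c"},
    {"id": "b_c", "compartment": "c"}],
  "reactions": [
    {"id": "EX_a_e", "metabolites": {"a_e": -1}, "lower_bound": -10, "upper_bound": 0},
    {"id": "T", "metabolites": {"a_e": -1, "a_c": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "C", "metabolites": {"a_c": -1, "b_c": 0.5}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "BM", "metabolites": {"b_c": -1}, "lower_bound": 0, "upper_bound": 1000,
     "objective_coefficient": 1}],
  "genes": []
}')

test_that("a minimal hand-written BIGG JSON loads with the right dimensions", {
  m <- micro_model()
  S <- gem_stoich(m)
  expect_equal(c(S$nrow, S$ncol), c(3L, 4L))
  expect_equal(m$rxns$EX_a_e$lb, -10)
})

test_that("BIGG JSON round-trips with identical bounds", {
  m <- toy_gem()
  m2 <- load_bigg_json(write_bigg_json(m))
  expect_equal(vapply(m2$rxns, `[[`, numeric(1), "lb"),
               vapply(m$rxns, `[[`, numeric(1), "lb"))
  expect_equal(vapply(m2$rxns, `[[`, numeric(1), "ub"),
               vapply(m$rxns, `[[`, numeric(1), "ub"))
  expect_equal(m2$mets$formula, m$mets$formula)
})

test_that("a 2-step chain with 50% yield grows at half the uptake bound", {
  sol <- solve_fba(micro_model())
  expect_equal(sol$objective, 5, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[["EX_a_e"]]), -10, tolerance = 1e-8)
})

test_that("the xylose surgery adds the isomerase route and removes GCD", {
  m <- toy_gem()
  expect_true("GCD" %in% names(m$rxns))
  m2 <- apply_xylose_surgery(m)
  expect_false("GCD" %in% names(m2$rxns))
  expect_true(all(c("EX_xyl__D_e", "XYLtex", "XYLt2pp", "XYLI1", "XYLK") %in%
                    names(m2$rxns)))
  expect_equal(length(m2$rxns), length(m$rxns) + 5L - 1L)
  # idempotency: applying twice collides on the added species
  expect_error(apply_xylose_surgery(m2), "already")
  # missing cofactor species
  m_broken <- m; m_broken$mets <- m$mets[m$mets$id != "h_p", ]
  expect_error(apply_xylose_surgery(m_broken), "h_p")
})

test_that("with the isomerase knocked out, forced xylose uptake is infeasible", {
  m <- apply_xylose_surgery(toy_gem())
  m <- fix_uptake(m, "EX_xyl__D_e", 1.45)
  m$rxns$XYLI1$lb <- 0; m$rxns$XYLI1$ub <- 0
  sol <- solve_fba(m)
  expect_false(identical(sol$status, "optimal"))
})

test_that("MFA bounds are mean +/- 1.96 SE, with SE 0 fixing the flux", {
  fl <- flux_distribution(c("upt", "r"), c(100, 50), sd_pct = c(0, 2),
                          uptake_rate_abs = 100)
  spec <- mfa_bounds_spec(fl, data.frame(core_rxn = "r", gem_ids = "R1", sign = 1))
  expect_equal(spec$lb, 50 - 3.92)
  expect_equal(spec$ub, 50 + 3.92)

  fl0 <- flux_distribution(c("upt", "r"), c(100, 50), sd_pct = 0,
                           uptake_rate_abs = 100)
  spec0 <- mfa_bounds_spec(fl0, data.frame(core_rxn = "r", gem_ids = "R1", sign = 1))
  expect_equal(spec0$lb, spec0$ub)

  m <- micro_model()
  expect_error(apply_mfa_bounds(m, data.frame(gem_ids = "T", lb = 5, ub = 2)),
               "crossed")
  expect_error(apply_mfa_bounds(m, data.frame(gem_ids = "NOPE", lb = 0, ub = 1)),
               "unknown GEM reaction")
})

test_that("grouped bounds constrain the summed flux at the optimum", {
  m <- apply_xylose_surgery(toy_gem())
  m <- fix_uptake(m, "EX_xyl__D_e", 1.45)
  spec <- data.frame(gem_ids = "THD1;THD2", lb = 0.3, ub = 0.4)
  m2 <- apply_mfa_bounds(m, spec)
  sol <- solve_fba(m2)
  tot <- sol$fluxes[["THD1"]] + sol$fluxes[["THD2"]]
  expect_gte(tot, 0.3 - 1e-6)
  expect_lte(tot, 0.4 + 1e-6)
})

test_that("optimal solutions satisfy mass balance independently of the solver", {
  m <- apply_xylose_surgery(toy_gem())
  m <- fix_uptake(m, "EX_xyl__D_e", 1.45)
  for (tb in c("none", "parsimonious")) {
    sol <- solve_fba(m, tie_break = tb)
    S <- gem_stoich(m)
    r <- numeric(S$nrow)
    for (k in seq_along(S$i)) r[S$i[k]] <- r[S$i[k]] + S$x[k] * sol$fluxes[[S$j[k]]]
    expect_lt(max(abs(r)), 1e-6)
  }
})

test_that("the parsimonious tie-break preserves the optimum and shrinks flux", {
  m <- apply_xylose_surgery(toy_gem())
  m <- fix_uptake(m, "EX_xyl__D_e", 1.45)
  plain <- solve_fba(m, tie_break = "none")
  pars <- solve_fba(m, tie_break = "parsimonious")
  expect_equal(pars$objective, plain$objective, tolerance = 1e-9)
  expect_lte(sum(abs(pars$fluxes)), sum(abs(plain$fluxes)) + 1e-6)
})

test_that("adding constraints never increases the optimum", {
  m <- apply_xylose_surgery(toy_gem())
  m <- fix_uptake(m, "EX_xyl__D_e", 1.45)
  base <- solve_fba(m)$objective
  set.seed(13)
  internal <- setdiff(names(m$rxns), c("EX_xyl__D_e", "BIOMASS_toy"))
  for (i in 1:8) {
    rid <- sample(internal, 1)
    m2 <- m
    m2$rxns[[rid]]$ub <- min(m2$rxns[[rid]]$ub, runif(1, 0, 2))
    sol <- solve_fba(m2, tie_break = "none")
    if (identical(sol$status, "optimal")) expect_lte(sol$objective, base + 1e-8)
  }
})

test_that("cofactor production counts producers only", {
  m <- toy_gem()
  sol <- structure(list(status = "optimal", tie_break = "none",
                        objective = 0,
                        fluxes = setNames(rep(0, length(m$rxns)), names(m$rxns))),
                   class = "fba_solution")
  sol$fluxes[["THD1"]] <- 2
  expect_equal(cofactor_summary(m, sol)$nadph_sum, 2)
  sol$fluxes[["THD1"]] <- -2
  expect_equal(cofactor_summary(m, sol)$nadph_sum, 0)
  expect_error(cofactor_summary(m, sol, nadph = "^nadph_z$"), "unresolvable")
})

test_that("net CO2 excludes exchange reactions, so it equals the export rate", {
  m <- apply_xylose_surgery(toy_gem())
  m <- fix_uptake(m, "EX_xyl__D_e", 1.45)
  sol <- solve_fba(m)
  cs <- cofactor_summary(m, sol)
  expect_equal(cs$co2_net, sol$fluxes[["EX_co2_e"]], tolerance = 1e-8)
})

test_that("identical constraints give unit ratios; forced bypass raises CO2", {
  m <- apply_xylose_surgery(toy_gem())
  m <- fix_uptake(m, "EX_xyl__D_e", 1.45)
  same <- compare_models(m, data.frame(gem_ids = character(), lb = numeric(),
                                       ub = numeric()))
  expect_equal(same$summary$ratio_mfa_fba, rep(1, 4), tolerance = 1e-8)

  # pseudo-MFA bounds force the decarboxylating bypass and transhydrogenase
  spec <- data.frame(gem_ids = c("OXID", "THD1;THD2"),
                     lb = c(0.5, 0.3), ub = c(0.6, 0.4))
  cmp <- compare_models(m, spec, fva_report = TRUE)
  s <- cmp$summary
  expect_true(all(c("OXID", "THD1", "EX_co2_e") %in% cmp$fva_mfa$reaction))
  expect_true(all(cmp$fva_mfa$min <= cmp$fva_mfa$max + 1e-9))
  expect_gt(s$ratio_mfa_fba[s$quantity == "co2_net"], 1)
  expect_gt(s$ratio_mfa_fba[s$quantity == "nadph_sum"], 1)
  expect_gt(s$ratio_mfa_fba[s$quantity == "nadh_sum"], 1)
  expect_lte(s$ratio_mfa_fba[s$quantity == "growth"], 1 + 1e-9)
})

test_that("FVA bounds enclose the parsimonious solution", {
  m <- apply_xylose_surgery(toy_gem())
  m <- fix_uptake(m, "EX_xyl__D_e", 1.45)
  sol <- solve_fba(m)
  rng <- fva(m, c("PPP", "OXID", "RESP"))
  for (k in seq_len(nrow(rng))) {
    v <- sol$fluxes[[rng$reaction[k]]]
    expect_gte(v, rng$min[k] - 1e-6)
    expect_lte(v, rng$max[k] + 1e-6)
  }
})

test_that("the packaged core-to-GEM mapping covers the measured core reactions", {
  map <- edemp_gem_mapping()
  expect_true(all(c("pgi", "gnd", "edd", "mdh") %in% map$core_rxn))
  expect_true("MDH;MDH2" %in% map$gem_ids)   # the grouped pair
  spec <- mfa_bounds_spec(edemp_fluxes(), map)
  expect_true(all(spec$lb <= spec$ub))
  # absolute scale: pgi = 89% of 1.45 mmol/gCDW/h
  expect_equal(spec$lb[spec$core_rxn == "pgi"] + 1.96 * 2.67 / 100 * 1.45,
               0.89 * 1.45, tolerance = 1e-6)
})
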