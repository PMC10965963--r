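test_that("a bare backbone with ideal carbon gives the identity matrix", {
  cfg <- correction_config(abundance = utils::modifyList(natural_abundance(),
                                                         list(C = c(1, 0))))
  M <- correction_matrix(fragment_formula(C = 3, backbone_carbons = 3), cfg)
  expect_equal(M[1:4, ], diag(4), ignore_attr = TRUE)
})

test_that("the C3 backbone column reproduces the binomial closed form", {
  M <- correction_matrix(fragment_formula(C = 3, backbone_carbons = 3))
  expect_equal(M["M+1", "L0"], 3 * 0.0107 * 0.9893^2, tolerance = 1e-10)
  expect_equal(M["M+1", "L0"], 0.03141, tolerance = 1e-3)
})

test_that("correction-matrix columns are stochastic", {
  fo <- fragment_formula(C = 11, H = 26, N = 1, O = 2, Si = 2, backbone_carbons = 3)
  expect_equal(unname(colSums(correction_matrix(fo))), rep(1, 4), tolerance = 1e-12)
})

test_that("convolving element distributions equals the summed-shift law", {
  # brute-force convolution over the joint shifts of two elements
  ab <- natural_abundance()
  d1 <- ab$O; d2 <- ab$Si
  joint <- outer(d1, d2)
  direct <- vapply(0:(length(d1) + length(d2) - 2), function(s) {
    tot <- 0
    for (i in seq_along(d1)) for (j in seq_along(d2))
      if ((i - 1) + (j - 1) == s) tot <- tot + joint[i, j]
    tot
  }, numeric(1))
  expect_equal(edempflux:::.conv(d1, d2), direct, tolerance = 1e-14)
})

test_that("natural-abundance correction inverts its own convolution", {
  fo <- fragment_formula(C = 11, H = 26, N = 1, O = 2, Si = 2, backbone_carbons = 3)
  M <- correction_matrix(fo)
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    clean <- runif(4); clean <- clean / sum(clean)
    rec <- correct_mid(drop(M %*% clean), fo)
    worst <- max(worst, max(abs(rec - clean)))
  }
  expect_lt(worst, 1e-6)
})

test_that("an unlabelled biological sample corrects to pure M+0", {
  fo <- fragment_formula(C = 18, H = 40, N = 1, O = 4, Si = 3, backbone_carbons = 4)
  obs <- drop(correction_matrix(fo) %*% c(1, 0, 0, 0, 0))
  expect_equal(as.numeric(correct_mid(obs, fo)), c(1, 0, 0, 0, 0), tolerance = 1e-8)
})

test_that("short observation vectors and missing elements are rejected", {
  fo <- fragment_formula(C = 3, backbone_carbons = 3)
  expect_error(correct_mid(c(0.9, 0.1), fo), "too short")
  cfg <- correction_config()
  cfg$abundance$Si <- NULL
  expect_error(correction_matrix(fragment_formula(C = 3, Si = 2, backbone_carbons = 3),
                                 cfg), "lacks element 'Si'")
})

test_that("unlabelled-biomass removal inverts the inoculum mixture", {
  expect_equal(remove_unlabeled_biomass(c(0.2, 0.3, 0.5), 0), c(0.2, 0.3, 0.5))
  mixed <- 0.5 * c(1, 0, 0) + 0.5 * c(0, 0, 1)
  expect_equal(remove_unlabeled_biomass(mixed, 0.5), c(0, 0, 1))
  expect_error(remove_unlabeled_biomass(c(1, 0), 1), "\\[0, 1\\)")
  expect_error(remove_unlabeled_biomass(c(1, 0), 1.2), "\\[0, 1\\)")
})

test_that("correction steps commute as linear maps", {
  # natural-abundance correction then biomass removal equals applying the
  # jointly composed linear correction
  fo <- fragment_formula(C = 5, H = 11, O = 8, backbone_carbons = 5)
  M <- correction_matrix(fo)
  f <- 0.07
  set.seed(3)
  clean <- runif(6); clean <- clean / sum(clean)
  unl <- c(1, numeric(5))
  observed <- drop(M %*% ((1 - f) * clean + f * unl))
  stepwise <- remove_unlabeled_biomass(as.numeric(correct_mid(observed, fo)), f)
  joint <- drop(MASS::ginv(M %*% ((1 - f) * diag(6))) %*%
                  (observed - f * drop(M %*% unl)))
  expect_equal(stepwise, joint / sum(joint), tolerance = 1e-8)
})

test_that("a synthetic dataset with inoculum carry-over round-trips", {
  net <- edemp_network()
  spec <- edemp_fragments()
  clean <- simulate_mids(net, edemp_fluxes(), tracer_xylose_12(), spec)
  formulas <- edemp_fragment_formulas()
  f <- 0.05
  # forward-model what the instrument sees: biomass mixing, then the
  # derivatization/natural-abundance convolution, then noise
  sdn <- 0.002
  set.seed(21)
  observed <- list()
  for (fid in spec$fragment_id) {
    row <- formulas[formulas$fragment_id == fid, ]
    fo <- fragment_formula(row$C, row$H, row$N, row$O, row$Si, row$S,
                           row$backbone_carbons)
    m <- mid_vector(clean, fid)
    mixed <- (1 - f) * m + f * c(1, numeric(length(m) - 1L))
    obs <- drop(correction_matrix(fo) %*% mixed)
    obs <- pmax(obs + rnorm(length(obs), 0, sdn), 0)
    observed[[fid]] <- obs / sum(obs)
  }
  ds <- mid_dataset(observed, spec, sd = sdn, check = FALSE)
  corr <- correct_mid_dataset(ds, formulas, spec,
                              correction_config(unlabeled_biomass_fraction = f))
  err <- abs(corr$fraction[match(paste(clean$fragment_id, clean$mass_shift),
                                 paste(corr$fragment_id, corr$mass_shift))] -
               clean$fraction)
  expect_lt(stats::median(err, na.rm = TRUE), sdn)
  expect_lt(max(err, na.rm = TRUE), 6 * sdn)
})
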