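# ---------------------------------------------------------------------------
# Correction of measured MIDs for natural isotope abundance and for
# unlabelled biomass carried over with the inoculum.
#
# The observed mass distribution of a derivatized fragment is the backbone
# label MID convolved with (i) natural heavy-isotope distributions of every
# non-backbone atom and (ii) natural 13C on the unlabelled backbone
# positions.  Correction inverts that linear map by non-negative least
# squares.
# ---------------------------------------------------------------------------

#' Natural isotope abundances (IUPAC 2013 representative values)
#'
#' Mass-shift probability vectors per element, index 1 = shift 0.
#' @return Named list of numeric vectors.
#' @export
natural_abundance <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
}

#' Correction configuration
#' @param abundance Natural-abundance table as from [natural_abundance()].
#' @param unlabeled_biomass_fraction Fraction of the analysed biomass that
#'   derives from the unlabelled inoculum, in `[0, 1)`.
#' @export
correction_config <- function(abundance = natural_abundance(),
                              unlabeled_biomass_fraction = 0) {
  for (el in names(abundance))
    if (abs(sum(abundance[[el]]) - 1) > 1e-6)
      stop(sprintf("abundances for element %s do not sum to 1", el))
  if (unlabeled_biomass_fraction < 0 || unlabeled_biomass_fraction >= 1)
    stop("unlabeled_biomass_fraction must be in [0, 1)")
  list(abundance = abundance,
       unlabeled_biomass_fraction = unlabeled_biomass_fraction)
}

#' Fragment elemental formula
#' @param C,H,N,O,Si,S Element counts of the observed (derivatized) fragment.
#' @param backbone_carbons Number of carbon positions belonging to the
#'   metabolite backbone (the correctable label positions).
#' @export
fragment_formula <- function(C, H = 0, N = 0, O = 0, Si = 0, S = 0,
                             backbone_carbons) {
  if (backbone_carbons > C) stop("backbone carbons exceed total carbon count")
  list(C = C, H = H, N = N, O = O, Si = Si, S = S,
       backbone_carbons = backbone_carbons)
}

# n-fold self-convolution of an element's isotope distribution
.element_dist <- function(d, n) {
  out <- 1
  if (n > 0) for (i in seq_len(n)) out <- .conv(out, d)
  out
}

#' Natural-abundance correction matrix
#'
#' Column j (backbone mass shift j-1) holds the observed mass distribution of
#' a fragment whose backbone carries exactly j-1 tracer labels: the
#' convolution of all non-backbone-atom natural isotope distributions with
#' the natural-13C binomial over the remaining unlabelled backbone positions,
#' shifted by j-1.  Columns are stochastic (sum to 1).
#'
#' @param formula A [fragment_formula()].
#' @param cfg A [correction_config()].
#' @return Matrix with `backbone_carbons + 1` columns.
#' @export
correction_matrix <- function(formula, cfg = correction_config()) {
  ab <- cfg$abundance
  nb <- formula$backbone_carbons
  counts <- c(C = formula$C - nb, H = formula$H, N = formula$N,
              O = formula$O, Si = formula$Si, S = formula$S)
  for (el in names(counts)[counts > 0])
    if (is.null(ab[[el]]))
      stop(sprintf("abundance table lacks element '%s' present in formula", el))
  base <- 1
  for (el in names(counts)) base <- .conv(base, .element_dist(ab[[el]], counts[[el]]))
  aC <- ab$C
  cols <- lapply(0:nb, function(j) {
    bb <- .element_dist(aC, nb - j)          # natural 13C on unlabelled positions
    .conv(.conv(base, bb), c(numeric(j), 1)) # shift by the j tracer labels
  })
  nr <- max(vapply(cols, length, integer(1)))
  M <- vapply(cols, function(cl) c(cl, numeric(nr - length(cl))), numeric(nr))
  dimnames(M) <- list(paste0("M+", seq_len(nr) - 1L), paste0("L", 0:nb))
  M
}

#' Correct an observed mass distribution for natural abundance
#'
#' Solves `observed = correction_matrix %*% mid` for the backbone-label MID
#' by non-negative least squares, renormalizes to sum 1 and reports the
#' residual.  A quality warning is attached when the residual exceeds
#' `residual_warn`.
#'
#' @param observed Numeric vector of observed mass fractions
#'   (`M+0 ... M+k`, `k >= backbone_carbons`).
#' @param formula A [fragment_formula()].
#' @param cfg A [correction_config()].
#' @param residual_warn Residual norm triggering a quality flag.
#' @return Numeric MID of length `backbone_carbons + 1` with attributes
#'   `residual` and (possibly) `quality_warning`.
#' @export
correct_mid <- function(observed, formula, cfg = correction_config(),
                        residual_warn = 0.01) {
  nb <- formula$backbone_carbons
  if (length(observed) < nb + 1L)
    stop(sprintf("observed vector too short: %d < %d", length(observed), nb + 1L))
  M <- correction_matrix(formula, cfg)
  n <- min(nrow(M), length(observed))
  fit <- pracma::lsqnonneg(M[seq_len(n), , drop = FALSE], observed[seq_len(n)])
  x <- fit$x
  res <- sqrt(sum((M[seq_len(n), , drop = FALSE] %*% x - observed[seq_len(n)])^2))
  if (sum(x) <= 0) stop("correction produced an all-zero MID")
  x <- x / sum(x)
  attr(x, "residual") <- res
  if (res > residual_warn)
    attr(x, "quality_warning") <-
      sprintf("correction residual %.4g exceeds %.4g", res, residual_warn)
  x
}

#' Remove the unlabelled-biomass contribution from a corrected MID
#'
#' Proteinogenic amino acids sampled after a labelling experiment contain a
#' fraction `f` of molecules synthesized before the tracer switch (inoculum
#' carry-over).  Assuming that population is unlabelled (M+0 after
#' natural-abundance correction), the labelled-population MID is
#' `(observed - f * unlabeled) / (1 - f)`, clipped at zero and renormalized.
#'
#' @param corrected Natural-abundance-corrected MID vector.
#' @param f Unlabelled biomass fraction in `[0, 1)`.
#' @param unlabeled MID of the unlabelled population (default: pure M+0).
#' @return Corrected MID of the labelled population.
#' @export
remove_unlabeled_biomass <- function(corrected, f,
                                     unlabeled = c(1, numeric(length(corrected) - 1L))) {
  if (f < 0 || f >= 1) stop("unlabelled biomass fraction must be in [0, 1)")
  if (f == 0) return(corrected)
  out <- (corrected - f * unlabeled) / (1 - f)
  out[out < 0] <- 0
  if (sum(out) <= 0) stop("biomass correction produced an all-zero MID")
  out / sum(out)
}

#' Correct a whole MID dataset
#'
#' Applies [correct_mid()] (and optionally [remove_unlabeled_biomass()]) to
#' every fragment of a dataset, using a fragment formula table.
#'
#' @param ds A `mid_dataset` of observed mass distributions.
#' @param formulas Data frame as from [edemp_fragment_formulas()].
#' @param cfg A [correction_config()]; its `unlabeled_biomass_fraction` is
#'   applied after natural-abundance correction.
#' @param spec The `measurement_spec` (for rebuilding the dataset).
#' @return A corrected `mid_dataset`.
#' @export
correct_mid_dataset <- function(ds, formulas, spec, cfg = correction_config()) {
  sds <- stats::aggregate(sd ~ fragment_id, data = as.data.frame(ds), FUN = max)
  out <- list()
  for (fid in unique(ds$fragment_id)) {
    row <- formulas[formulas$fragment_id == fid, , drop = FALSE]
    if (!nrow(row)) stop(sprintf("no formula for fragment '%s'", fid))
    fo <- fragment_formula(row$C, row$H, row$N, row$O, row$Si, row$S,
                           row$backbone_carbons)
    x <- correct_mid(mid_vector(ds, fid), fo, cfg)
    x <- remove_unlabeled_biomass(x, cfg$unlabeled_biomass_fraction)
    out[[fid]] <- as.numeric(x)
  }
  mid_dataset(out, spec, sd = setNames(sds$sd, sds$fragment_id)[names(out)],
              check = FALSE)
}
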