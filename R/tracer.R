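# ---------------------------------------------------------------------------
# Tracer specifications: isotopically labelled substrate mixtures.
# ---------------------------------------------------------------------------

#' Define a tracer
#'
#' A tracer is a mixture of labelled substrate species.  Each species gives
#' the positions carrying the heavy label; `purity` is the isotopic purity of
#' a nominally labelled position (e.g. 0.99 for a 99 atom-percent tracer).
#' Nominally unlabelled positions are treated as carbon-12 ("ideal atoms"):
#' natural heavy-isotope abundance is a measurement-side phenomenon handled
#' by the MID correction module.
#'
#' @param substrate_id Metabolite id of the (source) substrate.
#' @param n_carbons Number of substrate carbons.
#' @param species List of `list(positions = <integer vector of labelled
#'   1-based positions>, fraction = <mole fraction>)`.
#' @param purity Fraction of nominally labelled positions that actually carry
#'   the label.
#' @return A `tracer_spec` object.
#' @examples
#' # 100% 1,2-13C xylose at 99% purity
#' tracer_spec("XYL_ext", 5, list(list(positions = c(1, 2), fraction = 1)), 0.99)
#' @export
tracer_spec <- function(substrate_id, n_carbons, species, purity = 1) {
  fr <- vapply(species, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) stop("species mole fractions must sum to 1")
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
  for (sp in species) {
    if (length(sp$positions) && (min(sp$positions) < 1 || max(sp$positions) > n_carbons))
      stop("labelled positions outside 1..n_carbons")
  }
  structure(list(substrate_id = substrate_id, n_carbons = n_carbons,
                 species = species, purity = purity),
            class = "tracer_spec")
}

#' Reference tracer: 1,2-13C xylose at 99% purity
#' @param purity Isotopic purity (default 0.99).
#' @param fraction Mole fraction of the labelled species; the remainder is
#'   unlabelled xylose.
#' @export
tracer_xylose_12 <- function(purity = 0.99, fraction = 1) {
  sp <- list(list(positions = c(1L, 2L), fraction = fraction))
  if (fraction < 1)
    sp <- c(sp, list(list(positions = integer(), fraction = 1 - fraction)))
  tracer_spec("XYL_ext", 5L, sp, purity)
}

# MID of a substrate EMU (subset of tracer carbons): mixture over species of
# the Poisson-binomial of per-position label probabilities.
tracer_emu_mid <- function(tracer, positions) {
  out <- numeric(length(positions) + 1L)
  for (sp in tracer$species) {
    q <- ifelse(positions %in% sp$positions, tracer$purity, 0)
    mid <- 1
    for (p in q) mid <- .conv(mid, c(1 - p, p))
    out <- out + sp$fraction * mid
  }
  out
}

# full positional isotopomer distribution of the tracer over 2^n patterns
# (bit i of the 0-based state index = label at carbon i+1)
tracer_isotopomer_dist <- function(tracer) {
  n <- tracer$n_carbons
  dist <- numeric(2^n)
  for (sp in tracer$species) {
    q <- ifelse(seq_len(n) %in% sp$positions, tracer$purity, 0)
    d <- 1
    for (p in q) d <- c(d * (1 - p), d * p)  # little-endian bit order
    dist <- dist + sp$fraction * d
  }
  dist
}

# exact linear convolution
.conv <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (k in seq_along(a))
    out[k:(k + length(b) - 1L)] <- out[k:(k + length(b) - 1L)] + a[k] * b
  out
}
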