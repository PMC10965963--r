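# Accessors for the packaged EDEMP + xylose-isomerase core model fixtures.

.pkg_file <- function(...) {
  p <- system.file("extdata", ..., package = "edempflux")
  if (!nzchar(p)) stop(sprintf("packaged file not found: %s", file.path(...)))
  p
}

#' Packaged EDEMP + isomerase core network
#'
#' The atom-mapped core model of xylose assimilation in engineered
#' *P. putida*: XylA/XylB isomerase route into the non-oxidative PPP, the
#' EDEMP cycle (Pgi, Zwf/Pgl, Gnd, Edd/Eda, gluconeogenic Fba/Fbp/TpiA),
#' lumped lower glycolysis, anaplerosis, TCA cycle with glyoxylate shunt,
#' and a lumped biomass drain.
#' @return An `amn` network.
#' @export
edemp_network <- function() parse_network(.pkg_file("edemp_core.net"))

#' Packaged reference flux distribution (synthetic reconstruction)
#'
#' A steady-state-exact flux distribution for growth on xylose, normalized
#' to uptake = 100% with an absolute uptake rate of 1.45 mmol gCDW^-1 h^-1.
#' Reconstructed from the published aggregate flux statements (89% of uptake
#' through Pgi; over half of the 6PG node through the ED pathway; over a
#' third recycled through Gnd); not measured data.
#' @return A `flux_distribution`.
#' @export
edemp_fluxes <- function() load_flux_table(.pkg_file("edemp_fluxes_synthetic.tsv"))

#' Packaged measurement specification
#'
#' GC-MS TBDMS amino-acid fragments (mapped to their precursor metabolites)
#' plus intact IC-MS sugar-phosphate MIDs.
#' @return A `measurement_spec`.
#' @export
edemp_fragments <- function() read_measurement_spec(.pkg_file("edemp_fragments.json"))

#' Packaged fragment elemental formulas
#' @return Data frame with columns `fragment_id`, `C`, `H`, `N`, `O`, `Si`,
#'   `S`, `backbone_carbons`.
#' @export
edemp_fragment_formulas <- function() {
  utils::read.csv(.pkg_file("fragment_formulas.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Small toy networks used for oracle validation
#'
#' `toy_chain_network()`: linear 2-step chain A -> B -> C with identity maps.
#' `toy_condensation_network()`: two 2-carbon inputs condensing to a
#' 4-carbon product.  `mini_ppp_network()`: X5P/R5P/S7P/E4P/F6P/G3P toy with
#' the transketolase/transaldolase carbon-unit transfers.
#' @return An `amn` network.
#' @export
toy_chain_network <- function() parse_network(c(
  "@substrate A_ext", "@uptake upt", "@unbalanced A_ext",
  "upt: A_ext (ab) -> A (ab)",
  "r1: A (ab) -> B (ab)",
  "r2: B (ab) -> C (ab)",
  "out: C ->"))

#' @rdname toy_chain_network
#' @export
toy_condensation_network <- function() parse_network(c(
  "@substrate A_ext", "@uptake upt", "@unbalanced A_ext",
  "upt: A_ext (ab) -> A (ab)",
  "sp1: A (ab) -> B (ab)",
  "sp2: A (ab) -> C (ba)",
  "cond: B (ab) + C (cd) -> D (abcd)",
  "out: D ->"))

#' @rdname toy_chain_network
#' @export
mini_ppp_network <- function() parse_network(c(
  "@substrate X_ext", "@uptake upt", "@unbalanced X_ext",
  "upt: X_ext (abcde) -> X5P (abcde)",
  "rpe: X5P (abcde) <-> Ru5P (abcde)",
  "rpi: Ru5P (abcde) <-> R5P (abcde)",
  "tkt1: X5P (abcde) + R5P (fghij) <-> S7P (abfghij) + G3P (cde)",
  "tkt2: X5P (abcde) + E4P (fghi) <-> F6P (abfghi) + G3P (cde)",
  "tal: S7P (abcdefg) + G3P (hij) <-> F6P (abchij) + E4P (defg)",
  "r5p_out: R5P ->",
  "f6p_out: F6P ->",
  "g3p_out: G3P ->"))
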