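# ---------------------------------------------------------------------------
# End-to-end workflows: the 13C-MFA fit pipeline and the genome-scale
# comparison, driven by a YAML/JSON config or an equivalent R list.
# Every output bundle embeds the config hash, the seeds used and the
# package version.
# ---------------------------------------------------------------------------

.read_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L && file.exists(cfg)) {
    cfg <- if (grepl("\\.json$", cfg)) jsonlite::fromJSON(cfg, simplifyVector = TRUE)
           else yaml::read_yaml(cfg)
  }
  if (!is.list(cfg)) stop("config must be a list or a YAML/JSON file path")
  cfg
}

.require_file <- function(path, what) {
  if (is.null(path)) stop(sprintf("config lacks a path for %s", what))
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  path
}

.provenance <- function(cfg, seeds) {
  list(package = "edempflux",
       version = as.character(utils::packageVersion("edempflux")),
       config_hash = .djb2(jsonlite::toJSON(cfg, auto_unbox = TRUE)),
       seeds = seeds,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# small dependency-free string hash for provenance stamping
.djb2 <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(paste(s, collapse = ""))) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the 13C-MFA pipeline
#'
#' Stages: load network + measured MIDs, correct them for natural abundance
#' and unlabelled inoculum biomass, fit the flux distribution, profile
#' confidence intervals for requested reactions, and write a flux TSV plus a
#' JSON report (with seeds and package version) to the output directory.
#'
#' Config keys: `network` (path; default packaged EDEMP model), `mids`
#' (path, MID CSV; raw observed or already-corrected), `corrected`
#' (logical; skip correction), `formulas` (path, fragment formula CSV),
#' `fragments` (path, measurement spec JSON/YAML), `tracer`
#' (`list(positions=, fraction=, purity=)`), `uptake`, `growth`,
#' `unlabeled_biomass_fraction`, `fixed` (named list), `exch_rxns`,
#' `n_starts`, `seed`, `ci_reactions`, `outdir`.
#'
#' @param cfg Config list or YAML/JSON path.
#' @return List with the `flux_fit`, the goodness-of-fit verdict, CIs and
#'   output paths.
#' @export
run_mfa_pipeline <- function(cfg) {
  cfg <- .read_config(cfg)
  outdir <- cfg$outdir %||% stop("config needs 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- "load"
  res <- tryCatch({
    net <- if (is.null(cfg$network)) edemp_network()
           else parse_network(.require_file(cfg$network, "network"))
    spec <- if (is.null(cfg$fragments)) edemp_fragments()
            else read_measurement_spec(.require_file(cfg$fragments, "measurement spec"))
    ds <- read_mid_csv(.require_file(cfg$mids, "MID CSV"))
    tracer <- if (is.null(cfg$tracer)) tracer_xylose_12()
              else tracer_spec(net$substrate_id,
                               net$mets[net$substrate_id, "n_carbons"],
                               list(list(positions = cfg$tracer$positions,
                                         fraction = cfg$tracer$fraction %||% 1)),
                               purity = cfg$tracer$purity %||% 0.99)

    stage <- "correct"
    if (!isTRUE(cfg$corrected)) {
      formulas <- if (is.null(cfg$formulas)) edemp_fragment_formulas()
                  else utils::read.csv(.require_file(cfg$formulas, "formula table"),
                                       comment.char = "#", stringsAsFactors = FALSE)
      ccfg <- correction_config(
        unlabeled_biomass_fraction = cfg$unlabeled_biomass_fraction %||% 0)
      ds <- correct_mid_dataset(ds, formulas, spec, ccfg)
    }

    stage <- "fit"
    seed <- cfg$seed %||% 1
    fit <- fit_fluxes(net, ds, tracer, spec,
                      measured_rates = list(uptake = cfg$uptake %||% 1.45,
                                            growth = cfg$growth),
                      n_starts = cfg$n_starts %||% 50, seed = seed,
                      fixed = unlist(cfg$fixed) %||% c(pyc = 0),
                      exch_rxns = cfg$exch_rxns %||% c("pgi", "tkt1", "tkt2", "tal"))
    gof <- goodness_of_fit(fit)

    stage <- "confidence intervals"
    cis <- lapply(cfg$ci_reactions %||% character(), function(r)
      confidence_interval_continuation(fit, r))
    names(cis) <- cfg$ci_reactions

    stage <- "write"
    flux_path <- file.path(outdir, "fluxes.tsv")
    write_flux_table(fit$flux, flux_path)
    report <- list(
      provenance = .provenance(cfg, seeds = seed),
      ssr = fit$ssr, dof = fit$dof, goodness_of_fit = gof,
      best_start = fit$best_start, n_starts = fit$n_starts,
      free_fluxes = as.list(setNames(fit$par[seq_len(fit$basis$n_free)],
                                     fit$basis$free)),
      confidence_intervals = lapply(cis, function(ci)
        ci[c("estimate", "lb", "ub", "open_lb", "open_ub")]))
    report_path <- file.path(outdir, "mfa_report.json")
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), report_path)
    list(fit = fit, gof = gof, cis = cis,
         flux_path = flux_path, report_path = report_path)
  }, error = function(e)
    stop(sprintf("MFA pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))
  res
}

#' Run the genome-scale comparison workflow
#'
#' Stages: load BIGG model, apply the xylose surgery, fix the uptake,
#' derive MFA bounds from a core flux table, solve the uptake-only and
#' MFA-bounded models, and write the comparison report (TSV + JSON).
#'
#' Config keys: `model` (BIGG JSON path), `fluxes` (core flux TSV; default
#' the packaged distribution), `mapping` (core-to-GEM TSV; default
#' packaged), `uptake` (default 1.45), `uptake_exchange`
#' (default `EX_xyl__D_e`), `surgery` (logical, default TRUE), `tie_break`,
#' `outdir`.
#'
#' @param cfg Config list or YAML/JSON path.
#' @return List with the `gem_comparison` and output paths.
#' @export
run_gem_comparison <- function(cfg) {
  cfg <- .read_config(cfg)
  outdir <- cfg$outdir %||% stop("config needs 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  res <- tryCatch({
    model <- load_bigg_json(.require_file(cfg$model, "BIGG model"))
    stage <- "surgery"
    if (!isFALSE(cfg$surgery)) model <- apply_xylose_surgery(model)
    model <- fix_uptake(model, cfg$uptake_exchange %||% "EX_xyl__D_e",
                        cfg$uptake %||% 1.45)
    stage <- "bounds"
    flux <- if (is.null(cfg$fluxes)) edemp_fluxes()
            else load_flux_table(.require_file(cfg$fluxes, "core flux table"))
    mapping <- if (is.null(cfg$mapping)) edemp_gem_mapping()
               else utils::read.delim(.require_file(cfg$mapping, "mapping table"),
                                      comment.char = "#", stringsAsFactors = FALSE)
    spec <- mfa_bounds_spec(flux, mapping, uptake_rate_abs = cfg$uptake %||% 1.45)
    stage <- "solve"
    cmp <- compare_models(model, spec,
                          tie_break = cfg$tie_break %||% "parsimonious")
    if (!identical(cmp$status_fba, "optimal") || !identical(cmp$status_mfa, "optimal"))
      stop(sprintf("FBA infeasible (uptake-only: %s, MFA-bounded: %s)",
                   cmp$status_fba, cmp$status_mfa))
    stage <- "write"
    tsv_path <- file.path(outdir, "gem_comparison.tsv")
    utils::write.table(cmp$summary, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report <- list(provenance = .provenance(cfg, seeds = integer()),
                   summary = cmp$summary)
    json_path <- file.path(outdir, "gem_comparison.json")
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), json_path)
    list(comparison = cmp, tsv_path = tsv_path, report_path = json_path)
  }, error = function(e)
    stop(sprintf("GEM comparison failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
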