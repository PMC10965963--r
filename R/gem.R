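# ---------------------------------------------------------------------------
# Genome-scale flux balance analysis.
#
# Loads BIGG-schema JSON models, applies the xylose-assimilation surgery
# (heterologous isomerase route added, periplasmic glucose dehydrogenase
# removed), constrains central-carbon reactions with MFA-derived bounds
# (mean +/- 1.96 SE, grouped reactions as one summed constraint), maximizes
# biomass and accounts for NADPH/NADH production and net CO2 release.
# ---------------------------------------------------------------------------

#' Load a BIGG-schema JSON model
#'
#' @param text JSON content or a file path.
#' @return A `gem_model`: list with `mets` (data frame), `rxns` (named list
#'   with `lb`, `ub`, `objective`, `metabolites`), `groups` (summed-flux
#'   constraints, initially empty) and `id`.
#' @export
load_bigg_json <- function(text) {
  obj <- jsonlite::fromJSON(.as_lines(text) |> paste(collapse = "\n"),
                            simplifyVector = FALSE)
  if (is.null(obj$metabolites) || is.null(obj$reactions))
    stop("not a BIGG JSON model: missing 'metabolites' or 'reactions'")
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id,
               name = if (is.null(m$name)) NA_character_ else m$name,
               compartment = if (is.null(m$compartment)) NA_character_ else m$compartment,
               formula = if (is.null(m$formula) || is.na(m$formula)) NA_character_ else m$formula,
               charge = if (is.null(m$charge)) NA_real_ else as.numeric(m$charge),
               stringsAsFactors = FALSE)))
  rownames(mets) <- mets$id
  rxns <- list()
  for (r in obj$reactions) {
    coefs <- unlist(r$metabolites)
    if (length(bad <- setdiff(names(coefs), mets$id)))
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   r$id, paste(bad, collapse = ", ")))
    lb <- as.numeric(r$lower_bound); ub <- as.numeric(r$upper_bound)
    if (lb > ub) stop(sprintf("reaction '%s': lb > ub", r$id))
    rxns[[r$id]] <- list(id = r$id,
                         name = if (is.null(r$name)) NA_character_ else r$name,
                         lb = lb, ub = ub,
                         objective = if (is.null(r$objective_coefficient)) 0
                                     else as.numeric(r$objective_coefficient),
                         metabolites = coefs)
  }
  if (!any(vapply(rxns, `[[`, numeric(1), "objective") != 0))
    warning("model has no objective reaction")
  structure(list(id = if (is.null(obj$id)) "model" else obj$id,
                 mets = mets, rxns = rxns, groups = list()),
            class = "gem_model")
}

#' Serialize a `gem_model` back to BIGG JSON
#' @param model A `gem_model`.
#' @param path Optional output path; otherwise the JSON string is returned.
#' @export
write_bigg_json <- function(model, path = NULL) {
  obj <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$mets)), function(i) {
      m <- model$mets[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = m$formula, charge = m$charge)
    }),
    reactions = unname(lapply(model$rxns, function(r)
      list(id = r$id, name = r$name, metabolites = as.list(r$metabolites),
           lower_bound = r$lb, upper_bound = r$ub,
           objective_coefficient = r$objective))),
    genes = list())
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                          pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.gem_model <- function(x, ...) {
  cat(sprintf("GEM '%s': %d metabolites, %d reactions, %d grouped constraints\n",
              x$id, nrow(x$mets), length(x$rxns), length(x$groups)))
  invisible(x)
}

#' Stoichiometric matrix of a GEM in triplet form
#' @param model A `gem_model`.
#' @export
gem_stoich <- function(model) {
  i <- integer(); j <- integer(); x <- numeric()
  midx <- setNames(seq_len(nrow(model$mets)), model$mets$id)
  for (k in seq_along(model$rxns)) {
    co <- model$rxns[[k]]$metabolites
    i <- c(i, midx[names(co)]); j <- c(j, rep(k, length(co))); x <- c(x, unname(co))
  }
  list(i = unname(i), j = j, x = x,
       nrow = nrow(model$mets), ncol = length(model$rxns))
}

.parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  out <- numeric()
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- gsub("[^0-9]", "", t)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) + if (nzchar(n)) as.numeric(n) else 1
  }
  out
}

# elemental balance of one reaction; NULL when any formula is missing
.reaction_element_balance <- function(model, rid) {
  co <- model$rxns[[rid]]$metabolites
  tot <- numeric()
  for (m in names(co)) {
    f <- .parse_formula(model$mets[m, "formula"])
    if (is.null(f)) return(NULL)
    for (el in names(f)) tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0) + co[[m]] * f[[el]]
  }
  tot
}

.add_met <- function(model, id, name, compartment, formula = NA_character_) {
  if (id %in% model$mets$id) stop(sprintf("metabolite '%s' already in model", id))
  model$mets <- rbind(model$mets,
                      data.frame(id = id, name = name, compartment = compartment,
                                 formula = formula, charge = NA_real_,
                                 stringsAsFactors = FALSE))
  rownames(model$mets) <- model$mets$id
  model
}

.add_rxn <- function(model, id, mets, lb, ub, name = id, objective = 0) {
  if (id %in% names(model$rxns)) stop(sprintf("reaction '%s' already in model", id))
  if (length(bad <- setdiff(names(mets), model$mets$id)))
    stop(sprintf("reaction '%s' needs missing metabolite(s): %s",
                 id, paste(bad, collapse = ", ")))
  model$rxns[[id]] <- list(id = id, name = name, lb = lb, ub = ub,
                           objective = objective, metabolites = mets)
  model
}

#' Engineer a GEM for growth on xylose
#'
#' Adds extracellular/periplasmic/cytosolic D-xylose and cytosolic
#' D-xylulose, the transport steps (`XYLtex`, proton-symport `XYLt2pp`),
#' xylose isomerase (`XYLI1`), xylulokinase (`XYLK`) and the xylose exchange
#' reaction, and deletes the periplasmic glucose dehydrogenase `GCD` (so
#' glucose cannot be oxidized to gluconate).  Added reactions are checked
#' for elemental balance where formulas are available.
#'
#' @param model A `gem_model` containing `xu5p__D_c`, `atp_c`, `adp_c`,
#'   `h_c` and `h_p`.
#' @param gcd_id Id of the glucose dehydrogenase reaction to remove.
#' @return The modified copy of `model`.
#' @export
apply_xylose_surgery <- function(model, gcd_id = "GCD") {
  need <- c("xu5p__D_c", "atp_c", "adp_c", "h_c", "h_p")
  if (length(miss <- setdiff(need, model$mets$id)))
    stop(sprintf("model lacks cofactor species needed for the xylose route: %s",
                 paste(miss, collapse = ", ")))
  if (any(c("xyl__D_c", "xylu__D_c") %in% model$mets$id))
    stop("xylose species already present: surgery already applied?")
  model <- .add_met(model, "xyl__D_e", "D-xylose", "e", "C5H10O5")
  model <- .add_met(model, "xyl__D_p", "D-xylose", "p", "C5H10O5")
  model <- .add_met(model, "xyl__D_c", "D-xylose", "c", "C5H10O5")
  model <- .add_met(model, "xylu__D_c", "D-xylulose", "c", "C5H10O5")
  model <- .add_rxn(model, "EX_xyl__D_e", c(xyl__D_e = -1), lb = 0, ub = 1000,
                    name = "D-xylose exchange")
  model <- .add_rxn(model, "XYLtex", c(xyl__D_e = -1, xyl__D_p = 1),
                    lb = -1000, ub = 1000, name = "xylose transport (outer membrane)")
  model <- .add_rxn(model, "XYLt2pp", c(xyl__D_p = -1, h_p = -1, xyl__D_c = 1, h_c = 1),
                    lb = 0, ub = 1000, name = "xylose proton symport")
  model <- .add_rxn(model, "XYLI1", c(xyl__D_c = -1, xylu__D_c = 1),
                    lb = -1000, ub = 1000, name = "xylose isomerase")
  model <- .add_rxn(model, "XYLK", c(xylu__D_c = -1, atp_c = -1,
                                     xu5p__D_c = 1, adp_c = 1, h_c = 1),
                    lb = 0, ub = 1000, name = "xylulokinase")
  for (rid in c("XYLtex", "XYLt2pp", "XYLI1", "XYLK")) {
    bal <- .reaction_element_balance(model, rid)
    if (!is.null(bal) && any(abs(bal[c("C", "O", "P")] %vnz% 0) > 1e-9))
      stop(sprintf("added reaction '%s' is elementally unbalanced", rid))
  }
  if (gcd_id %in% names(model$rxns)) {
    model$rxns[[gcd_id]] <- NULL
  } else {
    warning(sprintf("glucose dehydrogenase '%s' not found; nothing deleted", gcd_id))
  }
  model
}

# safe vector lookup: NA -> default
`%vnz%` <- function(x, default) { x[is.na(x)] <- default; x }

#' Fix a substrate uptake rate
#'
#' Exchange-reaction convention: uptake is a negative exchange flux, so the
#' bound pair becomes `[-rate, -rate]`.
#' @param model A `gem_model`.
#' @param exchange_id Exchange reaction id.
#' @param rate Uptake in mmol gCDW^-1 h^-1 (positive).
#' @export
fix_uptake <- function(model, exchange_id, rate) {
  if (!exchange_id %in% names(model$rxns))
    stop(sprintf("exchange '%s' not in model", exchange_id))
  model$rxns[[exchange_id]]$lb <- -rate
  model$rxns[[exchange_id]]$ub <- -rate
  model
}

#' Build MFA-derived bounds for a GEM
#'
#' Converts a fitted core flux distribution to absolute rates
#' (`net_pct / 100 * uptake_rate_abs`) and maps each core reaction onto one
#' or more GEM reactions through a mapping table.  Bounds are
#' `mean -/+ 1.96 * SE`; multi-reaction entries (`MDH;MDH2`) become a single
#' constraint on the summed flux.
#'
#' @param flux A `flux_distribution` with `sd_pct` standard errors.
#' @param mapping Data frame with columns `core_rxn`, `gem_ids`
#'   (semicolon-separated), `sign` (+1 when the GEM direction convention
#'   matches the core model, -1 otherwise).
#' @param uptake_rate_abs Absolute uptake rate; defaults to the one stored
#'   on `flux`.
#' @return A `bounds_spec` data frame with `gem_ids`, `sign`, `lb`, `ub`.
#' @export
mfa_bounds_spec <- function(flux, mapping, uptake_rate_abs = NULL) {
  if (is.null(uptake_rate_abs)) uptake_rate_abs <- attr(flux, "uptake_rate_abs")
  if (is.null(uptake_rate_abs) || is.na(uptake_rate_abs))
    stop("uptake_rate_abs unavailable")
  rows <- lapply(seq_len(nrow(mapping)), function(k) {
    core <- mapping$core_rxn[[k]]
    if (!core %in% flux$reaction) return(NULL)
    mean_abs <- flux[core, "net_pct"] / 100 * uptake_rate_abs * mapping$sign[[k]]
    se_abs <- flux[core, "sd_pct"] / 100 * uptake_rate_abs
    if (is.na(se_abs) || se_abs < 0) stop(sprintf("invalid SE for '%s'", core))
    data.frame(core_rxn = core, gem_ids = mapping$gem_ids[[k]],
               lb = mean_abs - 1.96 * se_abs, ub = mean_abs + 1.96 * se_abs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("bounds_spec", "data.frame"))
}

#' Apply MFA-derived bounds to a GEM
#'
#' Single-reaction entries tighten that reaction's `lb`/`ub`; grouped
#' entries add one linear constraint on the summed flux.
#' @param model A `gem_model`.
#' @param spec A `bounds_spec` from [mfa_bounds_spec()] (or a data frame
#'   with `gem_ids`, `lb`, `ub`).
#' @export
apply_mfa_bounds <- function(model, spec) {
  for (k in seq_len(nrow(spec))) {
    ids <- strsplit(spec$gem_ids[[k]], ";", fixed = TRUE)[[1]]
    if (length(miss <- setdiff(ids, names(model$rxns))))
      stop(sprintf("bounds refer to unknown GEM reaction(s): %s",
                   paste(miss, collapse = ", ")))
    lb <- spec$lb[[k]]; ub <- spec$ub[[k]]
    if (lb > ub) stop(sprintf("crossed bounds for '%s'", spec$gem_ids[[k]]))
    if (length(ids) == 1L) {
      model$rxns[[ids]]$lb <- lb
      model$rxns[[ids]]$ub <- ub
    } else {
      model$groups[[length(model$groups) + 1L]] <-
        list(ids = ids, lb = lb, ub = ub, label = spec$gem_ids[[k]])
    }
  }
  model
}

# LP ingredients shared by solve_fba / fva
.gem_lp <- function(model) {
  S <- gem_stoich(model)
  ng <- length(model$groups)
  ridx <- setNames(seq_along(model$rxns), names(model$rxns))
  gi <- integer(); gj <- integer(); gx <- numeric()
  glb <- numeric(); gub <- numeric()
  for (g in seq_len(ng)) {
    grp <- model$groups[[g]]
    gi <- c(gi, rep(S$nrow + g, length(grp$ids)))
    gj <- c(gj, unname(ridx[grp$ids]))
    gx <- c(gx, rep(1, length(grp$ids)))
    glb <- c(glb, grp$lb); gub <- c(gub, grp$ub)
  }
  list(A = list(i = c(S$i, gi), j = c(S$j, gj), x = c(S$x, gx)),
       nrow = S$nrow + ng, ncol = S$ncol,
       rowlb = c(rep(0, S$nrow), glb), rowub = c(rep(0, S$nrow), gub),
       collb = vapply(model$rxns, `[[`, numeric(1), "lb"),
       colub = vapply(model$rxns, `[[`, numeric(1), "ub"),
       obj = vapply(model$rxns, `[[`, numeric(1), "objective"))
}

#' Flux balance analysis
#'
#' Maximizes the model objective (biomass formation).  With the
#' `"parsimonious"` tie-break a second LP minimizes the total absolute flux
#' at the fixed optimal objective, selecting a reproducible representative
#' among alternate optima.
#'
#' @param model A `gem_model`.
#' @param tie_break `"parsimonious"` (default) or `"none"`.
#' @return An `fba_solution`: `objective`, `fluxes` (named), `status`,
#'   `tie_break`.
#' @export
solve_fba <- function(model, tie_break = c("parsimonious", "none")) {
  tie_break <- match.arg(tie_break)
  lp <- .gem_lp(model)
  if (!any(lp$obj != 0)) stop("model objective is empty")
  res <- solve_lp_batch(lp$A, lp$nrow, lp$ncol, lp$rowlb, lp$rowub,
                        lp$collb, lp$colub,
                        list(list(name = "fba", obj = lp$obj, sense = "max")))[[1]]
  if (!identical(res$status, "optimal"))
    return(structure(list(objective = NA_real_, fluxes = NULL,
                          status = res$status, tie_break = tie_break),
                     class = "fba_solution"))
  opt <- res$objective
  v <- unlist(res$x)
  if (tie_break == "parsimonious") {
    # split variables: v = p - n, minimize sum(p + n) at fixed objective
    n <- lp$ncol
    A2 <- list(i = c(lp$A$i, lp$A$i, rep(lp$nrow + 1L, sum(lp$obj != 0) * 2L)),
               j = c(lp$A$j, lp$A$j + n,
                     which(lp$obj != 0), which(lp$obj != 0) + n),
               x = c(lp$A$x, -lp$A$x, lp$obj[lp$obj != 0], -lp$obj[lp$obj != 0]))
    res2 <- solve_lp_batch(A2, lp$nrow + 1L, 2L * n,
                           rowlb = c(lp$rowlb, opt), rowub = c(lp$rowub, opt),
                           collb = c(pmax(lp$collb, 0), pmax(-lp$colub, 0)),
                           colub = c(pmax(lp$colub, 0), pmax(-lp$collb, 0)),
                           list(list(name = "pfba", obj = rep(1, 2L * n),
                                     sense = "min")))[[1]]
    if (identical(res2$status, "optimal")) {
      x2 <- unlist(res2$x)
      v <- x2[seq_len(n)] - x2[n + seq_len(n)]
    }
  }
  names(v) <- names(model$rxns)
  structure(list(objective = opt, fluxes = v, status = "optimal",
                 tie_break = tie_break), class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("FBA solution: status %s, objective %.6g (%s tie-break)\n",
              x$status, x$objective, x$tie_break))
  invisible(x)
}

#' Flux variability analysis
#'
#' Min/max flux of each requested reaction with the objective fixed at a
#' fraction of its optimum.
#' @param model A `gem_model`.
#' @param rxns Reaction ids (default: all).
#' @param obj_frac Fraction of the optimal objective to enforce.
#' @return Data frame `reaction`, `min`, `max`.
#' @export
fva <- function(model, rxns = names(model$rxns), obj_frac = 1) {
  lp <- .gem_lp(model)
  base <- solve_lp_batch(lp$A, lp$nrow, lp$ncol, lp$rowlb, lp$rowub,
                         lp$collb, lp$colub,
                         list(list(name = "fba", obj = lp$obj, sense = "max")))[[1]]
  if (!identical(base$status, "optimal")) stop("FVA: base model not optimal")
  opt <- base$objective
  A2 <- list(i = c(lp$A$i, which(lp$obj != 0) * 0 + lp$nrow + 1L),
             j = c(lp$A$j, which(lp$obj != 0)),
             x = c(lp$A$x, lp$obj[lp$obj != 0]))
  ridx <- match(rxns, names(model$rxns))
  tasks <- list()
  for (k in seq_along(ridx)) {
    obj <- numeric(lp$ncol); obj[ridx[[k]]] <- 1
    tasks[[2 * k - 1]] <- list(name = paste0(rxns[[k]], ":min"), obj = obj, sense = "min")
    tasks[[2 * k]] <- list(name = paste0(rxns[[k]], ":max"), obj = obj, sense = "max")
  }
  res <- solve_lp_batch(A2, lp$nrow + 1L, lp$ncol,
                        rowlb = c(lp$rowlb, obj_frac * opt),
                        rowub = c(lp$rowub, Inf),
                        lp$collb, lp$colub, tasks)
  getv <- function(nm) {
    r <- res[[which(vapply(res, `[[`, character(1), "name") == nm)]]
    if (identical(r$status, "optimal")) r$objective else NA_real_
  }
  data.frame(reaction = rxns,
             min = vapply(rxns, function(r) getv(paste0(r, ":min")), numeric(1)),
             max = vapply(rxns, function(r) getv(paste0(r, ":max")), numeric(1)),
             row.names = NULL)
}

#' Cofactor and CO2 accounting of an FBA solution
#'
#' `nadph_sum` / `nadh_sum`: summed production rate of the cofactor over all
#' reactions that produce it at the solved flux (consumption excluded —
#' "oxidoreductase reactions that generate the reducing equivalent").
#' `co2_net`: net CO2 production summed over compartments, internal
#' reactions only (equals the net export rate at steady state).
#'
#' @param model A `gem_model`.
#' @param sol An optimal `fba_solution`.
#' @param nadph,nadh,co2 Regular expressions matching the species ids.
#' @return List `nadph_sum`, `nadh_sum`, `co2_net` (mmol gCDW^-1 h^-1).
#' @export
cofactor_summary <- function(model, sol,
                             nadph = "^nadph_c$", nadh = "^nadh_c$",
                             co2 = "^co2_[a-z]$") {
  if (!identical(sol$status, "optimal")) stop("solution not optimal")
  ids <- model$mets$id
  pick <- function(rx) grep(rx, ids, value = TRUE)
  sp_nadph <- pick(nadph); sp_nadh <- pick(nadh); sp_co2 <- pick(co2)
  if (!length(sp_nadph) || !length(sp_nadh) || !length(sp_co2))
    stop(sprintf("cofactor species unresolvable; candidates: %s",
                 paste(grep("nad|co2", ids, value = TRUE), collapse = ", ")))
  prod_sum <- function(species) {
    tot <- 0
    for (r in model$rxns) {
      co <- r$metabolites[names(r$metabolites) %in% species]
      if (!length(co)) next
      rate <- sum(co) * sol$fluxes[[r$id]]
      if (rate > 0) tot <- tot + rate
    }
    tot
  }
  net_sum <- function(species) {
    tot <- 0
    for (r in model$rxns) {
      if (length(r$metabolites) == 1L) next   # exchange/boundary reaction
      co <- r$metabolites[names(r$metabolites) %in% species]
      if (!length(co)) next
      tot <- tot + sum(co) * sol$fluxes[[r$id]]
    }
    tot
  }
  list(nadph_sum = prod_sum(sp_nadph), nadh_sum = prod_sum(sp_nadh),
       co2_net = net_sum(sp_co2))
}

#' Compare an MFA-constrained model with an uptake-only model
#'
#' Solves the model as given (uptake-only "FBA model") and after applying
#' MFA-derived bounds ("MFA model"), both with the parsimonious tie-break,
#' and reports growth rates, cofactor production sums, net CO2 rates, their
#' MFA/FBA ratios, and an FVA sensitivity range for each summed quantity's
#' contributing reactions.
#'
#' @param model A surgered `gem_model` with the uptake already fixed.
#' @param spec A `bounds_spec` of MFA-derived bounds.
#' @param tie_break Passed to [solve_fba()].
#' @param fva_report Also compute, for each model, the FVA range of every
#'   reaction touching the NADPH/NADH/CO2 species — the sensitivity of the
#'   summed quantities to alternate optima.
#' @param ... Passed to [cofactor_summary()] (species patterns).
#' @return A `gem_comparison` list.
#' @export
compare_models <- function(model, spec, tie_break = "parsimonious",
                           fva_report = FALSE, ...) {
  model_mfa <- apply_mfa_bounds(model, spec)
  sol_fba <- solve_fba(model, tie_break)
  sol_mfa <- solve_fba(model_mfa, tie_break)
  out <- list(status_fba = sol_fba$status, status_mfa = sol_mfa$status,
              growth_fba = sol_fba$objective, growth_mfa = sol_mfa$objective)
  if (identical(sol_fba$status, "optimal") && identical(sol_mfa$status, "optimal")) {
    cs_fba <- cofactor_summary(model, sol_fba, ...)
    cs_mfa <- cofactor_summary(model_mfa, sol_mfa, ...)
    out$summary <- data.frame(
      quantity = c("growth", "nadph_sum", "nadh_sum", "co2_net"),
      fba = c(sol_fba$objective, cs_fba$nadph_sum, cs_fba$nadh_sum, cs_fba$co2_net),
      mfa = c(sol_mfa$objective, cs_mfa$nadph_sum, cs_mfa$nadh_sum, cs_mfa$co2_net))
    out$summary$ratio_mfa_fba <- out$summary$mfa / out$summary$fba
    out$sol_fba <- sol_fba; out$sol_mfa <- sol_mfa
    if (fva_report) {
      species <- grep("^nad(p)?h_c$|^co2_[a-z]$", model$mets$id, value = TRUE)
      touch <- names(Filter(function(r) any(names(r$metabolites) %in% species),
                            model$rxns))
      out$fva_fba <- fva(model, touch)
      out$fva_mfa <- fva(model_mfa, touch)
    }
  }
  structure(out, class = "gem_comparison")
}

#' @export
print.gem_comparison <- function(x, ...) {
  cat("GEM comparison (MFA-bounded vs uptake-only):\n")
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  else cat(sprintf("  statuses: FBA %s, MFA %s\n", x$status_fba, x$status_mfa))
  invisible(x)
}

#' Packaged core-to-GEM reaction mapping
#'
#' The implementer's reconstruction of how the core-model reactions map to
#' iJN1463 reaction ids (the published comparison defines the exact set in
#' its supplementary data, which is not machine-readable here).  `sign` is
#' -1 where the GEM direction convention opposes the core model's.
#' @return Data frame `core_rxn`, `gem_ids`, `sign`.
#' @export
edemp_gem_mapping <- function() {
  utils::read.delim(.pkg_file("mfa_gem_map.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Reproduce the published genome-scale comparison (model supplied by user)
#'
#' Runs the full protocol against a user-downloaded iJN1463 BIGG JSON file:
#' xylose surgery, GCD deletion, uptake fixed at 1.45 mmol gCDW^-1 h^-1,
#' MFA bounds from the packaged core flux distribution, parsimonious FBA of
#' both models and the cofactor/CO2 comparison.
#'
#' @param path Path to `iJN1463.json` (BIGG download; not shipped).
#' @param flux Core flux distribution (default: the packaged fixture).
#' @param uptake Absolute xylose uptake rate.
#' @return A `gem_comparison`.
#' @export
reproduce_ijn1463_comparison <- function(path, flux = edemp_fluxes(),
                                         uptake = 1.45) {
  model <- load_bigg_json(path)
  model <- apply_xylose_surgery(model)
  model <- fix_uptake(model, "EX_xyl__D_e", uptake)
  spec <- mfa_bounds_spec(flux, edemp_gem_mapping(), uptake_rate_abs = uptake)
  compare_models(model, spec)
}
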