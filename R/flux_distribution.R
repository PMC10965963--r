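# ---------------------------------------------------------------------------
# Flux distributions: net (and optional exchange) fluxes as molar percent of
# substrate uptake (the flux-map convention: uptake set to 100).
# Absolute rates follow as net_pct/100 * uptake_rate_abs.
# ---------------------------------------------------------------------------

#' Construct a flux distribution
#'
#' @param reaction Character vector of reaction ids.
#' @param net_pct Net fluxes as molar percent of uptake (uptake = 100).
#' @param sd_pct Standard errors on the same scale (default 0).
#' @param exch_pct Exchange fluxes of reversible reactions (default 0).
#' @param lb_pct,ub_pct Optional bounds.
#' @param uptake_id Id of the uptake reaction; must be present and is
#'   normalized to 100 (with a warning if rescaling was needed).
#' @param uptake_rate_abs Absolute uptake rate in mmol gCDW^-1 h^-1.
#' @return A `flux_distribution`: data frame with attributes `uptake_id`,
#'   `uptake_rate_abs`.
#' @export
flux_distribution <- function(reaction, net_pct, sd_pct = 0, exch_pct = 0,
                              lb_pct = NA_real_, ub_pct = NA_real_,
                              uptake_id = "upt", uptake_rate_abs = NA_real_) {
  net_pct <- rep_len(as.numeric(net_pct), length(reaction))
  if (any(sd_pct < 0, na.rm = TRUE)) stop("negative sd_pct")
  fd <- data.frame(reaction = as.character(reaction), net_pct = as.numeric(net_pct),
                   sd_pct = rep_len(as.numeric(sd_pct), length(reaction)),
                   exch_pct = rep_len(as.numeric(exch_pct), length(reaction)),
                   lb_pct = rep_len(as.numeric(lb_pct), length(reaction)),
                   ub_pct = rep_len(as.numeric(ub_pct), length(reaction)),
                   stringsAsFactors = FALSE)
  rownames(fd) <- fd$reaction
  if (!uptake_id %in% fd$reaction)
    stop(sprintf("uptake reaction '%s' absent from flux table", uptake_id))
  up <- fd[uptake_id, "net_pct"]
  if (up <= 0) stop("uptake flux must be positive")
  if (abs(up - 100) > 1e-9) {
    warning(sprintf("rescaling fluxes so uptake = 100%% (was %g)", up))
    sc <- 100 / up
    fd$net_pct <- fd$net_pct * sc
    fd$sd_pct <- fd$sd_pct * sc
    fd$exch_pct <- fd$exch_pct * sc
    fd$lb_pct <- fd$lb_pct * sc
    fd$ub_pct <- fd$ub_pct * sc
  }
  structure(fd, uptake_id = uptake_id, uptake_rate_abs = uptake_rate_abs,
            class = c("flux_distribution", "data.frame"))
}

#' Net flux vector aligned to a network
#' @param flux A `flux_distribution`.
#' @param net An `amn` network.
#' @return Named numeric vector over `reaction_ids(net)`.
#' @export
flux_vector <- function(flux, net) {
  ids <- reaction_ids(net)
  missing <- setdiff(ids, flux$reaction)
  if (length(missing))
    stop(sprintf("flux distribution lacks entries for: %s", paste(missing, collapse = ", ")))
  v <- flux$net_pct[match(ids, flux$reaction)]
  names(v) <- ids
  v
}

#' Absolute fluxes in mmol gCDW^-1 h^-1
#' @inheritParams flux_vector
#' @export
flux_abs <- function(flux, net) {
  q <- attr(flux, "uptake_rate_abs")
  if (is.na(q)) stop("uptake_rate_abs not set on this flux distribution")
  flux_vector(flux, net) * q / 100
}

#' Check a flux distribution for metabolic steady state
#'
#' Computes the node balances S v over the balanced metabolites and reports
#' the largest absolute residual.  The check passes when the residual does
#' not exceed `tol` times the uptake flux (100).
#'
#' @param net An `amn` network.
#' @param flux A `flux_distribution` covering every reaction of `net`.
#' @param tol Tolerated residual, as a fraction of uptake (default 0.02).
#' @return List with `residuals` (named by metabolite), `max_residual`,
#'   `worst_metabolite`, `tol` and logical `pass`.
#' @export
validate_steady_state <- function(net, flux, tol = 0.02) {
  S <- stoich_matrix(net)
  v <- flux_vector(flux, net)
  r <- drop(S %*% v)
  worst <- names(r)[which.max(abs(r))]
  structure(list(residuals = r, max_residual = max(abs(r)),
                 worst_metabolite = worst, tol = tol,
                 pass = max(abs(r)) <= tol * 100),
            class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat(sprintf("steady state %s: max |S v| = %.4g at %s (tol %.4g%% of uptake)\n",
              if (x$pass) "PASS" else "FAIL", x$max_residual, x$worst_metabolite,
              x$tol * 100))
  invisible(x)
}

#' Project net fluxes onto the steady-state manifold
#'
#' Returns the minimal-norm adjustment of `v` such that S v = 0 over the
#' balanced metabolites.  Used to strip rounding residue from tabulated flux
#' maps before isotopomer simulation.
#' @param net An `amn` network.
#' @param v Named net flux vector over `reaction_ids(net)`.
#' @export
balance_fluxes <- function(net, v) {
  S <- stoich_matrix(net)
  r <- drop(S %*% v)
  if (max(abs(r)) < 1e-12) return(v)
  G <- S %*% t(S)
  dv <- tryCatch(-drop(t(S) %*% solve(G, r)),
                 error = function(e) -drop(MASS::ginv(S) %*% r))
  v + dv
}

#' Load a flux table (TSV)
#'
#' Expected columns: `reaction`, `net_pct`, `sd_pct`; optional `exch_pct`,
#' `lb_pct`, `ub_pct`.  A comment header line of the form
#' `# uptake_rate_abs = 1.45` sets the absolute uptake rate.
#'
#' @param text TSV content or path.
#' @param uptake_id Id of the uptake reaction (default `"upt"`).
#' @param uptake_rate_abs Overrides the header value when not `NA`.
#' @return A `flux_distribution` normalized to uptake = 100.
#' @export
load_flux_table <- function(text, uptake_id = "upt", uptake_rate_abs = NA_real_) {
  lines <- .as_lines(text)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.na(uptake_rate_abs)) {
    m <- regmatches(hdr, regexec("uptake_rate_abs\\s*=\\s*([0-9.eE+-]+)", hdr))
    m <- Filter(length, m)
    if (length(m)) uptake_rate_abs <- as.numeric(m[[1]][[2]])
  }
  df <- utils::read.delim(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                                       collapse = "\n"),
                          sep = "\t", stringsAsFactors = FALSE)
  need <- c("reaction", "net_pct", "sd_pct")
  if (!all(need %in% names(df)))
    stop(sprintf("flux table must have columns: %s", paste(need, collapse = ", ")))
  flux_distribution(df$reaction, df$net_pct, df$sd_pct,
                    exch_pct = if ("exch_pct" %in% names(df)) df$exch_pct else 0,
                    lb_pct = if ("lb_pct" %in% names(df)) df$lb_pct else NA_real_,
                    ub_pct = if ("ub_pct" %in% names(df)) df$ub_pct else NA_real_,
                    uptake_id = uptake_id, uptake_rate_abs = uptake_rate_abs)
}

#' Write a flux table (TSV)
#' @param flux A `flux_distribution`.
#' @param path Output path; when `NULL` the TSV is returned as a string.
#' @export
write_flux_table <- function(flux, path = NULL) {
  q <- attr(flux, "uptake_rate_abs")
  hdr <- if (!is.na(q)) sprintf("# uptake_rate_abs = %.6g", q) else NULL
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(as.data.frame(flux), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  txt <- paste(c(hdr, out), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
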