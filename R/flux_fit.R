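# ---------------------------------------------------------------------------
# Flux estimation from corrected MIDs.
#
# The steady-state constraint S v = 0 (plus measured-rate and user-fixed
# fluxes) defines an affine flux space; a well-conditioned set of "free"
# network fluxes is chosen as coordinates by pivoted QR on the null-space
# basis.  Exchange fluxes of selected reversible reactions are fitted on the
# transformed scale xi = exch/(exch + scale) in [0, 1).  The variance-
# weighted SSR is minimized by multi-start Levenberg-Marquardt; inequality
# constraints (irreversible net fluxes >= 0) enter as one-sided penalty
# residuals, which vanish at any interior optimum and are asserted after
# convergence.
# ---------------------------------------------------------------------------

#' Free-flux parameterization of the steady-state space
#'
#' @param net An `amn` network.
#' @param fixed Named numeric of fluxes fixed a priori (the uptake reaction
#'   is always fixed at 100).
#' @param prefer Reaction ids to place first among the free fluxes if
#'   possible (used by the profile-likelihood code to make a target flux a
#'   coordinate).
#' @return List with the particular solution `v0`, basis `N` (columns =
#'   free directions), `free` (reaction ids whose fluxes are the
#'   coordinates) and bookkeeping.
#' @export
free_flux_basis <- function(net, fixed = numeric(), prefer = character()) {
  ids <- reaction_ids(net)
  up <- net$uptake_id
  if (!up %in% names(fixed)) fixed[up] <- 100
  bad <- setdiff(names(fixed), ids)
  if (length(bad)) stop(sprintf("fixed fluxes not in network: %s", paste(bad, collapse = ", ")))
  S <- stoich_matrix(net)
  Ifix <- diag(length(ids))[match(names(fixed), ids), , drop = FALSE]
  E <- rbind(S, Ifix)
  d <- c(rep(0, nrow(S)), unname(fixed))
  v0 <- drop(MASS::ginv(E) %*% d)   # min-norm particular solution
  if (max(abs(E %*% v0 - d)) > 1e-6)
    stop("fixed fluxes are inconsistent with steady state")
  N <- MASS::Null(t(E))
  if (is.null(dim(N)) || ncol(N) == 0)
    stop("no free fluxes: system fully determined")
  rownames(N) <- ids
  # pick coordinate reactions: preferred first, then pivoted QR for conditioning
  k <- ncol(N)
  pref_idx <- match(intersect(prefer, ids), ids)
  pref_idx <- pref_idx[apply(abs(N[pref_idx, , drop = FALSE]), 1, max) > 1e-10]
  chosen <- integer()
  for (pi in pref_idx) {
    if (length(chosen) >= k) break
    chosen <- c(chosen, pi)
  }
  qrp <- qr(t(N), LAPACK = TRUE)
  for (pi in qrp$pivot) {
    if (length(chosen) >= k) break
    if (!pi %in% chosen) chosen <- c(chosen, pi)
  }
  chosen <- chosen[seq_len(k)]
  B <- N[chosen, , drop = FALSE]
  if (abs(det(B)) < 1e-12) stop("degenerate free-flux choice; pass different 'prefer'")
  Nf <- N %*% solve(B)                 # now v = v0f + Nf %*% u with u = v[chosen]
  v0f <- v0 - Nf %*% v0[chosen]
  list(net = net, ids = ids, fixed = fixed, v0 = drop(v0f), N = Nf,
       free = ids[chosen], free_idx = chosen, n_free = k)
}

#' Map free-flux coordinates to a full net flux vector
#' @param basis From [free_flux_basis()].
#' @param u Free-flux values (one per `basis$free`).
#' @export
flux_from_free <- function(basis, u) drop(basis$v0 + basis$N %*% u)

.exch_from_xi <- function(xi, scale = 100) scale * xi / (1 - xi)
.xi_from_exch <- function(ex, scale = 100) ex / (ex + scale)

# measurement vectors aligned once for the residual function
.meas_align <- function(dataset, spec, sd_floor) {
  fids <- intersect(spec$fragment_id, unique(dataset$fragment_id))
  if (!length(fids)) stop("dataset and measurement spec share no fragments")
  lapply(fids, function(f) {
    m <- dataset[dataset$fragment_id == f, , drop = FALSE]
    m <- m[order(m$mass_shift), , drop = FALSE]
    list(fragment = f, y = m$fraction, sd = pmax(m$sd, sd_floor))
  })
}

#' Fit fluxes to a MID dataset
#'
#' Variance-weighted least squares over the free net fluxes and the
#' exchange fluxes of `exch_rxns`, multi-started from seeded random draws.
#' The measured growth rate enters by fixing the biomass-drain flux at
#' `100 * growth / uptake`; the uptake reaction is pinned at 100%.
#'
#' @param net An `amn` network.
#' @param dataset A `mid_dataset` of (corrected) measured MIDs.
#' @param tracer A `tracer_spec`.
#' @param spec The `measurement_spec`.
#' @param measured_rates List with `uptake` (mmol gCDW^-1 h^-1) and
#'   optionally `growth` (h^-1, fixes the biomass drain `biomass_rxn`).
#' @param n_starts Number of random multi-starts (default 50).
#' @param seed RNG seed; identical seed and inputs give identical results.
#' @param fixed Further fluxes to fix, e.g. `c(pyc = 0)` for the
#'   label-degenerate anaplerotic pair of the packaged network.
#' @param exch_rxns Reversible reactions whose exchange flux is fitted;
#'   all other exchange fluxes are held at zero.
#' @param biomass_rxn Id of the biomass drain (default `"bm"` when present).
#' @param sd_floor Absolute SD floor per mass fraction (default 0.003).
#' @param free Optional explicit choice of free net fluxes.
#' @param penalty_weight Weight of the irreversibility penalty residuals.
#' @param init Optional list of full parameter vectors used as additional
#'   (warm) starts before the random ones.
#' @return A `flux_fit` object: `flux` (a `flux_distribution` with
#'   linearized SEs), `ssr`, `dof`, `par`, `basis`, convergence metadata.
#' @export
fit_fluxes <- function(net, dataset, tracer, spec,
                       measured_rates = list(uptake = 1.45, growth = NULL),
                       n_starts = 50, seed = 1, fixed = numeric(),
                       exch_rxns = NULL, biomass_rxn = "bm",
                       sd_floor = 0.003, free = NULL, penalty_weight = 1e3,
                       init = NULL) {
  ids <- reaction_ids(net)
  if (!is.null(measured_rates$growth) && biomass_rxn %in% ids &&
      !biomass_rxn %in% names(fixed))
    fixed[biomass_rxn] <- 100 * measured_rates$growth / measured_rates$uptake
  basis <- free_flux_basis(net, fixed, prefer = if (is.null(free)) character() else free)
  rev <- vapply(net$rxns, `[[`, logical(1), "reversible")
  if (is.null(exch_rxns)) exch_rxns <- character()
  if (length(bad <- setdiff(exch_rxns, ids[rev])))
    stop(sprintf("exchange fit requested for non-reversible: %s", paste(bad, collapse = ", ")))
  sys <- decompose_emu(net, spec)
  meas <- .meas_align(dataset, spec, sd_floor)
  irrev_idx <- which(!rev)
  nu <- basis$n_free
  nx <- length(exch_rxns)
  exch_idx <- match(exch_rxns, ids)

  resid_fn <- function(par) {
    u <- par[seq_len(nu)]
    v <- flux_from_free(basis, u)
    ex <- numeric(length(ids))
    if (nx) ex[exch_idx] <- .exch_from_xi(par[nu + seq_len(nx)])
    pen <- penalty_weight * pmin(v[irrev_idx], 0)
    sim <- tryCatch(.emu_solve(sys, v, ex, tracer),
                    error = function(e) NULL)
    if (is.null(sim)) {
      # singular system (e.g. zero total flux through a pool): large residual
      nres <- sum(vapply(meas, function(m) length(m$y), integer(1)))
      return(c(rep(1e3, nres), pen))
    }
    r <- unlist(lapply(meas, function(m)
      (sim[[sys$frag_keys[[m$fragment]]]] - m$y) / m$sd))
    c(r, pen)
  }
  n_meas_res <- sum(vapply(meas, function(m) length(m$y), integer(1)))
  meas_ssr <- function(par) sum(resid_fn(par)[seq_len(n_meas_res)]^2)

  lower <- c(rep(-Inf, nu), rep(0, nx))
  upper <- c(rep(Inf, nu), rep(0.97, nx))
  irrev_free <- basis$free %in% ids[irrev_idx]

  # starts are rejection-sampled inside the irreversibility polytope so the
  # optimizer begins from a physically meaningful flux map
  set.seed(seed)
  draw_feasible <- function() {
    for (k in seq_len(5000)) {
      u <- ifelse(irrev_free, stats::runif(nu, 0, 150), stats::runif(nu, -100, 150))
      if (min(flux_from_free(basis, u)[irrev_idx]) > -1e-9) return(u)
    }
    ifelse(irrev_free, stats::runif(nu, 0, 150), stats::runif(nu, -100, 150))
  }
  starts <- lapply(seq_len(n_starts), function(i) {
    x0 <- if (nx) stats::runif(nx, 0, 0.3) else numeric()
    c(draw_feasible(), x0)
  })
  if (!is.null(init)) {
    starts <- c(lapply(init, function(p) {
      stopifnot(length(p) == nu + nx)
      p
    }), starts)
    n_starts <- length(starts)
  }

  best <- NULL
  diag_tab <- data.frame(start = seq_len(n_starts), ssr = NA_real_,
                         violation = NA_real_, converged = FALSE)
  for (i in seq_len(n_starts)) {
    # stage 1: net fluxes only (exchanges held at their start draw) --
    # avoids the runaway-exchange local basin; stage 2: all parameters
    p0 <- starts[[i]]
    if (nx) {
      x0 <- p0[nu + seq_len(nx)]
      sa <- tryCatch(
        minpack.lm::nls.lm(par = p0[seq_len(nu)],
                           fn = function(u) resid_fn(c(u, x0)),
                           lower = lower[seq_len(nu)], upper = upper[seq_len(nu)],
                           control = minpack.lm::nls.lm.control(
                             maxiter = 150, ftol = 1e-12, epsfcn = 1e-8)),
        error = function(e) NULL)
      if (!is.null(sa)) p0 <- c(sa$par, x0)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-15, ptol = 1e-13,
                           epsfcn = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    v <- flux_from_free(basis, fit$par[seq_len(nu)])
    viol <- max(0, -min(v[irrev_idx]))
    ssr <- sum(resid_fn(fit$par)[seq_len(n_meas_res)]^2)
    diag_tab$ssr[i] <- ssr; diag_tab$violation[i] <- viol
    diag_tab$converged[i] <- viol < 1e-6
    if (viol < 1e-6 && (is.null(best) || ssr < best$ssr))
      best <- list(par = fit$par, ssr = ssr, fit = fit, start = i)
  }
  if (is.null(best))
    stop(paste0("no multi-start converged to a feasible flux distribution\n",
                paste(utils::capture.output(print(diag_tab)), collapse = "\n")))

  u <- best$par[seq_len(nu)]
  v <- flux_from_free(basis, u)
  ex <- numeric(length(ids))
  if (nx) ex[exch_idx] <- .exch_from_xi(best$par[nu + seq_len(nx)])

  # linearized SEs: residuals are already standardized, so cov(u) = (J'J)^-1
  J <- .num_jacobian(function(p) resid_fn(p)[seq_len(n_meas_res)], best$par)
  covp <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  v_se <- rep(NA_real_, length(ids))
  if (!is.null(covp)) {
    covu <- covp[seq_len(nu), seq_len(nu), drop = FALSE]
    v_se <- sqrt(pmax(rowSums((basis$N %*% covu) * basis$N), 0))
  }

  # a measured MID that sums to 1 has one linear dependency among its
  # fractions; raw (non-renormalized) intensities count fully
  dof <- sum(vapply(meas, function(m)
    length(m$y) - (abs(sum(m$y) - 1) < 1e-9), numeric(1))) - length(best$par)
  flux <- flux_distribution(ids, v, sd_pct = v_se, exch_pct = ex,
                            uptake_id = net$uptake_id,
                            uptake_rate_abs = if (is.null(measured_rates$uptake))
                              NA_real_ else measured_rates$uptake)
  structure(list(flux = flux, ssr = best$ssr, dof = dof, par = best$par,
                 basis = basis, exch_rxns = exch_rxns, net = net, sys = sys,
                 meas = meas, n_meas_res = n_meas_res, resid_fn = resid_fn,
                 tracer = tracer, sd_floor = sd_floor,
                 n_starts = n_starts, seed = seed, best_start = best$start,
                 starts_diagnostics = diag_tab,
                 lower = lower, upper = upper),
            class = "flux_fit")
}

.num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xj <- x; xj[j] <- xj[j] + h
    J[, j] <- (f(xj) - f0) / h
  }
  J
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("13C-MFA fit: SSR %.4g on %d dof (best of %d starts, seed %d)\n",
              x$ssr, x$dof, x$n_starts, x$seed))
  cat("free fluxes:", paste(sprintf("%s=%.2f", x$basis$free,
                                    x$par[seq_len(x$basis$n_free)]), collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square goodness-of-fit verdict
#'
#' A statistically acceptable fit has its variance-weighted SSR inside the
#' central chi-square acceptance band for the model's degrees of freedom.
#'
#' @param fit A `flux_fit`.
#' @param alpha Band tail probability (default 0.05: the 2.5th-97.5th
#'   percentile band).
#' @return List: `ssr`, `dof`, `lower`, `upper`, `pass`, `flag`
#'   (`"ok"`, `"fail_low"` for suspiciously small SSR, `"fail_high"`).
#' @export
goodness_of_fit <- function(fit, alpha = 0.05) {
  if (fit$dof <= 0) stop("non-positive degrees of freedom: model overparameterized")
  lo <- stats::qchisq(alpha / 2, fit$dof)
  hi <- stats::qchisq(1 - alpha / 2, fit$dof)
  flag <- if (fit$ssr < lo) "fail_low" else if (fit$ssr > hi) "fail_high" else "ok"
  list(ssr = fit$ssr, dof = fit$dof, lower = lo, upper = hi,
       pass = flag == "ok", flag = flag)
}

#' Confidence interval by parameter continuation
#'
#' Profiles the SSR along one reaction's net flux: the flux is stepped away
#' from its optimum (re-optimizing all other parameters at each step) until
#' the SSR exceeds `SSR_opt + qchisq(1-alpha, 1)`; the crossing is then
#' refined by bisection.  Reaches of the profile beyond `range_cap` without
#' a crossing are reported as open bounds (flux not identifiable in that
#' direction).
#'
#' @param fit A `flux_fit` from [fit_fluxes()].
#' @param reaction_id Net flux to profile.
#' @param alpha 1 - confidence level (default 0.05, threshold 3.84).
#' @param step Initial step size in flux units (%% of uptake).
#' @param range_cap Abandon the search beyond this distance from the optimum.
#' @return List with `lb`, `ub`, `open_lb`, `open_ub`, `threshold`.
#' @export
confidence_interval_continuation <- function(fit, reaction_id, alpha = 0.05,
                                             step = 1, range_cap = 300) {
  ids <- fit$basis$ids
  if (!reaction_id %in% ids) stop(sprintf("unknown reaction '%s'", reaction_id))
  if (reaction_id %in% names(fit$basis$fixed))
    stop(sprintf("'%s' is fixed; no confidence interval", reaction_id))
  thresh <- fit$ssr + stats::qchisq(1 - alpha, 1)

  # rebuild the parameterization so the target flux is the first coordinate
  basis <- free_flux_basis(fit$net, fit$basis$fixed,
                           prefer = c(reaction_id, setdiff(fit$basis$free, reaction_id)))
  if (basis$free[[1L]] != reaction_id)
    stop(sprintf("flux '%s' is not a free direction; it is determined by the fixed rates",
                 reaction_id))
  net <- fit$net; sys <- fit$sys; meas <- fit$meas; tracer <- fit$tracer
  rev <- vapply(net$rxns, `[[`, logical(1), "reversible")
  irrev_idx <- which(!rev)
  nu <- basis$n_free
  nx <- length(fit$exch_rxns)
  exch_idx <- match(fit$exch_rxns, ids)
  n_meas_res <- fit$n_meas_res

  resid_at <- function(target, par_rest) {
    u <- c(target, par_rest[seq_len(nu - 1L)])
    v <- flux_from_free(basis, u)
    ex <- numeric(length(ids))
    if (nx) ex[exch_idx] <- .exch_from_xi(par_rest[nu - 1L + seq_len(nx)])
    sim <- tryCatch(.emu_solve(sys, v, ex, tracer), error = function(e) NULL)
    if (is.null(sim)) return(c(rep(1e3, n_meas_res),
                               1e3 * pmin(v[irrev_idx], 0)))
    r <- unlist(lapply(meas, function(m)
      (sim[[sys$frag_keys[[m$fragment]]]] - m$y) / m$sd))
    c(r, 1e3 * pmin(v[irrev_idx], 0))
  }

  # express the current optimum in the new coordinates
  v_opt <- flux_vector(fit$flux, net)
  u_full <- v_opt[basis$free]
  x_opt <- if (nx) .xi_from_exch(fit$flux$exch_pct[match(fit$exch_rxns, fit$flux$reaction)])
           else numeric()
  opt_target <- u_full[[1L]]
  lower <- c(rep(-Inf, nu - 1L), rep(0, nx))
  upper <- c(rep(Inf, nu - 1L), rep(0.97, nx))

  profile_ssr <- function(target, start_rest) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = start_rest, fn = function(p) resid_at(target, p),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 80, ftol = 1e-12,
                                           epsfcn = 1e-8)),
      error = function(e) NULL)
    if (is.null(f)) return(list(ssr = Inf, par = start_rest))
    r <- resid_at(target, f$par)
    viol <- max(abs(r[-seq_len(n_meas_res)]))
    ssr <- sum(r[seq_len(n_meas_res)]^2)
    if (viol > 1e-3) ssr <- Inf   # left the feasible polytope
    list(ssr = ssr, par = f$par)
  }

  trace_side <- function(dir) {
    rest <- c(u_full[-1L], x_opt)
    h <- step
    c_prev <- opt_target; s_prev <- fit$ssr
    repeat {
      c_next <- c_prev + dir * h
      if (abs(c_next - opt_target) > range_cap)
        return(list(bound = c_prev + dir * range_cap, open = TRUE))
      pr <- profile_ssr(c_next, rest)
      if (pr$ssr > thresh) {
        # bisect between c_prev (below) and c_next (above)
        lo <- c_prev; hi <- c_next
        for (k in 1:25) {
          mid <- (lo + hi) / 2
          pm <- profile_ssr(mid, rest)
          if (pm$ssr > thresh) hi <- mid else { lo <- mid; rest <- pm$par }
          if (abs(hi - lo) < 0.1) break
        }
        return(list(bound = (lo + hi) / 2, open = FALSE))
      }
      rest <- pr$par
      c_prev <- c_next; s_prev <- pr$ssr
      h <- h * 1.7
    }
  }

  lo_side <- trace_side(-1)
  hi_side <- trace_side(+1)
  list(reaction = reaction_id, estimate = opt_target,
       lb = lo_side$bound, ub = hi_side$bound,
       open_lb = lo_side$open, open_ub = hi_side$open,
       threshold = thresh, alpha = alpha)
}
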