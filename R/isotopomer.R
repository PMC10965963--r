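# ---------------------------------------------------------------------------
# Exhaustive positional-isotopomer oracle.
#
# Solves the full stationary isotopomer balance over every balanced
# metabolite (2^n states each) by damped Gauss-Seidel fixed-point iteration,
# independently of the EMU cascade.  Intended as a validation oracle for
# small networks; a state-space guard refuses anything above ~2^20 states.
# ---------------------------------------------------------------------------

#' Simulate MIDs by exhaustive isotopomer balance
#'
#' Same contract as [simulate_mids()] but solved over the complete positional
#' isotopomer space.  Exact up to the fixed-point tolerance; exponential in
#' carbon count, so only usable on desk-scale networks.
#'
#' @inheritParams simulate_mids
#' @param tol Fixed-point convergence tolerance (max absolute change).
#' @param maxit Maximum Gauss-Seidel sweeps.
#' @param max_states Guard on the total number of isotopomer states.
#' @param balance As in [simulate_mids()].
#' @return A `mid_dataset`.
#' @export
brute_force_mids <- function(net, flux, tracer, spec, input_label = list(),
                             tol = 1e-13, maxit = 50000L, max_states = 2^20,
                             balance = TRUE) {
  subsets <- .spec_subsets(net, spec)
  bal <- net$mets[net$mets$is_balanced & net$mets$n_carbons > 0, "id"]
  nc <- setNames(net$mets$n_carbons, net$mets$id)
  total_states <- sum(2^nc[bal])
  if (total_states > max_states)
    stop(sprintf("isotopomer state space too large: %d states (guard %d)",
                 total_states, max_states))

  chans <- .uni_channels(net)
  v_net <- flux_vector(flux, net)
  if (balance) v_net <- balance_fluxes(net, v_net)
  v_exch <- flux$exch_pct[match(reaction_ids(net), flux$reaction)]
  v_exch[is.na(v_exch)] <- 0
  fl <- .chan_fluxes(chans, v_net, v_exch)

  cons <- setNames(numeric(length(bal)), bal)
  for (ci in seq_along(chans)) for (e in chans[[ci]]$lhs)
    if (e$met %in% bal) cons[[e$met]] <- cons[[e$met]] + fl[[ci]] * e$coef
  if (any(cons <= 0))
    stop(sprintf("no consuming flux for metabolite(s): %s",
                 paste(bal[cons <= 0], collapse = ", ")))

  # fixed input distributions (substrate from tracer, others unlabelled by default)
  input_dist <- function(met) {
    if (identical(met, net$substrate_id)) return(tracer_isotopomer_dist(tracer))
    n <- nc[[met]]
    q <- rep_len(if (!is.null(input_label[[met]])) input_label[[met]] else 0, n)
    d <- 1
    for (p in q) d <- c(d * (1 - p), d * p)
    d
  }

  # precompile production terms: for each channel x mapped product entry,
  # the joint-state -> product-state index map over the mapped lhs entries
  prods <- list()
  for (ci in seq_along(chans)) {
    ch <- chans[[ci]]
    if (fl[[ci]] == 0) { }  # keep structure; flux checked at use
    lhs_m <- Filter(function(e) !is.na(e$letters), ch$lhs)
    if (!length(lhs_m)) next
    lhs_letters <- lapply(lhs_m, function(e) strsplit(e$letters, "")[[1]])
    lhs_sizes <- vapply(lhs_letters, length, integer(1))
    for (e in ch$rhs) {
      if (is.na(e$letters) || !(e$met %in% bal)) next
      pl <- strsplit(e$letters, "")[[1]]
      # for each product carbon: which lhs entry, which bit
      srcs <- t(vapply(pl, function(l) {
        for (k in seq_along(lhs_letters)) {
          q <- match(l, lhs_letters[[k]])
          if (!is.na(q)) return(c(k, q))
        }
        stop("unbalanced atom letter")
      }, integer(2)))
      n_joint <- prod(2^lhs_sizes)
      joint <- seq_len(n_joint) - 1L
      # decode per-entry state from the mixed-radix joint index (entry 1 fastest)
      states <- matrix(0L, n_joint, length(lhs_m))
      rem <- joint
      for (k in seq_along(lhs_m)) {
        states[, k] <- rem %% (2^lhs_sizes[[k]])
        rem <- rem %/% (2^lhs_sizes[[k]])
      }
      map <- integer(n_joint)
      for (p in seq_along(pl)) {
        bit <- (states[, srcs[p, 1L]] %/% (2^(srcs[p, 2L] - 1L))) %% 2L
        map <- map + bit * 2L^(p - 1L)
      }
      prods[[length(prods) + 1L]] <-
        list(chan = ci, met = e$met, coef = e$coef,
             lhs_mets = vapply(lhs_m, `[[`, character(1), "met"),
             map = map + 1L, nprod = 2^length(pl))
    }
  }

  dist <- setNames(lapply(bal, function(m) c(1, numeric(2^nc[[m]] - 1L))), bal)
  inputs <- new.env(parent = emptyenv())
  get_dist <- function(m) {
    if (m %in% bal) return(dist[[m]])
    if (is.null(inputs[[m]])) inputs[[m]] <- input_dist(m)
    inputs[[m]]
  }
  prods_by_met <- split(prods, vapply(prods, `[[`, character(1), "met"))

  for (it in seq_len(maxit)) {
    delta <- 0
    for (m in bal) {
      acc <- numeric(2^nc[[m]])
      for (pr in prods_by_met[[m]]) {
        f <- fl[[pr$chan]] * pr$coef
        if (f == 0) next
        jp <- 1
        for (lm in pr$lhs_mets) jp <- as.vector(outer(jp, get_dist(lm)))
        contrib <- rowsum(jp * f, group = pr$map)
        acc[as.integer(rownames(contrib))] <-
          acc[as.integer(rownames(contrib))] + contrib[, 1L]
      }
      new <- acc / cons[[m]]
      # bilinear condensation terms make the raw iteration unstable in total
      # mass; the solution is a probability distribution, so renormalize
      sm <- sum(new)
      if (sm > 0) new <- new / sm
      delta <- max(delta, max(abs(new - dist[[m]])))
      dist[[m]] <- new
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    warning(sprintf("isotopomer fixed point not converged after %d sweeps (delta %.3g)",
                    maxit, delta))

  mids <- setNames(lapply(seq_len(nrow(spec)), function(i) {
    met <- spec$metabolite[[i]]
    idx <- subsets[[i]]
    d <- get_dist(met)
    st <- seq_along(d) - 1L
    shift <- integer(length(d))
    for (p in idx) shift <- shift + (st %/% 2L^(p - 1L)) %% 2L
    as.vector(rowsum(d, group = shift))
  }), spec$fragment_id)
  mid_dataset(mids, spec, sd = 0, check = TRUE, tol = 1e-6)
}
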