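# ---------------------------------------------------------------------------
# Elementary metabolite unit (EMU) decomposition and forward simulation.
#
# The EMU framework reduces the stationary isotopomer balance to a cascade of
# linear systems, one per EMU size: the mass isotopomer distribution of every
# carbon subset that can influence a measured fragment is the unknown, and
# condensation reactions couple a size-k EMU to convolutions of smaller EMUs
# already solved.  Reversible reactions are expanded into forward/backward
# channels with fluxes vf = max(net,0) + exch, vb = max(-net,0) + exch.
# ---------------------------------------------------------------------------

.emu_key <- function(met, idx) paste0(met, "|", paste(idx, collapse = ","))

# all unidirectional channels of a network (structure only, flux-free)
.uni_channels <- function(net) {
  chans <- list()
  for (ri in seq_along(net$rxns)) {
    rx <- net$rxns[[ri]]
    for (ch in rx$channels) {
      chans[[length(chans) + 1L]] <-
        list(lhs = ch$lhs, rhs = ch$rhs, rxn = ri, dir = 1, share = ch$share)
      if (rx$reversible)
        chans[[length(chans) + 1L]] <-
          list(lhs = ch$rhs, rhs = ch$lhs, rxn = ri, dir = -1, share = ch$share)
    }
  }
  chans
}

# channel fluxes from net/exchange vectors (aligned to reaction order)
.chan_fluxes <- function(chans, v_net, v_exch) {
  vf <- pmax(v_net, 0) + v_exch
  vb <- pmax(-v_net, 0) + v_exch
  vapply(chans, function(ch) ch$share * if (ch$dir > 0) vf[[ch$rxn]] else vb[[ch$rxn]],
         numeric(1))
}

#' Decompose a network into size-layered EMU systems
#'
#' Traces every measured fragment back through the atom maps to the tracer,
#' collecting the minimal set of EMUs whose mass isotopomer distributions
#' determine the measurements, and organizes them into one linear system per
#' EMU size.
#'
#' @param net An `amn` network.
#' @param spec A `measurement_spec`; every fragment must map to a network
#'   metabolite reachable from the substrate.
#' @return An `emu_system` (opaque compiled structure) for
#'   [simulate_mids()]; its `sizes` element names the layered systems, each
#'   with the EMU keys it solves.
#' @export
decompose_emu <- function(net, spec) {
  subsets <- .spec_subsets(net, spec)
  chans <- .uni_channels(net)
  balanced <- setNames(net$mets$is_balanced, net$mets$id)

  # producer index: met -> list of (chan index, rhs entry)
  prod_idx <- list()
  for (ci in seq_along(chans)) {
    for (e in chans[[ci]]$rhs) {
      if (is.na(e$letters)) next
      prod_idx[[e$met]] <- c(prod_idx[[e$met]], list(list(chan = ci, entry = e)))
    }
  }

  emus <- list()      # key -> list(met, idx, size)
  terms <- list()     # key -> list of list(chan, coef, srcs = list(list(met, idx)))
  queue <- list()
  enqueue <- function(met, idx) {
    key <- .emu_key(met, idx)
    if (!is.null(emus[[key]])) return(key)
    emus[[key]] <<- list(met = met, idx = idx, size = length(idx))
    if (balanced[[met]]) queue[[length(queue) + 1L]] <<- key
    key
  }
  for (i in seq_len(nrow(spec))) enqueue(spec$metabolite[[i]], subsets[[i]])

  while (length(queue)) {
    key <- queue[[1L]]; queue <- queue[-1L]
    em <- emus[[key]]
    prods <- prod_idx[[em$met]]
    if (is.null(prods))
      stop(sprintf("metabolite '%s' has no producing reaction with an atom map: fragment EMUs on it are unreachable from the substrate", em$met))
    tl <- list()
    for (p in prods) {
      letters <- strsplit(p$entry$letters, "")[[1]]
      src_letters <- letters[em$idx]
      srcs <- list()
      for (le in chans[[p$chan]]$lhs) {
        if (is.na(le$letters)) next
        ls <- strsplit(le$letters, "")[[1]]
        pos <- sort(which(ls %in% src_letters))
        if (length(pos)) srcs <- c(srcs, list(list(met = le$met, idx = pos)))
      }
      got <- sum(vapply(srcs, function(s) length(s$idx), integer(1)))
      if (got != em$size)
        stop(sprintf("atom bookkeeping failure for EMU %s in channel of '%s'",
                     key, names(net$rxns)[[chans[[p$chan]]$rxn]]))
      for (s in srcs) enqueue(s$met, s$idx)
      tl <- c(tl, list(list(chan = p$chan, coef = p$entry$coef, srcs = srcs)))
    }
    terms[[key]] <- tl
  }

  # consumption groups: balanced met -> (chan, coef) pairs
  cons_groups <- list()
  for (ci in seq_along(chans)) for (e in chans[[ci]]$lhs) {
    if (!isTRUE(balanced[[e$met]])) next
    cons_groups[[e$met]] <- rbind(cons_groups[[e$met]], c(ci, e$coef))
  }

  # layer by size
  unk_keys <- names(emus)[vapply(names(emus), function(k) balanced[[emus[[k]]$met]], logical(1))]
  sizes <- sort(unique(vapply(unk_keys, function(k) emus[[k]]$size, integer(1))))
  layers <- list()
  for (s in sizes) {
    keys <- unk_keys[vapply(unk_keys, function(k) emus[[k]]$size == s, logical(1))]
    kidx <- setNames(seq_along(keys), keys)
    met_of <- vapply(keys, function(k) emus[[k]]$met, character(1))
    Ai <- integer(); Aj <- integer(); Ac <- integer(); Aw <- numeric()
    Bterms <- list()
    for (k in keys) {
      i <- kidx[[k]]
      for (tm in terms[[k]]) {
        if (length(tm$srcs) == 1L) {
          s1 <- tm$srcs[[1L]]
          skey <- .emu_key(s1$met, s1$idx)
          if (balanced[[s1$met]] && emus[[skey]]$size == s) {
            Ai <- c(Ai, i); Aj <- c(Aj, kidx[[skey]]); Ac <- c(Ac, tm$chan)
            Aw <- c(Aw, tm$coef)
            next
          }
        }
        Bterms[[length(Bterms) + 1L]] <-
          list(i = i, chan = tm$chan, coef = tm$coef,
               srcs = lapply(tm$srcs, function(s1)
                 list(key = .emu_key(s1$met, s1$idx), met = s1$met, idx = s1$idx,
                      known = !balanced[[s1$met]])))
      }
    }
    layers[[as.character(s)]] <- list(size = s, keys = keys, met_of = met_of,
                                      A = list(i = Ai, j = Aj, chan = Ac, w = Aw),
                                      Bterms = Bterms)
  }

  frag_keys <- setNames(vapply(seq_len(nrow(spec)), function(i)
    .emu_key(spec$metabolite[[i]], subsets[[i]]), character(1)), spec$fragment_id)

  structure(list(net = net, spec = spec, chans = chans, layers = layers,
                 sizes = sizes, cons_groups = cons_groups, emus = emus,
                 frag_keys = frag_keys),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  cat(sprintf("EMU system: %d fragments, sizes %s, %d EMUs\n",
              nrow(x$spec), paste(x$sizes, collapse = "/"), length(x$emus)))
  for (s in x$sizes) {
    ly <- x$layers[[as.character(s)]]
    cat(sprintf("  size %d: %d unknowns\n", s, length(ly$keys)))
  }
  invisible(x)
}

# known-input EMU MID (substrate from the tracer; other unbalanced pools from
# per-carbon label probabilities, default 0 = unlabelled infinite pool)
.input_mid <- function(sys, met, idx, tracer, input_label) {
  if (identical(met, sys$net$substrate_id)) return(tracer_emu_mid(tracer, idx))
  q <- if (!is.null(input_label[[met]])) input_label[[met]] else 0
  mid <- 1
  for (p in rep_len(q, length(idx))) mid <- .conv(mid, c(1 - p, p))
  mid
}

#' Simulate mass isotopomer distributions by EMU cascade
#'
#' Forward-simulates the steady-state MID of every fragment in `spec` under
#' the given flux distribution and tracer.  Unbalanced pools other than the
#' substrate (e.g. CO2 consumed by carboxylation) default to unlabelled; the
#' network can alternatively declare CO2 balanced, in which case its labelling
#' is part of the solved system.
#'
#' @param net An `amn` network.
#' @param flux A `flux_distribution` (net and exchange fluxes; irreversible
#'   nets must be non-negative).
#' @param tracer A `tracer_spec`.
#' @param spec A `measurement_spec`.
#' @param sys Optional precompiled [decompose_emu()] system (reused for
#'   speed in fitting loops).
#' @param input_label Named list: unbalanced metabolite id -> per-carbon
#'   label probability (default 0 for all, i.e. unlabelled).
#' @param check_steady Warn if `flux` violates steady state at 2% of uptake.
#' @param balance Project the net fluxes onto the exact steady-state manifold
#'   (minimal least-squares adjustment) before simulating; removes rounding
#'   residue from tabulated flux maps.  The EMU balance assumes S v = 0
#'   exactly, so this is on by default.
#' @return A `mid_dataset` with one MID per fragment, each summing to 1.
#' @export
simulate_mids <- function(net, flux, tracer, spec, sys = NULL,
                          input_label = list(), check_steady = TRUE,
                          balance = TRUE) {
  if (is.null(sys)) sys <- decompose_emu(net, spec)
  v_net <- flux_vector(flux, net)
  if (balance) v_net <- balance_fluxes(net, v_net)
  v_exch <- flux$exch_pct[match(reaction_ids(net), flux$reaction)]
  v_exch[is.na(v_exch)] <- 0
  irrev <- !vapply(net$rxns, `[[`, logical(1), "reversible")
  if (any(v_net[irrev] < -1e-9))
    stop(sprintf("negative net flux through irreversible reaction(s): %s",
                 paste(names(v_net)[irrev & v_net < -1e-9], collapse = ", ")))
  if (check_steady) {
    ss <- validate_steady_state(net, flux)
    if (!ss$pass)
      warning(sprintf("flux distribution violates steady state (max residual %.3g at %s)",
                      ss$max_residual, ss$worst_metabolite))
  }
  mids <- .emu_solve(sys, v_net, v_exch, tracer, input_label)
  out <- setNames(lapply(names(sys$frag_keys), function(f) mids[[sys$frag_keys[[f]]]]),
                  names(sys$frag_keys))
  mid_dataset(out, sys$spec, sd = 0, check = TRUE, tol = 1e-8)
}

# core numeric pass: solve the layered systems for given channel fluxes
.emu_solve <- function(sys, v_net, v_exch, tracer, input_label = list()) {
  fl <- .chan_fluxes(sys$chans, v_net, v_exch)
  cons <- vapply(sys$cons_groups, function(g) sum(fl[g[, 1L]] * g[, 2L]), numeric(1))
  cache <- new.env(parent = emptyenv())
  get_mid <- function(src) {
    if (src$known) return(.input_mid(sys, src$met, src$idx, tracer, input_label))
    get(src$key, envir = cache)
  }
  for (s in sys$sizes) {
    ly <- sys$layers[[as.character(s)]]
    n <- length(ly$keys)
    ci <- cons[ly$met_of]
    if (any(is.na(ci) | ci <= 0))
      stop(sprintf("EMU system singular: no consuming flux for metabolite(s) %s",
                   paste(unique(ly$met_of[is.na(ci) | ci <= 0]), collapse = ", ")))
    A <- diag(ci, n, n)
    if (length(ly$A$i)) {
      vals <- fl[ly$A$chan] * ly$A$w
      idx <- (ly$A$j - 1L) * n + ly$A$i
      agg <- rowsum(vals, group = idx)
      A[as.integer(rownames(agg))] <- A[as.integer(rownames(agg))] - agg[, 1L]
    }
    B <- matrix(0, n, s + 1L)
    for (tm in ly$Bterms) {
      f <- fl[[tm$chan]] * tm$coef
      if (f == 0) next
      m <- 1
      for (src in tm$srcs) m <- .conv(m, get_mid(src))
      B[tm$i, ] <- B[tm$i, ] + f * m
    }
    X <- tryCatch(solve(A, B), error = function(e)
      stop(sprintf("EMU size-%d system singular (zero-flux dead end among: %s)",
                   s, paste(unique(ly$met_of), collapse = ", "))))
    for (i in seq_len(n)) assign(ly$keys[[i]], X[i, ], envir = cache)
  }
  as.list(cache)
}
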