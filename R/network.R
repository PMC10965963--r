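#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Atom-mapped metabolic networks
#
# A network is a set of reactions over carbon-counted metabolites.  Each
# reaction may carry an atom map: one lower-case letter per carbon atom, the
# same letter denoting the same atom on both sides.  Symmetric metabolites
# (succinate, fumarate) are handled by writing alternative product
# orientations with fractional coefficients, e.g.
#   sdh: SUC (abcd) -> 0.5 FUM (abcd) + 0.5 FUM (dcba)
# which the parser expands into equally weighted reaction "channels".
# ---------------------------------------------------------------------------

#' Parse an atom-mapped network file
#'
#' Reads the plain-text reaction dialect: one reaction per line,
#' `id: coeff MET (letters) + ... -> ... | EnzymeLabel`, `<->` for reversible
#' reactions, `#` comments, and directive lines `@substrate`, `@uptake`,
#' `@unbalanced`, `@carbons`.  Lumped reactions (e.g. a biomass drain) omit
#' the letter groups entirely.  Carbon counts are inferred from the atom maps
#' unless declared with `@carbons`.
#'
#' @param text Character scalar with the file content, or a character vector
#'   of lines, or a path to a file.
#' @return An object of class `amn` (atom-mapped network): a list with
#'   elements `mets` (data frame: `id`, `name`, `n_carbons`, `is_balanced`),
#'   `rxns` (named list of reactions, each with `id`, `enzyme`, `reversible`,
#'   stoichiometric entries and atom-map channels), `substrate_id` and
#'   `uptake_id`.
#' @examples
#' net <- parse_network("xylA: XYL (abcde) -> XLU (abcde)")
#' @export
parse_network <- function(text) {
  lines <- .as_lines(text)
  mets_declared <- list()
  substrate_id <- NA_character_
  uptake_id <- NA_character_
  unbalanced <- character()
  rxns <- list()

  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, "@")) {
      toks <- strsplit(line, "\\s+")[[1]]
      key <- toks[[1]]
      if (key == "@substrate") substrate_id <- toks[[2]]
      else if (key == "@uptake") uptake_id <- toks[[2]]
      else if (key == "@unbalanced") unbalanced <- c(unbalanced, toks[-1])
      else if (key == "@carbons") mets_declared[[toks[[2]]]] <- as.integer(toks[[3]])
      else stop(sprintf("line %d: unknown directive '%s'", i, key))
      next
    }
    rx <- tryCatch(.parse_reaction_line(line),
                   error = function(e) stop(sprintf("line %d: %s", i, conditionMessage(e)),
                                            call. = FALSE))
    if (rx$id %in% names(rxns)) stop(sprintf("line %d: duplicate reaction id '%s'", i, rx$id))
    rxns[[rx$id]] <- rx
  }
  if (!length(rxns)) stop("no reactions found")

  net <- .assemble_network(rxns, mets_declared, substrate_id, uptake_id, unbalanced)
  net
}

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

# one side of a reaction -> list of entries (met, coef, letters or NA)
.parse_side <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(list())
  terms <- strsplit(s, "\\s*\\+\\s*")[[1]]
  # coefficient must be whitespace-separated; metabolite ids may start with
  # a digit (6PG) but must contain a letter
  lapply(terms, function(tm) {
    m <- regmatches(tm, regexec(
      "^\\s*([0-9]*\\.?[0-9]+\\s+)?([A-Za-z0-9_]*[A-Za-z_][A-Za-z0-9_]*)\\s*(\\(([a-z]+)\\))?\\s*$",
      tm))[[1]]
    if (!length(m)) stop(sprintf("malformed term '%s'", tm))
    coef <- if (nzchar(trimws(m[[2]]))) as.numeric(trimws(m[[2]])) else 1
    letters <- if (nzchar(m[[5]])) m[[5]] else NA_character_
    list(met = m[[3]], coef = coef, letters = letters)
  })
}

.parse_reaction_line <- function(line) {
  enzyme <- NA_character_
  if (grepl("|", line, fixed = TRUE)) {
    parts <- strsplit(line, "|", fixed = TRUE)[[1]]
    line <- trimws(parts[[1]])
    enzyme <- trimws(paste(parts[-1], collapse = "|"))
  }
  m <- regmatches(line, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", line))[[1]]
  if (!length(m)) stop(sprintf("malformed reaction line '%s'", line))
  id <- m[[2]]
  body <- m[[3]]
  reversible <- grepl("<->", body, fixed = TRUE)
  sides <- strsplit(body, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1L && grepl("->", body, fixed = TRUE)) sides <- c(sides, "")
  if (length(sides) != 2L) stop(sprintf("reaction '%s' needs exactly one arrow", id))
  lhs <- .parse_side(sides[[1]])
  rhs <- .parse_side(sides[[2]])
  if (!length(lhs)) stop(sprintf("reaction '%s' has an empty substrate side", id))
  has_map <- vapply(c(lhs, rhs), function(e) !is.na(e$letters), logical(1))
  if (any(has_map) && !all(has_map))
    stop(sprintf("reaction '%s' mixes mapped and unmapped species", id))
  list(id = id, enzyme = enzyme, reversible = reversible,
       lhs = lhs, rhs = rhs, mapped = all(has_map) && length(has_map) > 0)
}

# Split a side into "alternative groups" (scrambled orientations of a
# symmetric metabolite: duplicated met, fractional equal coefs, letter sets
# that are permutations of each other) and plain entries.
.side_groups <- function(entries) {
  if (!length(entries)) return(list(plain = list(), groups = list()))
  mets <- vapply(entries, `[[`, character(1), "met")
  plain <- list(); groups <- list()
  for (mt in unique(mets)) {
    idx <- which(mets == mt)
    es <- entries[idx]
    if (length(idx) > 1L && all(vapply(es, function(e) e$coef < 1, logical(1)))) {
      sets <- vapply(es, function(e) paste(sort(strsplit(e$letters, "")[[1]]), collapse = ""),
                     character(1))
      if (length(unique(sets)) == 1L) { groups[[length(groups) + 1L]] <- es; next }
    }
    plain <- c(plain, es)
  }
  list(plain = plain, groups = groups)
}

# Expand a reaction into channels: list(lhs, rhs, share); each channel's
# chosen group entry gets coefficient 1 and share = its fractional coef.
.reaction_channels <- function(rx) {
  if (!rx$mapped) return(list(list(lhs = rx$lhs, rhs = rx$rhs, share = 1)))
  gl <- .side_groups(rx$lhs); gr <- .side_groups(rx$rhs)
  chans <- list(list(lhs = gl$plain, rhs = gr$plain, share = 1))
  expand <- function(chans, groups, side) {
    for (grp in groups) {
      tot <- sum(vapply(grp, `[[`, numeric(1), "coef"))
      new <- list()
      for (ch in chans) for (e in grp) {
        e2 <- e; e2$coef <- 1
        ch2 <- ch
        ch2[[side]] <- c(ch2[[side]], list(e2))
        ch2$share <- ch$share * e$coef / tot
        new[[length(new) + 1L]] <- ch2
      }
      chans <- new
    }
    chans
  }
  chans <- expand(chans, gl$groups, "lhs")
  chans <- expand(chans, gr$groups, "rhs")
  chans
}

.assemble_network <- function(rxns, mets_declared, substrate_id, uptake_id, unbalanced) {
  # infer carbon counts from atom maps
  n_carbons <- unlist(mets_declared)
  n_carbons <- if (is.null(n_carbons)) integer() else n_carbons
  seen <- character()
  for (rx in rxns) {
    for (e in c(rx$lhs, rx$rhs)) {
      seen <- union(seen, e$met)
      if (is.na(e$letters)) next
      nc <- nchar(e$letters)
      if (e$met %in% names(n_carbons)) {
        if (n_carbons[[e$met]] != nc)
          stop(sprintf("reaction '%s': metabolite '%s' has %d atom letters but %d carbons",
                       rx$id, e$met, nc, n_carbons[[e$met]]))
      } else n_carbons[[e$met]] <- nc
    }
  }
  missing_nc <- setdiff(seen, names(n_carbons))
  for (mt in missing_nc) n_carbons[[mt]] <- 0L

  # per-reaction validation: channels, letter balance, letter uniqueness
  for (rid in names(rxns)) {
    rx <- rxns[[rid]]
    if (!rx$mapped) { rxns[[rid]]$channels <- .reaction_channels(rx); next }
    chans <- .reaction_channels(rx)
    for (ch in chans) {
      for (e in c(ch$lhs, ch$rhs))
        if (anyDuplicated(strsplit(e$letters, "")[[1]]))
          stop(sprintf("reaction '%s': repeated letter within '%s'", rid, e$met))
      lt <- table(unlist(lapply(ch$lhs, function(e) strsplit(e$letters, "")[[1]])))
      rt <- table(unlist(lapply(ch$rhs, function(e) strsplit(e$letters, "")[[1]])))
      if (!identical(sort(names(lt)), sort(names(rt))) ||
          !all(lt[sort(names(lt))] == rt[sort(names(rt))]))
        stop(sprintf("reaction '%s': atom letters do not balance (lhs '%s' vs rhs '%s')",
                     rid, paste(names(lt), collapse = ""), paste(names(rt), collapse = "")))
    }
    rxns[[rid]]$channels <- chans
  }

  mets <- data.frame(
    id = names(n_carbons),
    name = names(n_carbons),
    n_carbons = as.integer(unlist(n_carbons)),
    is_balanced = !(names(n_carbons) %in% unbalanced),
    stringsAsFactors = FALSE
  )
  rownames(mets) <- mets$id

  net <- structure(list(mets = mets, rxns = rxns,
                        substrate_id = substrate_id, uptake_id = uptake_id),
                   class = "amn")
  if (!is.na(uptake_id)) {
    if (!uptake_id %in% names(rxns)) stop(sprintf("uptake reaction '%s' not found", uptake_id))
    if (!is.na(substrate_id)) {
      up <- rxns[[uptake_id]]
      lm <- vapply(up$lhs, `[[`, character(1), "met")
      if (!identical(lm, substrate_id))
        stop("uptake reaction must consume exactly the substrate")
    }
  }
  net
}

#' @export
print.amn <- function(x, ...) {
  cat(sprintf("Atom-mapped network: %d reactions, %d metabolites (%d balanced)\n",
              length(x$rxns), nrow(x$mets), sum(x$mets$is_balanced)))
  if (!is.na(x$substrate_id)) cat("substrate:", x$substrate_id, " uptake:", x$uptake_id, "\n")
  invisible(x)
}

#' Reaction ids of a network
#' @param net An `amn` network.
#' @return Character vector of reaction ids.
#' @export
reaction_ids <- function(net) names(net$rxns)

#' Enzyme labels of a network
#'
#' Lumped reactions carry composite labels such as `"Gap/Pgk/Pgm/Eno"`;
#' these are split so the result lists each enzyme once.
#' @param net An `amn` network.
#' @return Sorted character vector of enzyme labels.
#' @export
enzyme_labels <- function(net) {
  labs <- unlist(lapply(net$rxns, `[[`, "enzyme"))
  labs <- labs[!is.na(labs)]
  sort(unique(unlist(strsplit(labs, "/", fixed = TRUE))))
}

#' Stoichiometric matrix of a network
#'
#' @param net An `amn` network.
#' @param balanced_only Keep only rows for balanced (internal) metabolites.
#' @return Numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(net, balanced_only = TRUE) {
  mids <- net$mets$id
  S <- matrix(0, nrow = length(mids), ncol = length(net$rxns),
              dimnames = list(mids, names(net$rxns)))
  for (j in seq_along(net$rxns)) {
    rx <- net$rxns[[j]]
    for (e in rx$lhs) S[e$met, j] <- S[e$met, j] - e$coef
    for (e in rx$rhs) S[e$met, j] <- S[e$met, j] + e$coef
  }
  if (balanced_only) S <- S[net$mets$is_balanced, , drop = FALSE]
  S
}

#' Serialize a network back to its text dialect
#'
#' `parse_network(format_network(net))` reproduces an equivalent network
#' (same stoichiometry and atom maps).
#' @param net An `amn` network.
#' @return Character scalar (file content).
#' @export
format_network <- function(net) {
  out <- character()
  if (!is.na(net$substrate_id)) out <- c(out, paste("@substrate", net$substrate_id))
  if (!is.na(net$uptake_id)) out <- c(out, paste("@uptake", net$uptake_id))
  unb <- net$mets$id[!net$mets$is_balanced]
  if (length(unb)) out <- c(out, paste("@unbalanced", paste(unb, collapse = " ")))
  zero <- net$mets$id[net$mets$n_carbons == 0L]
  fmt_side <- function(side) paste(vapply(side, function(e) {
    co <- if (e$coef != 1) paste0(format(e$coef), " ") else ""
    lt <- if (!is.na(e$letters)) paste0(" (", e$letters, ")") else ""
    paste0(co, e$met, lt)
  }, character(1)), collapse = " + ")
  for (rx in net$rxns) {
    arrow <- if (rx$reversible) "<->" else "->"
    enz <- if (!is.na(rx$enzyme)) paste(" |", rx$enzyme) else ""
    out <- c(out, sprintf("%s: %s %s %s%s", rx$id, fmt_side(rx$lhs), arrow,
                          fmt_side(rx$rhs), enz))
  }
  paste(out, collapse = "\n")
}

#' Loss-free JSON serialization of a network
#' @param net An `amn` network.
#' @return JSON string.
#' @export
network_to_json <- function(net) {
  jsonlite::toJSON(list(
    substrate_id = net$substrate_id, uptake_id = net$uptake_id,
    metabolites = net$mets,
    reactions = lapply(unname(net$rxns), function(rx) {
      side <- function(s) lapply(s, function(e)
        list(met = e$met, coef = e$coef, letters = e$letters))
      list(id = rx$id, enzyme = rx$enzyme, reversible = rx$reversible,
           lhs = side(rx$lhs), rhs = side(rx$rhs))
    })), auto_unbox = TRUE, digits = NA, na = "null")
}

#' Read a network from its JSON serialization
#' @param text JSON string or path.
#' @return An `amn` network.
#' @export
network_from_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  side <- function(s) vapply(s, function(e) {
    lt <- if (is.null(e$letters)) "" else paste0(" (", e$letters, ")")
    sprintf("%s %s%s", format(e$coef), e$met, lt)
  }, character(1))
  lines <- vapply(obj$reactions, function(rx) {
    arrow <- if (isTRUE(rx$reversible)) "<->" else "->"
    enz <- if (!is.null(rx$enzyme) && !is.na(rx$enzyme)) paste(" |", rx$enzyme) else ""
    sprintf("%s: %s %s %s%s", rx$id, paste(side(rx$lhs), collapse = " + "),
            arrow, paste(side(rx$rhs), collapse = " + "), enz)
  }, character(1))
  head <- character()
  if (!is.null(obj$substrate_id) && !is.na(obj$substrate_id))
    head <- c(head, paste("@substrate", obj$substrate_id))
  if (!is.null(obj$uptake_id) && !is.na(obj$uptake_id))
    head <- c(head, paste("@uptake", obj$uptake_id))
  unb <- vapply(obj$metabolites, function(m) if (isFALSE(m$is_balanced)) m$id else NA_character_,
                character(1))
  unb <- unb[!is.na(unb)]
  if (length(unb)) head <- c(head, paste("@unbalanced", paste(unb, collapse = " ")))
  parse_network(c(head, lines))
}
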