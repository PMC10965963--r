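# ---------------------------------------------------------------------------
# Measurement specifications and MID datasets.
#
# A fragment is an observed carbon subset of a network metabolite, e.g. the
# full backbone of an intracellular sugar phosphate (IC-MS) or the carbon
# skeleton retained by a TBDMS amino-acid fragment (GC-MS), mapped to its
# biosynthetic precursor metabolite of the core network.
# ---------------------------------------------------------------------------

#' Build a measurement specification
#'
#' @param fragment_id Unique fragment labels, conventionally `Met[i-j]`.
#' @param metabolite Network metabolite observed.
#' @param carbons Carbon subsets as strings: `"1-3"`, `"2-4"`, `"1,3"`.
#' @param instrument Free-text instrument tag.
#' @return A `measurement_spec` data frame.
#' @export
measurement_spec <- function(fragment_id, metabolite, carbons,
                             instrument = NA_character_) {
  if (anyDuplicated(fragment_id)) stop("duplicate fragment ids")
  df <- data.frame(fragment_id = fragment_id, metabolite = metabolite,
                   carbons = carbons,
                   instrument = rep_len(instrument, length(fragment_id)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("measurement_spec", "data.frame"))
}

#' Parse a carbon-subset string such as "1-3" or "2,4"
#' @param s Character scalar.
#' @return Sorted integer vector of 1-based carbon indices.
#' @export
parse_carbons <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  idx <- unlist(lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      seq.int(ab[[1]], ab[[2]])
    } else as.integer(p)
  }))
  sort(unique(idx))
}

# validate a spec against a network; returns list of integer subsets
.spec_subsets <- function(net, spec) {
  lapply(seq_len(nrow(spec)), function(i) {
    met <- spec$metabolite[[i]]
    if (!met %in% net$mets$id)
      stop(sprintf("fragment '%s': metabolite '%s' not in network",
                   spec$fragment_id[[i]], met))
    idx <- parse_carbons(spec$carbons[[i]])
    nc <- net$mets[met, "n_carbons"]
    if (!length(idx) || min(idx) < 1 || max(idx) > nc)
      stop(sprintf("fragment '%s': carbons %s invalid for %s (%d carbons)",
                   spec$fragment_id[[i]], spec$carbons[[i]], met, nc))
    idx
  })
}

#' Read / write a measurement spec (JSON or YAML)
#' @param path File path (`.json`, `.yml`/`.yaml`).
#' @export
read_measurement_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
  df <- do.call(rbind, lapply(obj$fragments, function(f)
    data.frame(fragment_id = f$fragment_id, metabolite = f$metabolite,
               carbons = f$carbons,
               instrument = if (is.null(f$instrument)) NA_character_ else f$instrument,
               stringsAsFactors = FALSE)))
  measurement_spec(df$fragment_id, df$metabolite, df$carbons, df$instrument)
}

#' @rdname read_measurement_spec
#' @param spec A `measurement_spec`.
#' @export
write_measurement_spec <- function(spec, path) {
  obj <- list(fragments = lapply(seq_len(nrow(spec)), function(i)
    as.list(spec[i, , drop = FALSE])))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, na = "null"), path)
  invisible(path)
}

# --------------------------- MID datasets ----------------------------------

#' Construct a MID dataset from a list of MID vectors
#'
#' @param mids Named list: fragment id -> numeric MID vector (`M+0 ... M+n`).
#' @param spec The `measurement_spec` the fragments belong to.
#' @param sd Measurement SD per mass fraction: scalar or named list/vector.
#' @param check Verify each MID is non-negative and sums to 1 (within `tol`).
#' @param tol Tolerance on the sum (default 1e-9, the simulator contract).
#' @return A `mid_dataset`: long data frame with columns `fragment_id`,
#'   `metabolite`, `carbons`, `mass_shift`, `fraction`, `sd`.
#' @export
mid_dataset <- function(mids, spec, sd = 0, check = TRUE, tol = 1e-9) {
  stopifnot(all(names(mids) %in% spec$fragment_id))
  sdv <- if (length(sd) == 1L) setNames(rep(as.numeric(sd), length(mids)), names(mids))
         else unlist(sd)[names(mids)]
  rows <- lapply(names(mids), function(fid) {
    m <- mids[[fid]]
    if (check) {
      if (any(m < -1e-12)) stop(sprintf("fragment '%s': negative MID fraction", fid))
      if (abs(sum(m) - 1) > tol) stop(sprintf("fragment '%s': MID sums to %.12g", fid, sum(m)))
    }
    i <- match(fid, spec$fragment_id)
    data.frame(fragment_id = fid, metabolite = spec$metabolite[[i]],
               carbons = spec$carbons[[i]], mass_shift = seq_along(m) - 1L,
               fraction = as.numeric(m), sd = sdv[[fid]], stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("mid_dataset", "data.frame"))
}

#' Extract one fragment's MID vector
#' @param ds A `mid_dataset`.
#' @param fragment_id Fragment label.
#' @export
mid_vector <- function(ds, fragment_id) {
  sub <- ds[ds$fragment_id == fragment_id, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("fragment '%s' not in dataset", fragment_id))
  sub$fraction[order(sub$mass_shift)]
}

#' All MID vectors as a named list
#' @param ds A `mid_dataset`.
#' @export
mid_list <- function(ds) {
  fids <- unique(ds$fragment_id)
  setNames(lapply(fids, function(f) mid_vector(ds, f)), fids)
}

#' Read / write a MID dataset CSV
#'
#' Columns: `fragment_id, metabolite, carbons, mass_shift, fraction, sd`
#' (one row per mass isotopomer).
#' @param path CSV path.
#' @export
read_mid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("fragment_id", "metabolite", "carbons", "mass_shift", "fraction", "sd")
  if (!all(need %in% names(df)))
    stop(sprintf("MID CSV must have columns: %s", paste(need, collapse = ", ")))
  structure(df[need], class = c("mid_dataset", "data.frame"))
}

#' @rdname read_mid_csv
#' @param ds A `mid_dataset`.
#' @export
write_mid_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
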