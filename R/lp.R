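# ---------------------------------------------------------------------------
# Linear-programming backend.
#
# Problems are handed to scipy's HiGGS/HiGHS interface (pre-installed in the
# scientific Python stack this package targets) through a batch JSON bridge,
# so a whole FVA sweep costs a single interpreter start.
# ---------------------------------------------------------------------------

.find_python <- function() {
  for (cand in c(Sys.getenv("EDEMPFLUX_PYTHON"), "python", "python3")) {
    if (!nzchar(cand)) next
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found for the LP backend (set EDEMPFLUX_PYTHON)")
}

#' Solve a batch of linear programs over a shared constraint matrix
#'
#' @param A List with integer vectors `i`, `j` and numeric `x`: triplet form
#'   of the constraint matrix.
#' @param nrow,ncol Dimensions.
#' @param rowlb,rowub Row (constraint) bounds; equal values mean equality.
#' @param collb,colub Column (variable) bounds.
#' @param tasks List of tasks: each `list(name=, obj=, sense="max"/"min",
#'   collb=, colub=)` (bound overrides optional).
#' @return List of results: `name`, `status`, and for optimal solutions
#'   `objective` and `x`.
#' @export
solve_lp_batch <- function(A, nrow, ncol, rowlb, rowub, collb, colub, tasks) {
  stopifnot(length(A$i) == length(A$j), length(A$j) == length(A$x))
  py <- .find_python()
  script <- system.file("python", "lp_batch.py", package = "edempflux")
  if (!nzchar(script)) stop("lp_batch.py not found in installed package")
  inp <- tempfile(fileext = ".json"); outp <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, outp)), add = TRUE)
  fin <- function(v) { v[v == Inf] <- 1e30; v[v == -Inf] <- -1e30; v }
  enc <- jsonlite::toJSON(list(
    ncol = ncol, nrow = nrow,
    A = list(i = A$i, j = A$j, x = A$x),
    rowlb = fin(rowlb), rowub = fin(rowub),
    collb = fin(collb), colub = fin(colub),
    tasks = lapply(tasks, function(t) {
      t$obj <- as.numeric(t$obj)
      if (!is.null(t$collb)) t$collb <- fin(t$collb)
      if (!is.null(t$colub)) t$colub <- fin(t$colub)
      t
    })), auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(enc, inp)
  st <- system2(py, c(script, inp, outp), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outp))
    stop(sprintf("LP backend failed: %s", paste(st, collapse = "\n")))
  jsonlite::fromJSON(outp, simplifyVector = FALSE)$results
}
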