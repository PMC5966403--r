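#' @import methods
NULL

#' Multi-frame stem-loop coordinate ensemble
#'
#' Container for an ensemble (NMR-style bundle or trajectory) of a short
#' RNA hairpin: a fixed atom roster shared by every frame, plus one
#' coordinate set per frame.  Residues are numbered 1-based and
#' contiguous; every residue carries at least its C1' atom so that
#' backbone-level distance observables are always computable.
#'
#' @slot coords numeric array `n_atoms x 3 x n_frames`, coordinates in
#'   Angstrom.
#' @slot atoms `data.frame` with one row per atom and columns `residue`
#'   (integer index), `resname` (residue name, e.g. `"A"`), `atom`
#'   (atom name, prime convention, e.g. `"C1'"`), `element` and `mass`
#'   (atomic mass units).
#' @slot metadata list of free-form annotations (reference geometries,
#'   generator truth, source file).
#'
#' @seealso [simHairpinEnsemble()], [readEnsemblePDB()],
#'   [pairwiseBundleRmsd()], [rmsfProfile()]
#' @exportClass HairpinEnsemble
setClass("HairpinEnsemble",
  representation(
    coords = "array",
    atoms = "data.frame",
    metadata = "list"
  )
)

setValidity("HairpinEnsemble", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an n_atoms x 3 x n_frames array")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  need <- c("residue", "resname", "atom", "element", "mass")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@atoms) != d[1])
      msg <- c(msg, "atom table and coordinate array disagree on atom count")
    res <- sort(unique(object@atoms$residue))
    if (length(res) && !identical(res, seq(min(res), max(res))))
      msg <- c(msg, "residue indices must be contiguous")
    if (length(res) && min(res) != 1L)
      msg <- c(msg, "residue indices must start at 1")
  }
  if (length(msg)) msg else TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' Result of a 4PL least-squares fit
#' \deqn{y = bottom + (top - bottom) / (1 + (EC50/x)^{hill})}
#' performed in log-concentration space.  The EC50 is only reported
#' (non-`NA`) when the optimiser converged and the estimate lies within
#' ten-fold of the tested concentration range.
#'
#' @slot bottom,top numeric, lower and upper response asymptotes.
#' @slot ec50 numeric, half-maximal concentration (same units as the
#'   input concentrations); `NA` unless `converged` is `TRUE`.
#' @slot hill numeric, Hill slope (constrained positive).
#' @slot residualSSE numeric, residual sum of squares.
#' @slot converged logical.
#' @slot nObs integer, number of observations fitted.
#' @slot message character, diagnostic note (empty when converged).
#'
#' @seealso [fit4PL()], [splicingDoseResponse()]
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(
    bottom = "numeric",
    top = "numeric",
    ec50 = "numeric",
    hill = "numeric",
    residualSSE = "numeric",
    converged = "logical",
    nObs = "integer",
    message = "character"
  ),
  prototype(
    bottom = NA_real_, top = NA_real_, ec50 = NA_real_, hill = NA_real_,
    residualSSE = NA_real_, converged = FALSE, nObs = 0L, message = ""
  )
)

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (!is.na(object@ec50) && object@ec50 <= 0)
      msg <- c(msg, "ec50 must be positive")
    if (!is.na(object@hill) && object@hill <= 0)
      msg <- c(msg, "hill slope must be positive")
  } else if (!is.na(object@ec50)) {
    msg <- c(msg, "ec50 may only be reported for converged fits")
  }
  if (length(msg)) msg else TRUE
})
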