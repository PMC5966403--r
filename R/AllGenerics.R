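#' Number of frames in an ensemble
#' @param x a [HairpinEnsemble-class] object
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of residues in an ensemble
#' @param x a [HairpinEnsemble-class] object
#' @return integer
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Atom roster of an ensemble
#' @param x a [HairpinEnsemble-class] object
#' @return `data.frame` with columns residue, resname, atom, element, mass
#' @export
setGeneric("atomInfo", function(x) standardGeneric("atomInfo"))

#' Coordinates of one frame
#' @param x a [HairpinEnsemble-class] object
#' @param frame integer frame index
#' @return numeric matrix `n_atoms x 3` (Angstrom)
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))

#' Half-maximal concentration of a dose-response fit
#' @param object a [DoseResponseFit-class] object
#' @return numeric; `NA` with a warning when the fit did not converge
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))
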