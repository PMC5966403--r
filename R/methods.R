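#' @describeIn HairpinEnsemble number of frames
#' @param x,frame see generic
#' @aliases nFrames,HairpinEnsemble-method
#' @export
setMethod("nFrames", "HairpinEnsemble", function(x) dim(x@coords)[3])

#' @describeIn HairpinEnsemble number of residues
#' @aliases nResidues,HairpinEnsemble-method
#' @export
setMethod("nResidues", "HairpinEnsemble", function(x)
  length(unique(x@atoms$residue)))

#' @describeIn HairpinEnsemble atom roster
#' @aliases atomInfo,HairpinEnsemble-method
#' @export
setMethod("atomInfo", "HairpinEnsemble", function(x) x@atoms)

#' @describeIn HairpinEnsemble coordinates of one frame (n_atoms x 3)
#' @aliases frameCoords,HairpinEnsemble-method
#' @export
setMethod("frameCoords", "HairpinEnsemble", function(x, frame = 1L) {
  frame <- as.integer(frame)
  if (frame < 1L || frame > nFrames(x))
    stop("frame index out of range [1, ", nFrames(x), "]")
  m <- x@coords[, , frame, drop = FALSE]
  dim(m) <- dim(x@coords)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})

setMethod("show", "HairpinEnsemble", function(object) {
  a <- object@atoms
  cat("HairpinEnsemble:", nFrames(object), "frame(s),",
      nResidues(object), "residues,", nrow(a), "atoms\n")
  seq_chr <- vapply(split(a$resname, a$residue), `[`, character(1), 1L)
  cat("  sequence: 5'-", paste(seq_chr, collapse = ""), "-3'\n", sep = "")
  cat("  atoms per residue:", paste(sort(unique(a$atom[a$residue == 1])),
                                    collapse = " "), "\n")
})

#' @describeIn DoseResponseFit EC50 accessor; `NA` (with a warning) for
#'   non-converged fits
#' @param object a `DoseResponseFit`
#' @aliases ec50,DoseResponseFit-method
#' @export
setMethod("ec50", "DoseResponseFit", function(object) {
  if (!isTRUE(object@converged)) {
    warning("fit did not converge; no EC50 reported",
            if (nzchar(object@message)) paste0(" (", object@message, ")"))
    return(NA_real_)
  }
  object@ec50
})

setMethod("show", "DoseResponseFit", function(object) {
  cat("DoseResponseFit (4PL)\n")
  if (isTRUE(object@converged)) {
    cat(sprintf("  bottom = %.4g, top = %.4g, ec50 = %.4g, hill = %.4g\n",
                object@bottom, object@top, object@ec50, object@hill))
    cat(sprintf("  residual SSE = %.4g over %d points\n",
                object@residualSSE, object@nObs))
  } else {
    cat("  NOT converged")
    if (nzchar(object@message)) cat(":", object@message)
    cat("\n")
  }
})
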