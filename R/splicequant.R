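# Exon-inclusion quantification and treatment-effect read-outs:
# percent inclusion from band intensities, percent of maximum
# inclusion increment, ddCt fold changes, structural-probe deltas and
# CD extrema.

#' Percent exon inclusion from band intensities
#'
#' `100 * inc / (inc + skip)` after optional constant background
#' subtraction applied to both bands (floored at 0).
#'
#' @param inc,skip included / skipped band intensities (a.u., >= 0).
#' @param background constant background subtracted from both bands.
#' @return percent inclusion in \[0, 100\] (vectorised).
#' @examples
#' percentInclusion(72, 28)  # 72
#' @export
percentInclusion <- function(inc, skip, background = 0) {
  if (any(inc < 0) || any(skip < 0)) stop("band intensities must be >= 0")
  inc <- pmax(0, inc - background)
  skip <- pmax(0, skip - background)
  tot <- inc + skip
  if (any(tot == 0))
    stop("inc + skip must be positive after background subtraction")
  100 * inc / tot
}

#' Percent of maximum exon-inclusion increment possible
#'
#' Treatment-induced gain in exon inclusion normalised by the
#' remaining headroom:
#' \deqn{\%MIP = 100 \times \frac{E7_{treated} - E7_{control}}{100 - E7_{control}}}
#' May be negative when treatment reduces inclusion.  Undefined when
#' the control is already at 100 percent.
#'
#' @param e7Treated,e7Control exon-inclusion percentages in \[0, 100\].
#' @return percent of maximum increment possible (vectorised).
#' @examples
#' mip(60, 20)  # 50
#' @export
mip <- function(e7Treated, e7Control) {
  if (any(e7Treated < 0 | e7Treated > 100) ||
      any(e7Control < 0 | e7Control > 100))
    stop("inclusion percentages must be in [0, 100]")
  if (any(e7Control == 100))
    stop("Undefined: control inclusion of 100% leaves no headroom")
  100 * (e7Treated - e7Control) / (100 - e7Control)
}

#' Relative expression by the 2^-ddCt method
#'
#' \deqn{fold = 2^{-\Delta\Delta Ct}, \quad
#'   \Delta\Delta Ct = (Ct^{tgt}_{trt} - Ct^{ref}_{trt}) -
#'                     (Ct^{tgt}_{ctl} - Ct^{ref}_{ctl})}
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl
#'   cycle-threshold values (finite).
#' @return fold change (> 0, vectorised).
#' @examples
#' ddctFold(24, 20, 26, 20)  # 4
#' @export
ddctFold <- function(ctTargetTreated, ctRefTreated,
                     ctTargetControl, ctRefControl) {
  ct <- c(ctTargetTreated, ctRefTreated, ctTargetControl, ctRefControl)
  if (!all(is.finite(ct))) stop("Ct values must be finite")
  ddct <- (ctTargetTreated - ctRefTreated) - (ctTargetControl - ctRefControl)
  2^(-ddct)
}

#' Structural-probe signal deltas and their correlation with inclusion
#'
#' For each hairpin variant, computes the probe-signal change relative
#' to the reference variant, `delta% = 100 * (F - F_ref) / F_ref`
#' (replicates averaged first), then the Pearson correlation between
#' delta-percent and exon inclusion across variants with a t-based
#' two-tailed p-value.
#'
#' @param panel data.frame with columns `variant_id`, `probe_signal`,
#'   `e7_inclusion` (replicate rows allowed).
#' @param reference reference variant id (default `"n.m."`,
#'   non-mutated).
#' @return list with `deltas` (variant_id, mean_signal, delta_pct,
#'   e7_inclusion) and `r`, `p`, `n`.
#' @export
probeDeltaCorrelation <- function(panel, reference = "n.m.") {
  need <- c("variant_id", "probe_signal", "e7_inclusion")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  if (!reference %in% panel$variant_id)
    stop("reference variant '", reference, "' not present in panel")
  meanSig <- tapply(panel$probe_signal, panel$variant_id, mean)
  incl <- tapply(panel$e7_inclusion, panel$variant_id, mean)
  variants <- names(meanSig)
  if (length(variants) < 3)
    stop("need >= 3 variants for a correlation")
  fRef <- meanSig[[reference]]
  if (fRef == 0) stop("reference signal is zero; relative delta undefined")
  delta <- 100 * (meanSig - fRef) / fRef
  if (stats::sd(delta) == 0 || stats::sd(incl) == 0)
    stop("ConstantSignal: correlation undefined for constant input")
  ct <- stats::cor.test(delta, incl, method = "pearson",
                        alternative = "two.sided")
  list(deltas = data.frame(variant_id = variants,
                           mean_signal = unname(meanSig),
                           delta_pct = unname(delta),
                           e7_inclusion = unname(incl),
                           stringsAsFactors = FALSE),
       r = unname(ct$estimate), p = ct$p.value, n = length(variants))
}

# 3-point parabolic refinement of a grid extremum
parabolicRefine <- function(x, y, i) {
  if (i == 1 || i == length(y)) return(c(x[i], y[i]))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(c(x[i], y[i]))
  h <- (x[i + 1] - x[i - 1]) / 2
  dx <- 0.5 * (y[i - 1] - y[i + 1]) / denom * h
  c(x[i] + dx, y[i] - 0.25 * (y[i - 1] - y[i + 1]) * dx / h)
}

#' Locate circular-dichroism spectral extrema and peak shifts
#'
#' Finds the positive-band maximum within `positiveWindow` and the
#' negative-band minimum within `negativeWindow` by discrete
#' argmax/argmin refined with 3-point parabolic interpolation (sub-nm
#' reporting).  When a reference spectrum is supplied, reports the
#' positive-peak wavelength shift `lambda_max(spectrum) -
#' lambda_max(reference)`.
#'
#' @param spectrum data.frame with columns `wavelength_nm`, `molar_cd`.
#' @param reference optional reference spectrum (same columns).
#' @param positiveWindow,negativeWindow wavelength windows in nm.
#' @return list with `lambda_max`, `mag_max`, `lambda_min`, `mag_min`
#'   and (when a reference is given) `shift_nm`.
#' @export
cdExtrema <- function(spectrum, reference = NULL,
                      positiveWindow = c(240, 300),
                      negativeWindow = c(200, 235)) {
  need <- c("wavelength_nm", "molar_cd")
  if (!all(need %in% names(spectrum)))
    stop("spectrum must have columns: ", paste(need, collapse = ", "))
  one <- function(spec) {
    spec <- spec[order(spec$wavelength_nm), ]
    inWin <- function(w) spec$wavelength_nm >= w[1] & spec$wavelength_nm <= w[2]
    pos <- spec[inWin(positiveWindow), ]
    neg <- spec[inWin(negativeWindow), ]
    if (nrow(pos) < 5 || nrow(neg) < 5)
      stop("spectrum must cover both windows with >= 5 points each")
    iMax <- which.max(pos$molar_cd)
    iMin <- which.min(neg$molar_cd)
    if (pos$molar_cd[iMax] <= 0)
      stop("no positive extremum in the positive window")
    if (neg$molar_cd[iMin] >= 0)
      stop("no negative extremum in the negative window")
    pk <- parabolicRefine(pos$wavelength_nm, pos$molar_cd, iMax)
    tr <- parabolicRefine(neg$wavelength_nm, neg$molar_cd, iMin)
    list(lambda_max = pk[1], mag_max = pk[2],
         lambda_min = tr[1], mag_min = tr[2])
  }
  out <- one(spectrum)
  if (!is.null(reference))
    out$shift_nm <- out$lambda_max - one(reference)$lambda_max
  out
}

#' Hairpin fraction from native-gel band intensities
#'
#' `hairpin / (hairpin + duplex)` — the fraction of RNA running as the
#' folded hairpin versus intermolecular duplex on a native gel.
#'
#' @param hairpinBand,duplexBand band intensities (a.u., >= 0).
#' @return fraction in \[0, 1\] (vectorised).
#' @export
hairpinFraction <- function(hairpinBand, duplexBand) {
  if (any(hairpinBand < 0) || any(duplexBand < 0))
    stop("band intensities must be >= 0")
  tot <- hairpinBand + duplexBand
  if (any(tot == 0)) stop("hairpin + duplex must be positive")
  hairpinBand / tot
}

#' Dose-response fit of exon inclusion versus concentration
#'
#' Convenience wrapper around [fit4PL()] with percent inclusion as the
#' response.
#'
#' @param doses concentrations in uM.
#' @param inclusion percent-inclusion values.
#' @return a [DoseResponseFit-class] object.
#' @export
splicingDoseResponse <- function(doses, inclusion) {
  if (any(inclusion < 0 | inclusion > 100))
    stop("inclusion must be percentages in [0, 100]")
  fit4PL(doses, inclusion)
}
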