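# Seeded generators for every input the pipeline consumes.  Each
# generator returns the emitted table(s) plus a ground-truth table so
# downstream stages can be scored without external data.  All
# randomness is drawn under withr::with_seed, so identical arguments
# and seed reproduce identical output.

#' Simulate a fluorescence-displacement screening plate
#'
#' Emits well-level fluorescence readings for a dye-displacement binding
#' screen.  Four control/measurement roles are generated per replicate
#' index: `A` (dye + RNA + compound), `B` (dye + compound), `C`
#' (dye + RNA) and `D` (dye alone).  `C` and `D` are plate-level
#' controls (no compound); every compound contributes `A` and `B` wells.
#' True binders displace a fraction of the RNA-dependent dye signal
#' drawn from a truncated normal effect distribution; a configurable
#' fraction of compounds is autofluorescent, which adds signal to their
#' `A` and `B` wells (and cancels in the displacement ratio, as in the
#' physical assay).  Noise is multiplicative lognormal with the given
#' coefficient of variation — plate-reader noise scales with signal.
#'
#' A set of DMSO pseudo-compounds with zero displacement is included so
#' that hit calling has matched vehicle-control activities to test
#' against; they are marked `is_control` in the truth table.
#'
#' @param seed integer, mandatory.
#' @param nCompounds number of test compounds (default 304).
#' @param binderFraction fraction of compounds that truly bind.
#' @param meanEffect,sdEffect mean and SD (percent displacement) of the
#'   binder effect distribution, truncated at 0.
#' @param cv coefficient of variation of well fluorescence.
#' @param autofluorFraction fraction of compounds with autofluorescence.
#' @param autofluorMean mean autofluorescent signal added to A/B wells.
#' @param nDmso number of DMSO vehicle pseudo-compounds.
#' @param nReplicates replicate wells per role (default quadruplicate).
#' @param muC,muD mean fluorescence of the dye+RNA and dye-alone
#'   controls (arbitrary units).
#' @param concentration screening concentration in uM.
#' @param plateId plate identifier.
#' @return list with `wells` (data.frame: plate_id, well_id, role,
#'   compound_id, concentration_uM, replicate, fluorescence) and
#'   `truth` (compound_id, is_control, is_binder, true_activity,
#'   autofluor).
#' @seealso [screenPlate()], [callHits()]
#' @export
simPlate <- function(seed, nCompounds = 304, binderFraction = 0.18,
                     meanEffect = 40, sdEffect = 8, cv = 0.05,
                     autofluorFraction = 0.05, autofluorMean = 300,
                     nDmso = 8, nReplicates = 4,
                     muC = 1000, muD = 200, concentration = 100,
                     plateId = "P1") {
  seed <- assertSeed(seed)
  assertFraction(binderFraction, "binderFraction")
  assertFraction(autofluorFraction, "autofluorFraction")
  assertNonNegative(cv, "cv")
  if (nCompounds < 1 || nReplicates < 1) stop("need >= 1 compound and replicate")

  withr::with_seed(seed, {
    ids <- sprintf("CMP%04d", seq_len(nCompounds))
    isBinder <- stats::runif(nCompounds) < binderFraction
    effect <- ifelse(isBinder,
                     pmax(0, stats::rnorm(nCompounds, meanEffect, sdEffect)), 0)
    autofl <- stats::runif(nCompounds) < autofluorFraction
    autoSig <- ifelse(autofl, autofluorMean, 0)

    dmsoIds <- if (nDmso > 0) sprintf("DMSO%02d", seq_len(nDmso)) else character()
    allIds <- c(ids, dmsoIds)
    allEffect <- c(effect, rep(0, nDmso))
    allAuto <- c(autoSig, rep(0, nDmso))
    nAll <- length(allIds)

    rep_idx <- rep(seq_len(nReplicates), times = nAll)
    muB <- rep(muD + allAuto, each = nReplicates)
    muA <- muB + (muC - muD) * rep(1 - allEffect / 100, each = nReplicates)

    wells <- rbind(
      data.frame(plate_id = plateId,
                 well_id = sprintf("C_%d", seq_len(nReplicates)),
                 role = "C", compound_id = NA_character_,
                 concentration_uM = 0, replicate = seq_len(nReplicates),
                 fluorescence = muC * rlnormCV(nReplicates, cv),
                 stringsAsFactors = FALSE),
      data.frame(plate_id = plateId,
                 well_id = sprintf("D_%d", seq_len(nReplicates)),
                 role = "D", compound_id = NA_character_,
                 concentration_uM = 0, replicate = seq_len(nReplicates),
                 fluorescence = muD * rlnormCV(nReplicates, cv),
                 stringsAsFactors = FALSE),
      data.frame(plate_id = plateId,
                 well_id = sprintf("A_%s_%d", rep(allIds, each = nReplicates), rep_idx),
                 role = "A", compound_id = rep(allIds, each = nReplicates),
                 concentration_uM = concentration, replicate = rep_idx,
                 fluorescence = muA * rlnormCV(nAll * nReplicates, cv),
                 stringsAsFactors = FALSE),
      data.frame(plate_id = plateId,
                 well_id = sprintf("B_%s_%d", rep(allIds, each = nReplicates), rep_idx),
                 role = "B", compound_id = rep(allIds, each = nReplicates),
                 concentration_uM = concentration, replicate = rep_idx,
                 fluorescence = muB * rlnormCV(nAll * nReplicates, cv),
                 stringsAsFactors = FALSE)
    )
    rownames(wells) <- NULL

    truth <- data.frame(
      compound_id = allIds,
      is_control = c(rep(FALSE, nCompounds), rep(TRUE, nDmso)),
      is_binder = c(isBinder, rep(FALSE, nDmso)),
      true_activity = allEffect,
      autofluor = c(autofl, rep(FALSE, nDmso)),
      stringsAsFactors = FALSE
    )
    list(wells = wells, truth = truth)
  })
}

#' Simulate a four-parameter logistic dose-response series
#'
#' Mean response follows the 4PL curve
#' `bottom + (top - bottom)/(1 + (ec50/x)^hill)`; noise is
#' multiplicative lognormal with coefficient of variation `cv` applied
#' to the response above `bottom` (so `cv = 0` reproduces the closed
#' form exactly).
#'
#' @param seed integer, mandatory.
#' @param doses concentrations in uM (default 8 log-spaced doses
#'   0.5-256 uM spanning the default EC50).
#' @param bottom,top,ec50,hill true 4PL parameters.
#' @param nReplicates replicates per dose.
#' @param cv coefficient of variation of the response noise.
#' @return list with `data` (dose_uM, replicate, response) and `truth`
#'   (bottom, top, ec50, hill).
#' @seealso [fit4PL()]
#' @export
simDoseResponse <- function(seed, doses = NULL, bottom = 0, top = 100,
                            ec50 = 16, hill = 1, nReplicates = 4, cv = 0.05) {
  seed <- assertSeed(seed)
  assertNonNegative(cv, "cv")
  if (is.null(doses))
    doses <- 10^seq(log10(0.5), log10(256), length.out = 8)
  if (any(doses <= 0)) stop("concentrations must be positive")
  if (length(doses) < 4) stop("need at least 4 concentrations")
  if (ec50 <= 0 || hill <= 0) stop("ec50 and hill must be positive")

  withr::with_seed(seed, {
    mu <- bottom + (top - bottom) / (1 + (ec50 / doses)^hill)
    d <- data.frame(
      dose_uM = rep(doses, each = nReplicates),
      replicate = rep(seq_len(nReplicates), times = length(doses)),
      response = NA_real_
    )
    muRep <- rep(mu, each = nReplicates)
    d$response <- bottom + (muRep - bottom) * rlnormCV(nrow(d), cv)
    list(data = d,
         truth = data.frame(bottom = bottom, top = top, ec50 = ec50,
                            hill = hill))
  })
}

#' Simulate a junction-count table for cassette-exon splicing
#'
#' Per event and sample, an inclusion level is drawn beta-binomially
#' around the group PSI (intra-class correlation `rho`); each included
#' transcript contributes two inclusion-junction reads (upstream and
#' downstream of the cassette exon) while each skipped transcript
#' contributes one skipping-junction read, so `incl_counts = 2k` and
#' `skip_counts = depth - k` for `k` included transcripts out of
#' `depth`.  A chosen number of events carries a planted delta-PSI
#' between treated and control groups.
#'
#' @param seed integer, mandatory.
#' @param nEvents number of cassette-exon events.
#' @param nAffected number of events with a planted effect.
#' @param dPsi planted |delta PSI| for affected events.  The direction
#'   is chosen per event to keep PSI in \[0, 1\]; if neither direction
#'   accommodates the full magnitude, the larger feasible move is
#'   planted and the truth table records the achieved shift.
#' @param depth transcripts sampled per event and sample.
#' @param rho beta-binomial intra-class correlation, `0 <= rho < 1`.
#' @param nPerGroup samples per group (treated / control).
#' @param psiRange range of baseline (control) PSI values.
#' @return list with `junctions` (event_id, gene_id, sample_id, group,
#'   incl_counts, skip_counts) and `truth` (event_id, gene_id, affected,
#'   psi_control, psi_treated, true_dpsi).
#' @seealso [computePsi()], [deltaPsiFilter()]
#' @export
simJunctionTable <- function(seed, nEvents = 200, nAffected = 30, dPsi = 0.5,
                             depth = 200, rho = 0.01, nPerGroup = 4,
                             psiRange = c(0.05, 0.9)) {
  seed <- assertSeed(seed)
  if (depth <= 0) stop("depth must be positive")
  if (rho < 0 || rho >= 1) stop("overdispersion 'rho' must be in [0, 1)")
  if (nAffected > nEvents) stop("nAffected cannot exceed nEvents")

  withr::with_seed(seed, {
    eventId <- sprintf("EV%04d", seq_len(nEvents))
    # ~0.7 genes per event: some genes carry two events, as in real
    # transcriptomes, so the gene-level roll-up is exercised
    geneId <- sprintf("G%04d", ceiling(seq_len(nEvents) * 0.7))
    affected <- seq_len(nEvents) <= nAffected
    psiC <- stats::runif(nEvents, psiRange[1], psiRange[2])
    # plant the effect in whichever direction accommodates the larger
    # move, clamped to [0, 1]; true_dpsi records the achieved shift
    upGain <- pmin(1, psiC + dPsi) - psiC
    downGain <- psiC - pmax(0, psiC - dPsi)
    psiT <- ifelse(affected,
                   ifelse(upGain >= downGain, psiC + upGain,
                          psiC - downGain),
                   psiC)

    samples <- c(sprintf("trt_%d", seq_len(nPerGroup)),
                 sprintf("ctl_%d", seq_len(nPerGroup)))
    groups <- rep(c("treated", "control"), each = nPerGroup)

    n <- nEvents * length(samples)
    psiMat <- cbind(matrix(psiT, nEvents, nPerGroup),
                    matrix(psiC, nEvents, nPerGroup))
    k <- rbetabinom(n, depth, as.vector(psiMat), rho)
    junctions <- data.frame(
      event_id = rep(eventId, times = length(samples)),
      gene_id = rep(geneId, times = length(samples)),
      sample_id = rep(samples, each = nEvents),
      group = rep(groups, each = nEvents),
      incl_counts = 2L * k,
      skip_counts = depth - k,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(event_id = eventId, gene_id = geneId,
                        affected = affected, psi_control = psiC,
                        psi_treated = psiT, true_dpsi = psiT - psiC,
                        stringsAsFactors = FALSE)
    list(junctions = junctions, truth = truth)
  })
}

#' Simulate a structural-probe panel correlated with exon inclusion
#'
#' Emulates a panel of hairpin variants whose probe signal (e.g.
#' fluorescent-base emission) tracks exon-inclusion levels with a
#' planted Pearson correlation `rTrue` between the per-variant signal
#' change (percent vs the reference variant) and inclusion.
#'
#' @param seed integer, mandatory.
#' @param variants variant identifiers; the first is the reference.
#' @param inclusion exon-inclusion percentages, one per variant.
#' @param rTrue planted correlation between delta-signal and inclusion.
#' @param deltaScale SD (percent) of the planted signal changes.
#' @param refSignal reference-variant signal (arbitrary units).
#' @param nReplicates replicate measurements per variant.
#' @param cv replicate-level coefficient of variation.
#' @return list with `panel` (variant_id, replicate, probe_signal,
#'   e7_inclusion) and `truth` (variant_id, e7_inclusion, true_delta_pct).
#' @seealso [probeDeltaCorrelation()]
#' @export
simProbePanel <- function(seed,
                          variants = c("n.m.", "2C", "3C", "4G", "6C", "9C"),
                          inclusion = c(16, 10, 40, 30, 62, 50),
                          rTrue = 0.9, deltaScale = 30, refSignal = 100,
                          nReplicates = 8, cv = 0.02) {
  seed <- assertSeed(seed)
  if (length(variants) != length(inclusion))
    stop("variants and inclusion must have the same length")
  if (abs(rTrue) > 1) stop("rTrue must be in [-1, 1]")
  nv <- length(variants)

  withr::with_seed(seed, {
    x <- as.vector(scale(inclusion))
    z <- stats::rnorm(nv)
    z <- as.vector(scale(z - x * sum(x * z) / sum(x * x)))  # orthogonal noise
    delta <- deltaScale * (rTrue * x + sqrt(max(0, 1 - rTrue^2)) * z)
    mu <- refSignal * (1 + delta / 100)
    panel <- data.frame(
      variant_id = rep(variants, each = nReplicates),
      replicate = rep(seq_len(nReplicates), times = nv),
      probe_signal = rep(mu, each = nReplicates) *
        rlnormCV(nv * nReplicates, cv),
      e7_inclusion = rep(inclusion, each = nReplicates),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(variant_id = variants, e7_inclusion = inclusion,
                        true_delta_pct = delta, stringsAsFactors = FALSE)
    list(panel = panel, truth = truth)
  })
}

#' Simulate a circular-dichroism spectrum of a structured RNA
#'
#' Spectrum is the sum of two signed Gaussian bands: a positive band
#' near 265 nm (base stacking) and a negative band near 210 nm
#' (A-form helicity), plus optional Gaussian noise.  Shifting
#' `peakPos` emulates the wavelength shifts that accompany base-stacking
#' rearrangements.
#'
#' @param seed integer, mandatory.
#' @param peakPos,peakNeg band centres in nm.
#' @param ampPos,ampNeg band amplitudes (molar CD units; `ampNeg < 0`).
#' @param widthPos,widthNeg Gaussian SD of each band in nm.
#' @param wavelengths sampling grid in nm.
#' @param noiseSd additive noise SD.
#' @param variant variant label carried through to the output.
#' @return data.frame with columns wavelength_nm, molar_cd, variant.
#' @seealso [cdExtrema()]
#' @export
simCdSpectrum <- function(seed, peakPos = 265, peakNeg = 210,
                          ampPos = 8, ampNeg = -10,
                          widthPos = 14, widthNeg = 9,
                          wavelengths = seq(200, 320, by = 0.5),
                          noiseSd = 0, variant = "n.m.") {
  seed <- assertSeed(seed)
  assertNonNegative(noiseSd, "noiseSd")
  withr::with_seed(seed, {
    v <- ampPos * exp(-(wavelengths - peakPos)^2 / (2 * widthPos^2)) +
         ampNeg * exp(-(wavelengths - peakNeg)^2 / (2 * widthNeg^2)) +
         stats::rnorm(length(wavelengths), 0, noiseSd)
    data.frame(wavelength_nm = wavelengths, molar_cd = v, variant = variant,
               stringsAsFactors = FALSE)
  })
}

#' Simulate inclusion/skipping gel band intensities
#'
#' @param seed integer, mandatory.
#' @param trueInclusion true percent-inclusion values, one per condition.
#' @param conditions condition labels (default cond_1, cond_2, ...).
#' @param total total band intensity per lane (arbitrary units).
#' @param nReplicates lanes per condition.
#' @param cv per-band coefficient of variation (`0` gives exact band
#'   pairs, e.g. inclusion 72 percent gives bands 72 / 28).
#' @return list with `bands` (sample_id, condition, inc_intensity,
#'   skip_intensity) and `truth` (condition, true_inclusion).
#' @seealso [percentInclusion()]
#' @export
simGelBands <- function(seed, trueInclusion = c(16, 72), conditions = NULL,
                        total = 100, nReplicates = 3, cv = 0.05) {
  seed <- assertSeed(seed)
  assertNonNegative(cv, "cv")
  if (any(trueInclusion < 0 | trueInclusion > 100))
    stop("trueInclusion must be percentages in [0, 100]")
  if (is.null(conditions))
    conditions <- sprintf("cond_%d", seq_along(trueInclusion))
  nc <- length(conditions)
  withr::with_seed(seed, {
    inc <- rep(total * trueInclusion / 100, each = nReplicates)
    skp <- rep(total * (100 - trueInclusion) / 100, each = nReplicates)
    bands <- data.frame(
      sample_id = sprintf("%s_r%d", rep(conditions, each = nReplicates),
                          rep(seq_len(nReplicates), times = nc)),
      condition = rep(conditions, each = nReplicates),
      inc_intensity = inc * rlnormCV(nc * nReplicates, cv),
      skip_intensity = skp * rlnormCV(nc * nReplicates, cv),
      stringsAsFactors = FALSE
    )
    list(bands = bands,
         truth = data.frame(condition = conditions,
                            true_inclusion = trueInclusion,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a qPCR Ct table consistent with a stated fold change
#'
#' Generates target and reference-gene Ct values for treated and
#' control samples such that the expected `2^-ddCt` fold change equals
#' `foldChange`.
#'
#' @param seed integer, mandatory.
#' @param foldChange true relative expression (treated vs control,
#'   normalised to the reference gene).
#' @param ctTargetControl,ctRef baseline Ct values (cycles).
#' @param nReplicates replicates per condition.
#' @param noiseSd per-well Ct noise SD in cycles.
#' @return list with `ct` (sample_id, condition, gene, is_reference, ct)
#'   and `truth` (fold_change).
#' @seealso [ddctFold()]
#' @export
simCtTable <- function(seed, foldChange = 4, ctTargetControl = 26,
                       ctRef = 20, nReplicates = 3, noiseSd = 0.05) {
  seed <- assertSeed(seed)
  if (foldChange <= 0) stop("foldChange must be positive")
  assertNonNegative(noiseSd, "noiseSd")
  withr::with_seed(seed, {
    ctTargetTreated <- ctTargetControl - log2(foldChange)
    mk <- function(cond, gene, isRef, mu)
      data.frame(sample_id = sprintf("%s_r%d", cond, seq_len(nReplicates)),
                 condition = cond, gene = gene, is_reference = isRef,
                 ct = mu + stats::rnorm(nReplicates, 0, noiseSd),
                 stringsAsFactors = FALSE)
    ct <- rbind(mk("treated", "target", FALSE, ctTargetTreated),
                mk("treated", "REF", TRUE, ctRef),
                mk("control", "target", FALSE, ctTargetControl),
                mk("control", "REF", TRUE, ctRef))
    list(ct = ct, truth = data.frame(fold_change = foldChange))
  })
}
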