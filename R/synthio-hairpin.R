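# Idealized 19-residue stem-loop geometry and the two-state ensemble
# generator.  The construction is a convention: an A-helix-like stem
# (rise 2.8 A, twist 33 deg per base-pair step) for residues 1-7 paired
# with 19-13, and an arc for loop residues 8-12.  Two reference
# conformations are built: "pentaloop" (loop-closing pair 8-12 open,
# terminus closed) and "triloop" (8-12 closed, terminal pair 1-19
# opened), so the terminal-opening and loop-closing distances are
# anticorrelated across any mixed-state ensemble by construction.

ATOM_MASSES <- c(C = 12.011, N = 14.007, O = 15.999, P = 30.974)

# default sequence: pinned identities at positions 1, 2, 8, 9, 11, 12,
# 15, 18, 19 (terminal pair A1-U19, wobble U2.G18, loop-closing A8-U12,
# triloop A9..U11, G15); remaining positions default to A
defaultHairpinSequence <- function() {
  s <- rep("A", 19)
  s[c(1, 2, 8, 9, 11, 12, 15, 18, 19)] <-
    c("A", "U", "A", "A", "U", "U", "G", "G", "U")
  s
}

# cylindrical placement of one residue's four heavy atoms (P, C1',
# glycosidic N, base C2) given the C1' cylindrical coordinates
placeResidue <- function(theta, radius, z) {
  er <- c(cos(theta), sin(theta), 0)
  et <- c(-sin(theta), cos(theta), 0)
  ez <- c(0, 0, 1)
  c1 <- radius * er + z * ez
  rbind(
    P = c1 + 1.0 * er + 0.5 * et - 1.5 * ez,
    `C1'` = c1,
    N = c1 - 2.5 * er + 0.3 * et,
    C2 = c1 - 4.0 * er + 0.8 * et + 0.3 * ez
  )
}

# reference coordinates (n_atoms x 3) for the pentaloop state, plus the
# atom roster
buildPentaloopReference <- function(sequence, rise = 2.8, twistDeg = 33) {
  twist <- twistDeg * pi / 180
  coords <- vector("list", 19)
  # stem: base pair j couples residue j (5' strand) and 20-j (3' strand)
  for (j in 1:7) {
    th <- (j - 1) * twist
    z <- (j - 1) * rise
    coords[[j]] <- placeResidue(th, 9.0, z)
    coords[[20 - j]] <- placeResidue(th + 154 * pi / 180, 9.0, z)
  }
  # loop residues 8-12 on an arc capping the helix
  loopTheta <- c(231, 262, 295, 328, 359) * pi / 180
  loopR <- c(6.0, 5.0, 4.5, 5.0, 6.0)
  loopZ <- 6 * rise + c(2.2, 3.7, 4.7, 3.7, 2.2)
  for (k in 0:4)
    coords[[8 + k]] <- placeResidue(loopTheta[k + 1], loopR[k + 1],
                                    loopZ[k + 1])
  xyz <- do.call(rbind, coords)
  atoms <- data.frame(
    residue = rep(1:19, each = 4),
    resname = rep(sequence, each = 4),
    atom = rep(c("P", "C1'", "N", "C2"), 19),
    element = rep(c("P", "C", "N", "C"), 19),
    mass = unname(ATOM_MASSES[rep(c("P", "C", "N", "C"), 19)]),
    stringsAsFactors = FALSE
  )
  rownames(xyz) <- NULL
  list(xyz = xyz, atoms = atoms)
}

residueCom <- function(xyz, atoms, res) {
  i <- atoms$residue == res
  w <- atoms$mass[i]
  colSums(xyz[i, , drop = FALSE] * w) / sum(w)
}

# shift all atoms of two residues along their joining axis so their
# centre-of-mass distance changes by `delta` (positive = apart)
shiftPairApart <- function(xyz, atoms, resA, resB, delta) {
  u <- residueCom(xyz, atoms, resB) - residueCom(xyz, atoms, resA)
  u <- u / sqrt(sum(u^2))
  ia <- atoms$residue == resA
  ib <- atoms$residue == resB
  xyz[ia, ] <- sweep(xyz[ia, , drop = FALSE], 2, (delta / 2) * u, `-`)
  xyz[ib, ] <- sweep(xyz[ib, , drop = FALSE], 2, (delta / 2) * u, `+`)
  xyz
}

# the triloop reference: loop-closing pair 8-12 brought to dLoopTri
# (centre of mass), residues 9-11 lifted, terminal pair 1-19 opened by
# terminalOpening Angstrom
buildTriloopReference <- function(ref, dLoopTri = 5.5, terminalOpening = 2,
                                  loopLift = 1.2) {
  xyz <- ref$xyz
  atoms <- ref$atoms
  d0 <- sqrt(sum((residueCom(xyz, atoms, 8) - residueCom(xyz, atoms, 12))^2))
  xyz <- shiftPairApart(xyz, atoms, 8, 12, dLoopTri - d0)
  i911 <- atoms$residue %in% 9:11
  xyz[i911, 3] <- xyz[i911, 3] + loopLift
  shiftPairApart(xyz, atoms, 1, 19, terminalOpening)
}

refDistance <- function(xyz, atoms, resA, resB, mode = "com") {
  if (mode == "com") {
    a <- residueCom(xyz, atoms, resA)
    b <- residueCom(xyz, atoms, resB)
  } else {
    a <- xyz[atoms$residue == resA & atoms$atom == "C1'", ]
    b <- xyz[atoms$residue == resB & atoms$atom == "C1'", ]
  }
  sqrt(sum((a - b)^2))
}

#' Simulate a two-state stem-loop coordinate ensemble
#'
#' Builds an idealized 19-residue hairpin (helical stem, rise 2.8 A,
#' twist 33 deg per base-pair step; four labelled heavy atoms per
#' residue including C1') with two reference conformations:
#' *pentaloop* (loop-closing pair 8-12 open, terminus closed) and
#' *triloop* (pair 8-12 closed, terminal pair 1-19 opened).  Frame
#' states are sampled i.i.d. with probability `pTriloop` of the triloop
#' state, and isotropic Gaussian jitter of SD `sigma` per axis is added
#' to every atom.  Because the two reference states move the terminal
#' (1-19) and loop (8-12) distances in opposite directions, those two
#' observables are anticorrelated across any mixed-state ensemble by
#' construction.
#'
#' @param seed integer, mandatory.
#' @param nFrames number of frames (models).
#' @param pTriloop probability that a frame is in the triloop state.
#' @param sigma per-axis Gaussian coordinate jitter in Angstrom.
#' @param terminalOpening extra terminal 1-19 opening of the triloop
#'   reference relative to the pentaloop reference, in Angstrom.
#' @param dTermShift additional terminal opening applied to *both*
#'   references (use to build "ligand-bound" ensembles with a planted
#'   terminal-opening shift).
#' @param sequence 19 residue names; defaults to the pinned stem-loop
#'   sequence (see Details of the class).
#' @return list with `ensemble` (a [HairpinEnsemble-class]; its
#'   `metadata$reference` stores the reference state geometries and
#'   reference distances) and `truth` (frame, state).
#' @seealso [classifyLoopState()], [residueDistanceSeries()],
#'   [openingShift()]
#' @export
simHairpinEnsemble <- function(seed, nFrames = 40, pTriloop = 0.5,
                               sigma = 0.75, terminalOpening = 2,
                               dTermShift = 0, sequence = NULL) {
  seed <- assertSeed(seed)
  assertFraction(pTriloop, "pTriloop")
  assertNonNegative(sigma, "sigma")
  if (nFrames < 1) stop("nFrames must be >= 1")
  if (is.null(sequence)) sequence <- defaultHairpinSequence()
  if (length(sequence) != 19) stop("sequence must have 19 residues")

  ref <- buildPentaloopReference(sequence)
  pentXyz <- ref$xyz
  triXyz <- buildTriloopReference(ref, terminalOpening = terminalOpening)
  if (dTermShift != 0) {
    pentXyz <- shiftPairApart(pentXyz, ref$atoms, 1, 19, dTermShift)
    triXyz <- shiftPairApart(triXyz, ref$atoms, 1, 19, dTermShift)
  }
  nAtoms <- nrow(pentXyz)

  withr::with_seed(seed, {
    states <- ifelse(stats::runif(nFrames) < pTriloop, "triloop", "pentaloop")
    coords <- array(NA_real_, c(nAtoms, 3, nFrames))
    for (f in seq_len(nFrames)) {
      base <- if (states[f] == "triloop") triXyz else pentXyz
      coords[, , f] <- base + stats::rnorm(nAtoms * 3, 0, sigma)
    }
    refDist <- list(
      d_term_c1 = c(pentaloop = refDistance(pentXyz, ref$atoms, 1, 19, "c1"),
                    triloop = refDistance(triXyz, ref$atoms, 1, 19, "c1")),
      d_loop_com = c(pentaloop = refDistance(pentXyz, ref$atoms, 8, 12, "com"),
                     triloop = refDistance(triXyz, ref$atoms, 8, 12, "com")),
      d_loop_c1 = c(pentaloop = refDistance(pentXyz, ref$atoms, 8, 12, "c1"),
                    triloop = refDistance(triXyz, ref$atoms, 8, 12, "c1"))
    )
    ens <- new("HairpinEnsemble", coords = coords, atoms = ref$atoms,
               metadata = list(reference = list(pentaloop = pentXyz,
                                                triloop = triXyz,
                                                distances = refDist),
                               sigma = sigma, pTriloop = pTriloop))
    list(ensemble = ens,
         truth = data.frame(frame = seq_len(nFrames), state = states,
                            stringsAsFactors = FALSE))
  })
}
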