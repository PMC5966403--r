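# Geometry analytics over stem-loop ensembles: Kabsch superposition,
# pairwise bundle RMSD, RMSF, internal distance observables,
# loop-state classification and terminal-opening shifts.

#' Atom selections for stem-loop analyses
#'
#' `all_heavy` selects every non-hydrogen atom; `stem_heavy` restricts
#' to residues 1-7 and 13-19 (the helical stem); `loop_heavy` to
#' residues 8-12 (the loop).
#'
#' @param ensemble a [HairpinEnsemble-class] object.
#' @param selection one of `"all_heavy"`, `"stem_heavy"`, `"loop_heavy"`.
#' @return logical vector over the atom roster.
#' @export
selectAtoms <- function(ensemble,
                        selection = c("all_heavy", "stem_heavy",
                                      "loop_heavy")) {
  selection <- match.arg(selection)
  a <- ensemble@atoms
  heavy <- toupper(a$element) != "H"
  idx <- switch(selection,
    all_heavy = heavy,
    stem_heavy = heavy & (a$residue <= 7 | a$residue >= 13),
    loop_heavy = heavy & a$residue >= 8 & a$residue <= 12)
  if (!any(idx)) stop("empty atom selection: ", selection)
  idx
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares proper rotation and translation superposing `X` onto
#' `Y` by singular value decomposition of the cross-covariance matrix,
#' with the determinant sign corrected so that no improper rotation
#' (reflection) is ever returned.
#'
#' @param X,Y numeric `n x 3` coordinate matrices with matched rows,
#'   `n >= 3`.
#' @return list with `rotation` (3x3, `det = +1`), `translation`
#'   (length-3 vector such that `X %*% rotation + translation`
#'   superposes onto `Y`), and `rmsd` (Angstrom).
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3)
    stop("X and Y must be matched n x 3 matrices")
  n <- nrow(X)
  if (n < 3) stop("need at least 3 atom pairs")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    warning("near-collinear coordinates: superposition is ill-conditioned")
  s <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  rmsd <- sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  list(rotation = R, translation = as.vector(cy - cx %*% R), rmsd = rmsd)
}

#' Mean pairwise RMSD of an ensemble bundle
#'
#' Every unordered model pair is superposed independently on the
#' selected atoms and the minimised RMSD recorded; the mean and SD
#' over all `N(N-1)/2` pairs is the bundle-precision statistic
#' reported for NMR ensembles.
#'
#' @param ensemble a [HairpinEnsemble-class] object with >= 2 models.
#' @param selection see [selectAtoms()].
#' @return list with `mean`, `sd` (both Angstrom), `n_pairs` and the
#'   per-pair `rmsds`.
#' @export
pairwiseBundleRmsd <- function(ensemble, selection = "all_heavy") {
  idx <- selectAtoms(ensemble, selection)
  nF <- nFrames(ensemble)
  if (nF < 2) stop("need at least 2 models")
  pairs <- utils::combn(nF, 2)
  rmsds <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    kabsch(ensemble@coords[idx, , i], ensemble@coords[idx, , j])$rmsd
  }, numeric(1))
  list(mean = mean(rmsds),
       sd = if (length(rmsds) > 1) stats::sd(rmsds) else 0,
       n_pairs = length(rmsds), rmsds = rmsds)
}

#' Per-residue root-mean-square fluctuation
#'
#' All frames are superposed onto an iteratively refined mean
#' structure (default 3 refinement passes) using the selected atoms;
#' the per-atom RMSF is the root mean squared displacement from the
#' converged mean position, and the per-residue value is the
#' unweighted mean over that residue's selected atoms.
#'
#' @param ensemble a [HairpinEnsemble-class] object with >= 2 frames.
#' @param selection see [selectAtoms()].
#' @param iterations mean-structure refinement passes.
#' @return list with `residue` (data.frame residue, rmsf) and `atom`
#'   (per-atom RMSF, named by residue:atom).
#' @export
rmsfProfile <- function(ensemble, selection = "all_heavy", iterations = 3) {
  idx <- selectAtoms(ensemble, selection)
  nF <- nFrames(ensemble)
  if (nF < 2) stop("need at least 2 frames")
  sub <- ensemble@coords[idx, , , drop = FALSE]
  aligned <- sub
  ref <- sub[, , 1]
  for (it in seq_len(iterations)) {
    for (f in seq_len(nF)) {
      fit <- kabsch(sub[, , f], ref)
      aligned[, , f] <- sweep(sub[, , f] %*% fit$rotation, 2,
                              fit$translation, `+`)
    }
    ref <- rowMeans(aligned, dims = 2)
  }
  disp2 <- sweep(aligned, c(1, 2), ref)^2
  rmsfAtom <- sqrt(rowMeans(disp2[, 1, ] + disp2[, 2, ] + disp2[, 3, ]))
  a <- ensemble@atoms[idx, ]
  names(rmsfAtom) <- paste0(a$residue, ":", a$atom)
  byRes <- tapply(rmsfAtom, a$residue, mean)
  list(residue = data.frame(residue = as.integer(names(byRes)),
                            rmsf = unname(byRes)),
       atom = rmsfAtom)
}

residueCoords <- function(ensemble, res, mode) {
  a <- ensemble@atoms
  if (mode == "c1") {
    i <- which(a$residue == res & a$atom == "C1'")
    if (!length(i))
      stop("residue ", res, " has no C1' atom")
    m <- ensemble@coords[i[1], , , drop = FALSE]
    matrix(m, ncol = nFrames(ensemble))       # 3 x frames
  } else {
    i <- which(a$residue == res & toupper(a$element) != "H")
    if (!length(i)) stop("residue ", res, " has no heavy atoms")
    w <- a$mass[i]
    sub <- ensemble@coords[i, , , drop = FALSE]
    apply(sub, c(2, 3), function(v) sum(v * w) / sum(w))  # 3 x frames
  }
}

#' Per-frame distance between two residues
#'
#' Euclidean distance per frame between the two residues' C1' atoms
#' (`mode = "c1"`) or mass-weighted heavy-atom centres of mass
#' (`mode = "com"`).  No superposition is involved: these are internal
#' coordinates, invariant under rigid motion of each frame.
#'
#' @param ensemble a [HairpinEnsemble-class] object.
#' @param resA,resB residue indices.
#' @param mode `"c1"` or `"com"`.
#' @return list with `distances` (per frame, Angstrom), `mean`, `sd`.
#' @export
residueDistanceSeries <- function(ensemble, resA, resB,
                                  mode = c("c1", "com")) {
  mode <- match.arg(mode)
  pa <- residueCoords(ensemble, resA, mode)
  pb <- residueCoords(ensemble, resB, mode)
  d <- sqrt(colSums((pa - pb)^2))
  list(distances = unname(d), mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else 0)
}

#' Classify per-frame loop state from the loop-closing distance
#'
#' A frame is *triloop* iff the distance between residues 8 and 12
#' (the loop-closing pair) is strictly below `threshold`; otherwise
#' *pentaloop* (a frame exactly at the threshold is pentaloop).  The
#' default threshold is the midpoint of the generator's two reference
#' loop distances when the ensemble carries them, else 7.0 Angstrom —
#' a calibration constant for the centre-of-mass observable.
#'
#' @param ensemble a [HairpinEnsemble-class] object.
#' @param threshold loop-closing distance threshold in Angstrom (> 0).
#' @param mode distance mode, see [residueDistanceSeries()].
#' @param conf confidence level for the binomial CI on the fractions.
#' @return list with `states` (per frame), `fraction_triloop`,
#'   `fraction_pentaloop`, `ci_triloop` (binomial CI), `threshold`.
#' @export
classifyLoopState <- function(ensemble, threshold = NULL, mode = "com",
                              conf = 0.95) {
  if (is.null(threshold)) {
    refs <- ensemble@metadata$reference$distances
    key <- if (identical(mode, "c1")) "d_loop_c1" else "d_loop_com"
    threshold <- if (!is.null(refs[[key]])) mean(refs[[key]]) else 7.0
  }
  if (threshold <= 0) stop("threshold must be positive")
  d <- residueDistanceSeries(ensemble, 8, 12, mode)$distances
  states <- ifelse(d < threshold, "triloop", "pentaloop")
  k <- sum(states == "triloop")
  ci <- stats::binom.test(k, length(states), conf.level = conf)$conf.int
  list(states = states,
       fraction_triloop = k / length(states),
       fraction_pentaloop = 1 - k / length(states),
       ci_triloop = as.vector(ci), threshold = threshold)
}

# moving-block bootstrap means of a series
blockBootMeans <- function(x, blockLength, nBoot) {
  n <- length(x)
  if (n < blockLength)
    stop("fewer frames (", n, ") than one block (", blockLength, ")")
  nBlocks <- ceiling(n / blockLength)
  starts <- seq_len(n - blockLength + 1)
  vapply(seq_len(nBoot), function(b) {
    s <- sample(starts, nBlocks, replace = TRUE)
    idx <- as.vector(outer(0:(blockLength - 1), s, `+`))[seq_len(n)]
    mean(x[idx])
  }, numeric(1))
}

#' Terminal-opening shift between two ensembles
#'
#' Compares the terminal 1-19 C1'-C1' distance (the terminal-opening
#' indicator) between a free and a bound/perturbed ensemble:
#' `delta = mean(d_term | bound) - mean(d_term | free)`, with a
#' moving-block bootstrap confidence interval (frames within a block
#' stay together, respecting serial correlation in trajectories).
#' Also reports the Pearson correlation between the terminal-opening
#' and loop-closing distances within each ensemble.
#'
#' @param free,bound [HairpinEnsemble-class] objects.
#' @param blockLength bootstrap block length in frames (default 50).
#' @param nBoot bootstrap replicates.
#' @param loopMode distance mode for the 8-12 loop observable.
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap resampling.
#' @return list with `delta`, `ci`, `cor_free`, `cor_bound`,
#'   `mean_free`, `mean_bound`.
#' @export
openingShift <- function(free, bound, blockLength = 50, nBoot = 1000,
                         loopMode = "com", conf = 0.95, seed = NULL) {
  dFree <- residueDistanceSeries(free, 1, 19, "c1")$distances
  dBound <- residueDistanceSeries(bound, 1, 19, "c1")$distances
  lFree <- residueDistanceSeries(free, 8, 12, loopMode)$distances
  lBound <- residueDistanceSeries(bound, 8, 12, loopMode)$distances
  run <- function() {
    bF <- blockBootMeans(dFree, blockLength, nBoot)
    bB <- blockBootMeans(dBound, blockLength, nBoot)
    stats::quantile(bB - bF, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  }
  ci <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(delta = mean(dBound) - mean(dFree), ci = ci,
       cor_free = stats::cor(dFree, lFree),
       cor_bound = stats::cor(dBound, lBound),
       mean_free = mean(dFree), mean_bound = mean(dBound))
}
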