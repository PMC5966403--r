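# Independent oracles used to cross-check package computations.

# Horn quaternion superposition: closed-form optimal proper-rotation
# RMSD via the largest eigenvalue of the 4x4 quaternion matrix.
# Algebraically independent of the SVD route used by kabsch().
hornRmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  S <- t(Xc) %*% Yc
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- rbind(
    c(Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx),
    c(Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz),
    c(Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy),
    c(Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz))
  lmax <- max(eigen(N, symmetric = TRUE)$values)
  sqrt(max(0, sum(Xc^2) + sum(Yc^2) - 2 * lmax) / nrow(X))
}

# Brute-force hypergeometric upper tail by complete enumeration of all
# draws (feasible for populations <= 25): probability that a uniform
# draw of nA windows from nTot (of which the first kTot "contain" the
# motif) contains at least kA containing windows.
bruteHyperTail <- function(kA, kTot, nTot, nA) {
  draws <- utils::combn(nTot, nA)
  mean(colSums(draws <= kTot) >= kA)
}

# random proper rotation matrix
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(
    c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
    c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
    c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

# minimal two-residue, one-atom-per-residue ensemble for distance tests
tinyEnsemble <- function(posA, posB, nFrames = 3) {
  coords <- array(NA_real_, c(2, 3, nFrames))
  for (f in seq_len(nFrames)) coords[, , f] <- rbind(posA, posB)
  new("HairpinEnsemble",
      coords = coords,
      atoms = data.frame(residue = 1:2, resname = c("A", "U"),
                         atom = c("C1'", "C1'"), element = c("C", "C"),
                         mass = c(12.011, 12.011),
                         stringsAsFactors = FALSE),
      metadata = list())
}

# apply one rigid motion to every frame of an ensemble
rigidTransform <- function(ens, R, t) {
  co <- ens@coords
  for (f in seq_len(dim(co)[3]))
    co[, , f] <- sweep(co[, , f] %*% R, 2, t, `+`)
  methods::initialize(ens, coords = co)
}
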