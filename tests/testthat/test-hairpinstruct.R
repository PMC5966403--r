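# Ensemble I/O, superposition, RMSD/RMSF, distance observables and
# loop-state classification.

test_that("PDB write/read round-trips at format precision", {
  ens <- simHairpinEnsemble(3, nFrames = 5, sigma = 0.5)$ensemble
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, f)
  back <- readEnsemblePDB(f)
  expect_equal(nFrames(back), 5)
  expect_equal(nResidues(back), 19)
  expect_lt(max(abs(back@coords - ens@coords)), 1e-3)
  expect_equal(atomInfo(back)$atom, atomInfo(ens)$atom)
})

test_that("the reader accepts the star dialect for prime atom names", {
  ens <- simHairpinEnsemble(4, nFrames = 2, sigma = 0.3)$ensemble
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, f)
  txt <- gsub("C1'", "C1*", readLines(f), fixed = TRUE)
  writeLines(txt, f)
  back <- readEnsemblePDB(f)
  expect_true(all(c("C1'") %in% atomInfo(back)$atom))
})

test_that("a missing atom is reported with its model and atom name", {
  ens <- simHairpinEnsemble(5, nFrames = 3, sigma = 0.3)$ensemble
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, f)
  txt <- readLines(f)
  # drop the C1' atom of residue 7 from model 2 only
  modelLines <- which(startsWith(txt, "MODEL"))
  m2 <- modelLines[as.integer(substr(txt[modelLines], 11, 14)) == 2]
  block <- txt[m2:length(txt)]
  victim <- m2 - 1 + which(grepl("C1'", block, fixed = TRUE) &
                             substr(block, 23, 26) == "   7")[1]
  writeLines(txt[-victim], f)
  expect_error(readEnsemblePDB(f), "model 2.*7 C1'")
})

test_that("coordinates agree with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  ens <- simHairpinEnsemble(6, nFrames = 3, sigma = 0.4)$ensemble
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, f)
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(pdb$xyz), 3)
  for (m in 1:3)
    expect_lt(max(abs(matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE) -
                        ens@coords[, , m])), 1e-3)
})

test_that("Kabsch superposition is exact on rigid transforms", {
  withr::with_seed(10, {
    for (i in 1:10) {
      X <- matrix(rnorm(3 * 8), ncol = 3)
      R0 <- randomRotation()
      t0 <- rnorm(3)
      Y <- sweep(X %*% R0, 2, t0, `+`)
      k <- kabsch(X, Y)
      expect_lt(k$rmsd, 1e-9)
      expect_equal(det(k$rotation), 1, tolerance = 1e-9)
      expect_equal(k$rotation, R0, tolerance = 1e-7)
    }
  })
})

test_that("Kabsch refuses reflections and matches the quaternion oracle", {
  withr::with_seed(20, {
    # chiral set vs its mirror image: no proper rotation superposes them
    X <- matrix(rnorm(3 * 6), ncol = 3)
    Xm <- X
    Xm[, 1] <- -Xm[, 1]
    expect_gt(kabsch(X, Xm)$rmsd, 0.1)
    # random pairs: SVD rmsd equals the Horn quaternion rmsd
    for (i in 1:20) {
      A <- matrix(rnorm(3 * 5), ncol = 3)
      B <- matrix(rnorm(3 * 5), ncol = 3)
      expect_equal(kabsch(A, B)$rmsd, hornRmsd(A, B), tolerance = 1e-8)
      expect_equal(kabsch(A, B)$rmsd, kabsch(B, A)$rmsd, tolerance = 1e-10)
    }
  })
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("pairwise bundle RMSD handles degenerate and 2-model bundles", {
  ens <- simHairpinEnsemble(7, nFrames = 4, pTriloop = 1, sigma = 0)$ensemble
  pb <- pairwiseBundleRmsd(ens)
  expect_equal(pb$mean, 0, tolerance = 1e-9)
  expect_equal(pb$sd, 0, tolerance = 1e-9)
  two <- simHairpinEnsemble(8, nFrames = 2, sigma = 0.5)$ensemble
  pb2 <- pairwiseBundleRmsd(two)
  single <- kabsch(two@coords[, , 1], two@coords[, , 2])$rmsd
  expect_equal(pb2$mean, single)
  expect_equal(pb2$sd, 0)
  expect_equal(pb2$n_pairs, 1)
})

test_that("RMSF is zero for a static bundle and higher in the loop", {
  static <- simHairpinEnsemble(9, nFrames = 5, pTriloop = 0, sigma = 0)$ensemble
  r0 <- rmsfProfile(static)
  expect_equal(max(r0$residue$rmsf), 0, tolerance = 1e-9)
  # two-state mixture concentrates motion in the loop
  mixed <- simHairpinEnsemble(10, nFrames = 400, pTriloop = 0.5,
                              sigma = 0.3)$ensemble
  r <- rmsfProfile(mixed)
  loop <- mean(r$residue$rmsf[r$residue$residue %in% 8:12])
  stem <- mean(r$residue$rmsf[r$residue$residue %in% 3:6])
  expect_gt(loop, stem)
})

test_that("isotropic jitter gives RMSF near sigma * sqrt(3)", {
  e <- simHairpinEnsemble(11, nFrames = 3000, pTriloop = 1,
                          sigma = 0.5)$ensemble
  r <- rmsfProfile(e)
  expect_equal(mean(r$atom), 0.5 * sqrt(3), tolerance = 0.04)
})

test_that("distance observables are exact internal coordinates", {
  tiny <- tinyEnsemble(c(0, 0, 0), c(3, 4, 0))
  d <- residueDistanceSeries(tiny, 1, 2, "c1")
  expect_equal(d$distances, rep(5, 3))
  expect_equal(d$sd, 0)
  # centre of mass of a one-atom residue is that atom
  dc <- residueDistanceSeries(tiny, 1, 2, "com")
  expect_equal(dc$distances, rep(5, 3))
  expect_error(residueDistanceSeries(tiny, 1, 3, "c1"), "no C1'")
})

test_that("per-state distances match the generator's references", {
  e <- simHairpinEnsemble(12, nFrames = 600, pTriloop = 0.5, sigma = 0.2)
  refs <- e$ensemble@metadata$reference$distances
  dLoop <- residueDistanceSeries(e$ensemble, 8, 12, "com")$distances
  tri <- e$truth$state == "triloop"
  expect_equal(mean(dLoop[tri]), refs$d_loop_com[["triloop"]],
               tolerance = 0.1)
  expect_equal(mean(dLoop[!tri]), refs$d_loop_com[["pentaloop"]],
               tolerance = 0.1)
})

test_that("loop-state classification recovers the mixture and boundary", {
  e <- simHairpinEnsemble(13, nFrames = 5000, pTriloop = 0.7, sigma = 0.5)
  cls <- classifyLoopState(e$ensemble)
  expect_lt(abs(cls$fraction_triloop - 0.7), 0.05)
  expect_equal(cls$fraction_triloop + cls$fraction_pentaloop, 1)
  expect_true(cls$ci_triloop[1] < 0.7 && 0.7 < cls$ci_triloop[2])
  # a frame exactly at the threshold is pentaloop (strict inequality)
  one <- simHairpinEnsemble(14, nFrames = 1, pTriloop = 1, sigma = 0)
  d <- residueDistanceSeries(one$ensemble, 8, 12, "com")$distances
  expect_equal(classifyLoopState(one$ensemble, threshold = d)$states,
               "pentaloop")
  expect_error(classifyLoopState(one$ensemble, threshold = -1), "positive")
  # fractions are invariant to frame order
  perm <- sample(nFrames(e$ensemble))
  shuffled <- methods::initialize(e$ensemble,
                                  coords = e$ensemble@coords[, , perm])
  expect_equal(classifyLoopState(shuffled)$fraction_triloop,
               cls$fraction_triloop)
})

test_that("all metrics are invariant under a global rigid motion", {
  e <- simHairpinEnsemble(15, nFrames = 30, sigma = 0.5)$ensemble
  withr::with_seed(30, {
    moved <- rigidTransform(e, randomRotation(), rnorm(3, 0, 20))
  })
  expect_equal(pairwiseBundleRmsd(moved)$mean, pairwiseBundleRmsd(e)$mean,
               tolerance = 1e-6)
  expect_equal(rmsfProfile(moved)$residue$rmsf, rmsfProfile(e)$residue$rmsf,
               tolerance = 1e-6)
  expect_equal(residueDistanceSeries(moved, 1, 19, "c1")$distances,
               residueDistanceSeries(e, 1, 19, "c1")$distances,
               tolerance = 1e-6)
})

test_that("terminal-opening shift recovers a planted +2 A construction", {
  free <- simHairpinEnsemble(16, nFrames = 300, sigma = 0.75)$ensemble
  bound <- simHairpinEnsemble(17, nFrames = 300, sigma = 0.75,
                              dTermShift = 2)$ensemble
  os <- openingShift(free, bound, blockLength = 50, seed = 1)
  expect_gt(os$delta, 1.5)
  expect_lt(os$delta, 2.5)
  expect_gt(os$ci[1], 0)            # CI excludes zero
  expect_lt(os$cor_free, 0)         # built-in anticorrelation
  # identical ensembles: no shift, CI covers zero
  os0 <- openingShift(free, free, blockLength = 50, seed = 2)
  expect_equal(os0$delta, 0)
  expect_lte(os0$ci[1], 0)
  expect_gte(os0$ci[2], 0)
  expect_error(openingShift(free, bound, blockLength = 1000),
               "fewer frames")
})
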