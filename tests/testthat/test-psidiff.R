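# PSI computation, delta-PSI filters, the response classifier and
# donor-motif enrichment.

mkJunctions <- function(I, S, group = "treated") {
  data.frame(event_id = "E1", gene_id = "G1",
             sample_id = paste0("s", seq_along(I)), group = group,
             incl_counts = I, skip_counts = S,
             stringsAsFactors = FALSE)
}

test_that("PSI halves the two-junction inclusion count", {
  expect_equal(computePsi(mkJunctions(40, 20))$psi, 0.5)   # I/2 = S
  expect_equal(computePsi(mkJunctions(10, 0))$psi, 1)      # no skipping
  expect_equal(computePsi(mkJunctions(60, 20))$psi, 0.6)
  expect_error(computePsi(mkJunctions(-2, 5)), "non-negative")
  expect_error(computePsi(mkJunctions(1.5, 5)), "integers")
})

test_that("uncovered samples are excluded and empty events dropped", {
  j <- rbind(mkJunctions(c(20, 0), c(10, 0)),
             within(mkJunctions(c(0, 0), c(0, 0)), event_id <- "E2"))
  expect_warning(psi <- computePsi(j), "E2")
  expect_false("E2" %in% psi$event_id)
  expect_equal(sum(is.na(psi$psi)), 1)
})

test_that("delta-PSI thresholds use the absolute-value convention", {
  mk <- function(psiT, psiC) {
    I <- as.integer(round(200 * c(psiT, psiC))) * 2L
    S <- as.integer(200 - round(200 * c(psiT, psiC)))
    data.frame(event_id = "E", gene_id = "G",
               sample_id = c("t1", "c1"), group = c("treated", "control"),
               incl_counts = I, skip_counts = S, stringsAsFactors = FALSE)
  }
  f1 <- deltaPsiFilter(computePsi(mk(0.91, 0.50)))   # dpsi = +0.41
  expect_true(f1$events$modified)
  expect_false(f1$events$strong)
  f2 <- deltaPsiFilter(computePsi(mk(0.10, 0.80)))   # dpsi = -0.70
  expect_true(f2$events$modified)
  expect_true(f2$events$strong)
  expect_error(deltaPsiFilter(computePsi(mk(0.9, 0.5)), t1 = 0), "\\(0, 1\\]")
  expect_error(deltaPsiFilter(computePsi(mk(0.9, 0.5)), t1 = 0.7, t2 = 0.4),
               "t2")
})

test_that("dpsi is antisymmetric and the strong set is nested", {
  j <- simJunctionTable(21, nEvents = 60, nAffected = 20, dPsi = 0.6)
  psi <- computePsi(j$junctions)
  f <- deltaPsiFilter(psi)
  expect_true(all(f$events$event_id[f$events$strong] %in%
                    f$events$event_id[f$events$modified]))
  swapped <- psi
  swapped$group <- ifelse(psi$group == "treated", "control", "treated")
  fs <- deltaPsiFilter(swapped)
  m <- match(f$events$event_id, fs$events$event_id)
  expect_equal(f$events$dpsi, -fs$events$dpsi[m], tolerance = 1e-12)
  expect_gte(f$genes_modified, 1)
  expect_lte(f$genes_modified, f$n_modified)
})

test_that("planted delta-PSI events are detected with high accuracy", {
  j <- simJunctionTable(7, nEvents = 200, nAffected = 30, dPsi = 0.5,
                        depth = 200, rho = 0.01)
  f <- deltaPsiFilter(computePsi(j$junctions))
  called <- f$events$event_id[f$events$modified]
  planted <- j$truth$event_id[j$truth$affected]
  sens <- length(intersect(called, planted)) / length(planted)
  spec <- 1 - length(setdiff(called, planted)) /
    (nrow(j$truth) - length(planted))
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("response classifier reproduces the canonical patterns", {
  mkM <- function(gene, smaT, smaC, wtT, wtC)
    data.frame(gene_id = gene,
               background = rep(c("SMA", "WT"), each = 8),
               condition = rep(rep(c("treated", "control"), each = 4), 2),
               value = c(smaT, smaC, wtT, wtC),
               stringsAsFactors = FALSE)
  up <- c(2.0, 2.1, 1.9, 2.05)
  flat1 <- c(1.0, 1.05, 0.95, 1.0)
  flat2 <- c(1.02, 0.97, 1.01, 1.0)
  m <- rbind(
    mkM("smn_gene", up, flat1, flat2, flat1),        # SMA only
    mkM("off_gene", up, flat1, up + 0.02, flat2),    # both, same direction
    mkM("null_gene", flat2, flat1, flat1, flat2),    # neither
    mkM("wt_gene", flat2, flat1, up, flat1))         # WT only
  cls <- classifySmnDependence(m)
  lab <- setNames(cls$label, cls$gene_id)
  expect_equal(lab[["smn_gene"]], "smn_mediated")
  expect_equal(lab[["off_gene"]], "off_target")
  expect_equal(lab[["null_gene"]], "non_responsive")
  expect_equal(lab[["wt_gene"]], "wt_only")
  expect_error(classifySmnDependence(m[m$condition == "treated", ]),
               "InsufficientData")
})

test_that("classifier type-I rate stays within twice alpha", {
  withr::with_seed(99, {
    n <- 400
    m <- data.frame(
      gene_id = rep(sprintf("g%03d", 1:n), each = 16),
      background = rep(rep(c("SMA", "WT"), each = 8), n),
      condition = rep(rep(rep(c("treated", "control"), each = 4), 2), n),
      value = rnorm(16 * n))
    cls <- classifySmnDependence(m)
  })
  expect_lte(mean(cls$label != "non_responsive"), 0.15)
})

test_that("motif enrichment matches the exact hypergeometric tail", {
  aff <- rep("CAGGTAAGT", 5)
  bg <- rep("ACACACACA", 20)
  res <- motifEnrichment(aff, bg)
  expect_equal(res$p, 1 / choose(25, 5), tolerance = 1e-12)
  expect_equal(res$p, bruteHyperTail(5, 5, 25, 5), tolerance = 1e-12)
  # a partially enriched configuration, still enumerable
  aff2 <- c(rep("CAGGTAAGT", 3), "ACACACACA", "TTTTTTTTT")
  bg2 <- c(rep("CAGGTAAGT", 4), rep("GCGCGCGCG", 16))
  res2 <- motifEnrichment(aff2, bg2)
  expect_equal(res2$p, bruteHyperTail(res2$k_affected,
                                      res2$k_affected + res2$k_background,
                                      25, 5), tolerance = 1e-12)
  # absent motif: p = 1
  expect_equal(motifEnrichment(rep("ACACACACA", 3),
                               rep("TGTGTGTGT", 5))$p, 1)
})

test_that("motif matching honours Hamming distance and IUPAC codes", {
  # the E7 donor GAGTAAG differs from AGGTAAG at two positions
  win <- "AGAGTAAGA"
  expect_equal(motifEnrichment(win, "ACACACACA", maxMismatch = 1)$k_affected,
               0)
  expect_equal(motifEnrichment(win, "ACACACACA", maxMismatch = 2)$k_affected,
               1)
  # IUPAC R matches A and G in the windows
  expect_equal(motifEnrichment(c("CAGGTAAGT", "CAGGTGAGT"), "ACACACACA",
                               motif = "AGGTRAG")$k_affected, 2)
  expect_error(motifEnrichment("CAGGTAAGT", "ACACACA"), "same length")
  expect_error(motifEnrichment("ACGT", "ACGT", motif = "AGGTAAG"),
               "longer")
  expect_error(motifEnrichment("CAGGTAAGT", "ACACACACA", motif = "AG!T"),
               "IUPAC")
})
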