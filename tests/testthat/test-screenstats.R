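# Displacement activity, assay QC, Welch tests, hit calling and 4PL
# fitting.

mkWells <- function(A, B, C, D) {
  n <- length(A)
  rbind(
    data.frame(role = "A", replicate = seq_len(n), fluorescence = A),
    data.frame(role = "B", replicate = seq_len(n), fluorescence = B),
    data.frame(role = "C", replicate = seq_along(C), fluorescence = C),
    data.frame(role = "D", replicate = seq_along(D), fluorescence = D))
}

test_that("displacement activity matches hand-evaluated cases", {
  expect_equal(computeActivity(mkWells(900, 100, 1000, 200))$mean, 0)
  expect_equal(computeActivity(mkWells(100, 100, 1000, 200))$mean, 100)
  expect_equal(computeActivity(mkWells(600, 100, 1000, 200))$mean, 37.5)
  # fluorescence enhancers are reported unclamped
  expect_lt(computeActivity(mkWells(1300, 100, 1000, 200))$mean, 0)
})

test_that("activity is invariant under common rescaling of all wells", {
  set.seed(11)
  for (i in 1:20) {
    A <- runif(4, 300, 900); B <- runif(4, 100, 300)
    C <- runif(4, 900, 1100); D <- runif(4, 150, 250)
    k <- runif(1, 0.1, 10)
    a1 <- computeActivity(mkWells(A, B, C, D))$activities
    a2 <- computeActivity(mkWells(k * A, k * B, k * C, k * D))$activities
    expect_equal(a1, a2, tolerance = 1e-10)
  }
})

test_that("activity computation fails loudly on bad input", {
  w <- mkWells(600, 100, 1000, 200)
  expect_error(computeActivity(w[w$role != "D", ]), "MissingControl")
  # RNA adds no dye signal: C barely above D
  expect_error(computeActivity(mkWells(600, 100, 205, 200)),
               "AssayWindowInvalid")
})

test_that("Z-factor follows the screening-window definition", {
  # zero spread gives the ideal Z of 1
  expect_equal(zFactor(c(100, 100), c(0, 0))$z_factor, 1)
  expect_error(zFactor(c(5, 5, 5), c(5, 5, 5)), "DegenerateControls")
  expect_error(zFactor(100, c(0, 1)), "at least 2")
  # plug-in value at large n: pos ~ N(100,5), neg ~ N(0,5) gives 0.70
  withr::with_seed(101, {
    z <- zFactor(rnorm(1e4, 100, 5), rnorm(1e4, 0, 5))$z_factor
  })
  expect_equal(z, 0.70, tolerance = 0.01)
  # strictly decreasing in control spread, never above 1
  z1 <- zFactor(c(99, 100, 101), c(0, 1, 2))$z_factor
  z2 <- zFactor(c(95, 100, 105), c(-5, 0, 5))$z_factor
  expect_gt(z1, z2)
  expect_lte(z1, 1)
})

test_that("Welch test agrees with the textbook formula and t.test", {
  w <- welchTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.2247, tolerance = 1e-4)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.2878, tolerance = 1e-3)
  # identical groups
  wi <- welchTest(c(5, 6, 7), c(5, 6, 7))
  expect_equal(wi$t, 0)
  expect_equal(wi$p, 1)
  # zero-variance degenerate pair
  expect_equal(welchTest(c(2, 2), c(2, 2))$p, 1)
  expect_error(welchTest(1, c(1, 2)), "InsufficientData")
  # equal variances and equal n: Satterthwaite df = 2n - 2
  set.seed(7)
  x <- rnorm(6); y <- x + 1  # same sample variance by construction
  expect_equal(welchTest(x, y)$df, 10)
})

test_that("hit calling enforces the cutoff, Bonferroni and ordering", {
  acts <- rbind(high = c(50, 52, 48, 51), low = c(19.9, 19.9, 19.9, 19.8),
                mid = c(30, 31, 29, 30))
  dmso <- c(-1, 0.5, 1, -0.5, 0, 0.8, -0.8, 0.2)
  h <- callHits(acts, dmso, cutoff = 20, alpha = 0.05, m = 3)
  expect_equal(h$compound_id, c("high", "mid", "low"))  # ranked
  # sub-cutoff compound is never a hit regardless of p
  expect_false(h$is_hit[h$compound_id == "low"])
  expect_true(all(h$p_adj >= h$p_value))
  expect_equal(h$p_adj, pmin(1, 3 * h$p_value))
  # per-compound p agrees with the scalar Welch test
  w <- welchTest(acts["mid", ], dmso)
  expect_equal(h$p_value[h$compound_id == "mid"], w$p, tolerance = 1e-12)
  # monotone in mean activity: raising a compound keeps it a hit
  acts2 <- acts
  acts2["mid", ] <- acts2["mid", ] + 30
  h2 <- callHits(acts2, dmso, cutoff = 20, alpha = 0.05, m = 3)
  expect_true(h2$is_hit[h2$compound_id == "mid"])
  expect_error(callHits(acts[0, , drop = FALSE], dmso), "empty")
})

test_that("ties in mean activity break lexicographically", {
  acts <- rbind(b = c(30, 30), a = c(30, 30), c = c(40, 40))
  h <- callHits(acts, c(0, 0, 1, -1), m = 3)
  expect_equal(h$compound_id, c("c", "a", "b"))
})

test_that("autofluorescence flag uses a strict relative threshold", {
  expect_false(flagAutofluorescence(c(100, 100), c(100, 100)))
  expect_true(flagAutofluorescence(150, 100))
  expect_false(flagAutofluorescence(120, 100))  # exactly at threshold
  expect_error(flagAutofluorescence(10, 0), "zero")
})

test_that("screenPlate recovers planted binders and flags autofluors", {
  p <- simPlate(1, nCompounds = 80, autofluorFraction = 0.1)
  r <- screenPlate(p$wells)
  flagged <- r$hits$compound_id[r$hits$autofluor_flag]
  truthAuto <- p$truth$compound_id[p$truth$autofluor & !p$truth$is_control]
  expect_setequal(flagged, truthAuto)
  # every called hit is a true binder on this plate
  hits <- r$hits$compound_id[r$hits$is_hit]
  binders <- p$truth$compound_id[p$truth$is_binder]
  expect_true(all(hits %in% binders))
  expect_lte(r$qc$z_factor, 1)
})

test_that("secondary screen rate uses integer rounding", {
  expect_identical(screenRate(8, 19), 42)
  expect_identical(screenRate(54, 304, digits = 1), 17.8)
  expect_error(screenRate(5, 0), "n > 0")
})

test_that("4PL fit recovers noiseless parameters to high precision", {
  x <- rep(c(0.5, 2, 8, 16, 32, 128, 512), each = 2)
  y <- 0 + (100 - 0) / (1 + (16 / x)^1)
  f <- fit4PL(x, y)
  expect_true(f@converged)
  expect_equal(f@bottom, 0, tolerance = 1e-6)
  expect_equal(f@top, 100, tolerance = 1e-6)
  expect_equal(ec50(f), 16, tolerance = 1e-6)
  expect_equal(f@hill, 1, tolerance = 1e-6)
  # midpoint identity on the fitted curve
  yMid <- f@bottom + (f@top - f@bottom) / (1 + (ec50(f) / ec50(f))^f@hill)
  expect_equal(yMid, (f@top + f@bottom) / 2)
})

test_that("4PL fit refuses unsupported inputs", {
  expect_error(fit4PL(c(1, 2, 3), c(1, 2, 3)), "InsufficientDoses")
  expect_error(fit4PL(c(0, 1, 2, 4), c(1, 2, 3, 4)), "positive")
  f <- fit4PL(c(1, 4, 16, 64), rep(50, 4))
  expect_false(f@converged)
  expect_warning(e <- ec50(f), "did not converge")
  expect_true(is.na(e))
})
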