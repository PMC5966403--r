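# Plate-level fluorescence-displacement analytics: per-replicate
# displacement activity, assay-window QC, Welch tests, Bonferroni hit
# calling and autofluorescence flagging.

#' Displacement activity of one compound from its four well roles
#'
#' Computes, per replicate index i,
#' \deqn{activity_i = 100 - \frac{A_i - B_i}{\bar C - \bar D} \times 100}
#' where `A` is dye + RNA + compound, `B` dye + compound, `C` dye + RNA
#' and `D` dye alone.  The compound wells enter per replicate; the
#' assay window `C - D` is the mean over the control replicates, since
#' control wells carry no physical pairing to compound replicates and
#' averaging them keeps control noise out of every per-replicate
#' activity.  The activity is *not* clamped, so fluorescence enhancers
#' yield negative values.  An assay-window guard refuses the
#' computation when the RNA-dependent signal `(C - D)` is not at least
#' `epsilon * D` (unstable ratios).
#'
#' @param wells data.frame with columns `role`, `replicate`,
#'   `fluorescence` for a single compound (roles A and B) plus the
#'   plate controls (roles C and D).
#' @param epsilon assay-window guard on `(mean C - mean D) / mean D`.
#' @return list with `activities` (per-replicate percent), `mean`, `sd`
#'   and `n`.
#' @examples
#' w <- data.frame(role = c("A", "B", "C", "D"), replicate = 1,
#'                 fluorescence = c(600, 100, 1000, 200))
#' computeActivity(w)$mean  # 37.5
#' @seealso [callHits()], [screenPlate()]
#' @export
computeActivity <- function(wells, epsilon = 0.05) {
  need <- c("role", "replicate", "fluorescence")
  if (!all(need %in% names(wells)))
    stop("wells must have columns: ", paste(need, collapse = ", "))
  for (r in c("A", "B", "C", "D"))
    if (!any(wells$role == r))
      stop("MissingControl: no wells with role '", r, "'")
  byRole <- function(r) {
    w <- wells[wells$role == r, ]
    stats::setNames(w$fluorescence, w$replicate)
  }
  A <- byRole("A"); B <- byRole("B"); C <- byRole("C"); D <- byRole("D")
  reps <- intersect(names(A), names(B))
  if (!length(reps))
    stop("MissingControl: no replicate index common to roles A and B")
  window <- mean(C) - mean(D)
  if (window <= epsilon * mean(D))
    stop("AssayWindowInvalid: (C - D) <= ", epsilon, " * D; ",
         "RNA adds no usable dye signal")
  act <- 100 - (A[reps] - B[reps]) / window * 100
  list(activities = unname(act), mean = mean(act),
       sd = if (length(act) > 1) stats::sd(act) else NA_real_,
       n = length(act))
}

#' Screening-window quality coefficient (Z-factor)
#'
#' \deqn{Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|}}
#' with sample standard deviations; the control-based screening-window
#' coefficient.  `Z'` is at most 1 and decreases as control spread
#' grows; values near 0.5-1 indicate a screen-suitable assay.
#'
#' @param pos,neg numeric readings of the positive and negative controls
#'   (at least two each).
#' @return list with `mu_pos`, `mu_neg`, `sigma_pos`, `sigma_neg`,
#'   `z_factor`.
#' @export
zFactor <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 readings per control group")
  muP <- mean(pos); muN <- mean(neg)
  if (muP == muN)
    stop("DegenerateControls: control means are equal; Z-factor undefined")
  z <- 1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(muP - muN)
  list(mu_pos = muP, mu_neg = muN,
       sigma_pos = stats::sd(pos), sigma_neg = stats::sd(neg),
       z_factor = z)
}

#' Two-sample Welch t-test
#'
#' Unequal-variance t-statistic with Satterthwaite degrees of freedom
#' and a two-tailed p-value (wraps [stats::t.test()]).  When both
#' groups have zero variance and equal means, `p = 1` by convention.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welchTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("InsufficientData: each group needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both variances are zero with unequal means; ",
         "Welch statistic undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Flag compound autofluorescence
#'
#' A compound is flagged when its dye + compound wells (role `B`)
#' exceed the dye-alone baseline (role `D`) by more than
#' `relThreshold` in relative terms (strict inequality):
#' `(mean(B) - mean(D)) / mean(D) > relThreshold`.
#'
#' @param bReadings,dReadings numeric fluorescence readings.
#' @param relThreshold relative excess threshold (default 0.2).
#' @return logical flag.
#' @export
flagAutofluorescence <- function(bReadings, dReadings, relThreshold = 0.2) {
  if (!length(bReadings) || !length(dReadings))
    stop("need at least one reading per role")
  mD <- mean(dReadings)
  if (mD == 0) stop("mean dye-alone reading is zero; relative excess undefined")
  (mean(bReadings) - mD) / mD > relThreshold
}

# vectorised Welch test of each row of `mat` (replicate columns)
# against the pooled reference vector `ref`; identical arithmetic to
# stats::t.test(var.equal = FALSE)
welchRows <- function(mat, ref) {
  n1 <- ncol(mat)
  m1 <- rowMeans(mat)
  v1 <- rowSums((mat - m1)^2) / (n1 - 1)
  n0 <- length(ref)
  m0 <- mean(ref)
  v0 <- stats::var(ref)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  t[degenerate] <- 0
  list(t = t, df = df, p = p, mean = m1, sd = sqrt(v1), n = n1)
}

#' Call screening hits with a cutoff and Bonferroni-corrected Welch tests
#'
#' A compound is a hit iff its mean activity exceeds `cutoff` (strict)
#' *and* its Bonferroni-adjusted Welch p-value against the DMSO
#' vehicle-control activities is below `alpha`.  The Bonferroni factor
#' `m` defaults to the number of compounds tested.  The result is
#' sorted by mean activity, descending, ties broken by compound id.
#'
#' @param activities numeric matrix of per-replicate activities, one
#'   row per compound (rownames = compound ids), or a data.frame with
#'   columns `compound_id`, `replicate`, `activity`.
#' @param dmsoActivities numeric vector of vehicle-control activities.
#' @param cutoff minimum mean percent displacement (default 20).
#' @param alpha familywise significance level (default 0.05).
#' @param m Bonferroni factor; default `nrow(activities)`.
#' @return data.frame ranked by mean activity with columns
#'   `compound_id`, `mean_activity`, `sd`, `n`, `t`, `df`, `p_value`,
#'   `p_adj`, `is_hit`.
#' @seealso [screenPlate()] for the full wells-to-hits path.
#' @export
callHits <- function(activities, dmsoActivities, cutoff = 20, alpha = 0.05,
                     m = NULL) {
  if (is.data.frame(activities)) {
    need <- c("compound_id", "replicate", "activity")
    if (!all(need %in% names(activities)))
      stop("activities data.frame needs columns: ",
           paste(need, collapse = ", "))
    wide <- tapply(activities$activity,
                   list(activities$compound_id, activities$replicate),
                   identity)
    activities <- matrix(wide, nrow = nrow(wide),
                         dimnames = dimnames(wide))
  }
  if (!nrow(activities)) stop("empty activity input")
  if (length(dmsoActivities) < 2)
    stop("InsufficientData: need >= 2 DMSO control activities")
  if (is.null(m)) m <- nrow(activities)

  wt <- welchRows(activities, dmsoActivities)
  pAdj <- pmin(1, m * wt$p)
  res <- data.frame(
    compound_id = rownames(activities),
    mean_activity = wt$mean, sd = wt$sd, n = wt$n,
    t = wt$t, df = wt$df, p_value = wt$p, p_adj = pAdj,
    is_hit = wt$mean > cutoff & pAdj < alpha,
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$mean_activity, res$compound_id), ]
  rownames(res) <- NULL
  res
}

#' Full plate analysis: wells to QC, activities and ranked hits
#'
#' Orchestrates the plate-level chain on a wells table as produced by
#' [simPlate()] (or read from `wells.tsv`): checks the assay window,
#' computes per-replicate activities for every compound (the
#' displacement formula of [computeActivity()], vectorised), pools the
#' DMSO pseudo-compound
#' activities as the vehicle reference, flags autofluorescent
#' compounds, computes the control-based Z-factor from the C and D
#' wells, and calls hits.
#'
#' @param wells data.frame with columns `plate_id`, `well_id`, `role`,
#'   `compound_id`, `concentration_uM`, `replicate`, `fluorescence`.
#' @param cutoff,alpha hit-calling parameters, see [callHits()].
#' @param epsilon assay-window guard, see [computeActivity()].
#' @param dmsoPattern regular expression identifying vehicle-control
#'   pseudo-compound ids.
#' @return list with `hits` (ranked data.frame including
#'   `autofluor_flag`), `qc` (Z-factor of the C vs D controls) and
#'   `dmso_activities`.
#' @export
screenPlate <- function(wells, cutoff = 20, alpha = 0.05, epsilon = 0.05,
                        dmsoPattern = "^DMSO") {
  need <- c("role", "compound_id", "replicate", "fluorescence")
  if (!all(need %in% names(wells)))
    stop("wells must have columns: ", paste(need, collapse = ", "))
  if (any(wells$fluorescence < 0)) stop("fluorescence must be >= 0")

  Cw <- wells[wells$role == "C", ]
  Dw <- wells[wells$role == "D", ]
  if (!nrow(Cw) || !nrow(Dw))
    stop("MissingControl: plate must carry C (dye+RNA) and D (dye) wells")
  if (mean(Cw$fluorescence) - mean(Dw$fluorescence) <=
      epsilon * mean(Dw$fluorescence))
    stop("AssayWindowInvalid: (C - D) <= ", epsilon, " * D")
  Cr <- stats::setNames(Cw$fluorescence, Cw$replicate)
  Dr <- stats::setNames(Dw$fluorescence, Dw$replicate)

  ab <- wells[wells$role %in% c("A", "B"), ]
  if (any(is.na(ab$compound_id)))
    stop("A/B wells must carry a compound_id")
  ids <- sort(unique(ab$compound_id))
  reps <- sort(unique(ab$replicate))
  key <- function(role) {
    w <- ab[ab$role == role, ]
    mat <- matrix(NA_real_, length(ids), length(reps),
                  dimnames = list(ids, reps))
    mat[cbind(match(w$compound_id, ids), match(w$replicate, reps))] <-
      w$fluorescence
    mat
  }
  A <- key("A"); B <- key("B")
  if (anyNA(A) || anyNA(B))
    stop("MissingControl: some compounds lack paired A/B replicate wells")
  act <- 100 - (A - B) / (mean(Cr) - mean(Dr)) * 100

  isDmso <- grepl(dmsoPattern, ids)
  if (sum(isDmso) * length(reps) < 2)
    stop("InsufficientData: no DMSO vehicle activities on the plate")
  dmsoAct <- as.vector(act[isDmso, , drop = FALSE])
  hits <- callHits(act[!isDmso, , drop = FALSE], dmsoAct,
                   cutoff = cutoff, alpha = alpha, m = sum(!isDmso))

  mB <- rowMeans(B)
  autofl <- (mB - mean(Dr)) / mean(Dr) > 0.2
  hits$autofluor_flag <- unname(autofl[hits$compound_id])

  qc <- zFactor(Cr, Dr)
  list(hits = hits, qc = qc, dmso_activities = dmsoAct)
}

#' Integer-rounded positive rate of a follow-up screen
#'
#' Reports `k` actives out of `n` tested as a percentage, rounded to
#' `digits` decimals (integer rounding by default, the convention used
#' for secondary-screen summaries).
#'
#' @param k number of actives.
#' @param n number tested.
#' @param digits decimals to round to.
#' @return numeric percentage.
#' @examples
#' screenRate(8, 19)  # 42
#' @export
screenRate <- function(k, n, digits = 0) {
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n with n > 0")
  round(100 * k / n, digits)
}
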