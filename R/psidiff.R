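# Junction-count differential splicing: per-sample PSI, delta-PSI
# filters with gene-level roll-up, the SMN-mediated vs off-target
# response classifier, and splice-donor motif enrichment.

#' Per-sample percent-spliced-in from junction counts
#'
#' For a cassette exon, each included transcript produces two
#' inclusion-junction reads (upstream and downstream) while each
#' skipped transcript produces one skipping-junction read, so the
#' summed inclusion count is halved before normalising:
#' \deqn{PSI = \frac{I/2}{I/2 + S}}
#' Samples with `I + S = 0` get `NA` (excluded from group means);
#' events where every sample is undefined are dropped with a warning.
#'
#' @param junctions data.frame with columns `event_id`, `gene_id`,
#'   `sample_id`, `group`, `incl_counts`, `skip_counts`.
#' @return data.frame of the same rows plus a `psi` column in \[0, 1\]
#'   (undefined-everywhere events removed).
#' @seealso [deltaPsiFilter()]
#' @export
computePsi <- function(junctions) {
  need <- c("event_id", "gene_id", "sample_id", "group",
            "incl_counts", "skip_counts")
  if (!all(need %in% names(junctions)))
    stop("junctions must have columns: ", paste(need, collapse = ", "))
  I <- junctions$incl_counts
  S <- junctions$skip_counts
  if (any(I < 0) || any(S < 0) || any(I != round(I)) || any(S != round(S)))
    stop("junction counts must be non-negative integers")
  psi <- ifelse(I + S > 0, (I / 2) / (I / 2 + S), NA_real_)
  out <- junctions
  out$psi <- psi
  allNA <- tapply(psi, junctions$event_id, function(v) all(is.na(v)))
  if (any(allNA)) {
    dropped <- names(allNA)[allNA]
    warning("dropping ", length(dropped),
            " event(s) with no covered sample: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    out <- out[!out$event_id %in% dropped, ]
  }
  out
}

#' Delta-PSI filtering of cassette-exon events
#'
#' Computes per-event group-mean PSI and
#' `dpsi = mean(treated) - mean(control)`, then flags events with
#' `|dpsi| > t1` as *modified* and `|dpsi| > t2` as *strongly
#' affected* (absolute-value convention: both inclusion-promoting and
#' inclusion-reducing events count).  `t2 >= t1` guarantees the strong
#' set is nested in the modified set.  Gene-level roll-ups count
#' distinct gene ids among flagged events.
#'
#' @param psiTable output of [computePsi()].
#' @param t1,t2 delta-PSI thresholds in (0, 1\] (defaults 0.4, 0.65).
#' @param treatedGroup,controlGroup group labels.
#' @return list with `events` (event_id, gene_id, psi_treated,
#'   psi_control, dpsi, modified, strong), `n_modified`, `n_strong`,
#'   `genes_modified`, `genes_strong`.
#' @export
deltaPsiFilter <- function(psiTable, t1 = 0.4, t2 = 0.65,
                           treatedGroup = "treated",
                           controlGroup = "control") {
  if (t1 <= 0 || t1 > 1 || t2 <= 0 || t2 > 1)
    stop("thresholds must lie in (0, 1]")
  if (t2 < t1) stop("t2 must be >= t1")
  if (!"psi" %in% names(psiTable))
    stop("psiTable must come from computePsi() (needs a 'psi' column)")
  tt <- psiTable[psiTable$group == treatedGroup, ]
  cc <- psiTable[psiTable$group == controlGroup, ]
  if (!nrow(tt) || !nrow(cc))
    stop("need >= 1 sample in each of '", treatedGroup, "' and '",
         controlGroup, "'")
  mT <- tapply(tt$psi, tt$event_id, mean, na.rm = TRUE)
  mC <- tapply(cc$psi, cc$event_id, mean, na.rm = TRUE)
  ev <- intersect(names(mT), names(mC))
  gene <- psiTable$gene_id[match(ev, psiTable$event_id)]
  dpsi <- mT[ev] - mC[ev]
  events <- data.frame(
    event_id = ev, gene_id = gene,
    psi_treated = unname(mT[ev]), psi_control = unname(mC[ev]),
    dpsi = unname(dpsi),
    modified = unname(abs(dpsi) > t1),
    strong = unname(abs(dpsi) > t2),
    stringsAsFactors = FALSE
  )
  rownames(events) <- NULL
  list(events = events,
       n_modified = sum(events$modified),
       n_strong = sum(events$strong),
       genes_modified = length(unique(events$gene_id[events$modified])),
       genes_strong = length(unique(events$gene_id[events$strong])))
}

#' Classify gene responses as SMN-mediated or off-target
#'
#' For each gene, runs a Welch test of treated vs control measurements
#' separately in the SMA and the unaffected (WT) genetic background.
#' The label follows the decision rule: genes responding in SMA but
#' not WT are *smn_mediated* (their change tracks SMN restoration,
#' which only the SMA background lacks); genes responding in both
#' backgrounds with the same direction are *off_target*; responding in
#' WT only is *wt_only*; anything else is *non_responsive*.
#'
#' @param measurements data.frame with columns `gene_id`, `background`
#'   (`"SMA"` / `"WT"`), `condition` (`"treated"` / `"control"`) and
#'   `value`.
#' @param alpha per-test significance level (default 0.05, no
#'   multiplicity correction within the validation panel).
#' @return data.frame with `gene_id`, `sma_p`, `wt_p`, `sma_direction`,
#'   `wt_direction`, `label`.
#' @export
classifySmnDependence <- function(measurements, alpha = 0.05) {
  need <- c("gene_id", "background", "condition", "value")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  genes <- unique(measurements$gene_id)
  one <- function(g) {
    gm <- measurements[measurements$gene_id == g, ]
    test <- function(bg) {
      b <- gm[gm$background == bg, ]
      x <- b$value[b$condition == "treated"]
      y <- b$value[b$condition == "control"]
      if (length(x) < 2 || length(y) < 2)
        stop("InsufficientData: gene ", g, ", background ", bg,
             " needs >= 2 replicates per condition")
      wt <- welchTest(x, y)
      list(p = wt$p, dir = sign(mean(x) - mean(y)))
    }
    sma <- test("SMA"); wt <- test("WT")
    sigS <- sma$p < alpha; sigW <- wt$p < alpha
    label <- if (sigS && !sigW) "smn_mediated"
      else if (sigS && sigW && sma$dir == wt$dir) "off_target"
      else if (!sigS && sigW) "wt_only"
      else "non_responsive"
    data.frame(gene_id = g, sma_p = sma$p, wt_p = wt$p,
               sma_direction = sma$dir, wt_direction = wt$dir,
               label = label, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(genes, one))
  rownames(out) <- NULL
  out
}

#' Splice-donor motif enrichment by hypergeometric test
#'
#' A donor window *contains* the motif iff some offset matches with
#' Hamming distance at most `maxMismatch`; IUPAC ambiguity codes in
#' the motif are honoured (the windows themselves are read literally).
#' Over-representation of containing windows among the affected set
#' versus the pooled affected + background population is scored with a
#' one-sided hypergeometric tail.
#'
#' @param affected,background character vectors (or `DNAStringSet`) of
#'   donor windows, all the same length, DNA alphabet.  The canonical
#'   window is the 9-mer spanning the last 3 exonic and first 6
#'   intronic bases, supplied exon-then-intron on the plus strand.
#' @param motif IUPAC motif string (default the enriched donor motif
#'   `"AGGTAAG"`).
#' @param maxMismatch maximum Hamming distance for a match.
#' @return list with `motif`, `k_affected`, `n_affected`,
#'   `k_background`, `n_background`, `p`.
#' @export
motifEnrichment <- function(affected, background, motif = "AGGTAAG",
                            maxMismatch = 0) {
  toSet <- function(x, what) {
    x <- if (methods::is(x, "DNAStringSet")) x else {
      if (!is.character(x)) stop(what, " must be character or DNAStringSet")
      Biostrings::DNAStringSet(x)
    }
    if (!length(x)) stop(what, " must contain at least one window")
    x
  }
  aff <- toSet(affected, "affected")
  bg <- toSet(background, "background")
  widths <- unique(c(Biostrings::width(aff), Biostrings::width(bg)))
  if (length(widths) != 1)
    stop("all donor windows must have the same length")
  pat <- tryCatch(Biostrings::DNAString(motif),
                  error = function(e) stop("motif contains non-IUPAC characters"))
  if (length(pat) > widths)
    stop("motif is longer than the donor windows")
  contains <- function(set)
    Biostrings::vcountPattern(pat, set, max.mismatch = maxMismatch,
                              fixed = "subject") > 0
  kA <- sum(contains(aff)); nA <- length(aff)
  kB <- sum(contains(bg)); nB <- length(bg)
  kTot <- kA + kB; nTot <- nA + nB
  p <- stats::phyper(kA - 1, kTot, nTot - kTot, nA, lower.tail = FALSE)
  list(motif = motif, k_affected = kA, n_affected = nA,
       k_background = kB, n_background = nB, p = p)
}
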