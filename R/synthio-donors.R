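#' Simulate splice-donor sequence windows with a planted motif
#'
#' Emits 9-mer donor windows (last 3 exonic + first 6 intronic bases,
#' exon-then-intron, plus strand) for an "affected" and a "background"
#' set.  A chosen fraction of the affected windows carries the
#' enriched motif at a random admissible offset; all other positions
#' (and all background windows) are uniform random DNA.
#'
#' @param seed integer, mandatory.
#' @param nAffected,nBackground set sizes.
#' @param motif planted motif (default `"AGGTAAG"`).
#' @param enrichedFraction fraction of affected windows carrying the
#'   motif.
#' @param width window width (default 9).
#' @return list with `affected` and `background`
#'   (`Biostrings::DNAStringSet`) and `truth` (set, window, has_motif).
#' @seealso [motifEnrichment()]
#' @export
simDonorWindows <- function(seed, nAffected = 41, nBackground = 200,
                            motif = "AGGTAAG", enrichedFraction = 0.5,
                            width = 9) {
  seed <- assertSeed(seed)
  assertFraction(enrichedFraction, "enrichedFraction")
  if (nchar(motif) > width) stop("motif is longer than the window")
  withr::with_seed(seed, {
    rnd <- function(n, w)
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
              collapse = ""), character(1))
    planted <- stats::runif(nAffected) < enrichedFraction
    aff <- rnd(nAffected, width)
    slots <- width - nchar(motif) + 1
    for (i in which(planted)) {
      off <- sample.int(slots, 1)
      substr(aff[i], off, off + nchar(motif) - 1) <- motif
    }
    bg <- rnd(nBackground, width)
    affSet <- Biostrings::DNAStringSet(aff)
    names(affSet) <- sprintf("affected_%03d", seq_len(nAffected))
    bgSet <- Biostrings::DNAStringSet(bg)
    names(bgSet) <- sprintf("background_%03d", seq_len(nBackground))
    truth <- data.frame(
      set = c(rep("affected", nAffected), rep("background", nBackground)),
      window = c(aff, bg),
      planted = c(planted, rep(FALSE, nBackground)),
      stringsAsFactors = FALSE
    )
    list(affected = affSet, background = bgSet, truth = truth)
  })
}
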