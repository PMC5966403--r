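# Orchestration: YAML configuration validation and end-to-end runs.
# A single global seed fans out to per-stage sub-seeds by stable
# hashing of stage names, so enabling or disabling one stage never
# changes another stage's random stream.

pipelineDefaults <- function() {
  list(
    seed = 1L,
    outdir = "splicescreen_out",
    stages = c("simulate", "screen", "splicing", "psi", "struct"),
    simulate = list(
      n_compounds = 304L, binder_fraction = 0.18, cv = 0.05,
      n_events = 200L, n_affected = 30L, d_psi = 0.5, depth = 200L,
      rho = 0.01, n_frames = 40L, p_triloop = 0.5, sigma = 0.75,
      n_donor_affected = 41L, n_donor_background = 200L
    ),
    screen = list(cutoff = 20, alpha = 0.05),
    splicing = list(reference_variant = "n.m.", control_condition = "cond_1"),
    psi = list(t1 = 0.4, t2 = 0.65, motif = "AGGTAAG", max_mismatch = 0L),
    struct = list(selection = "all_heavy", loop_mode = "com",
                  threshold = NULL, block_length = 10L),
    inputs = list(wells = NULL, dose = NULL, bands = NULL, ct = NULL,
                  probe = NULL, cd = NULL, cd_reference = NULL,
                  junctions = NULL, donors_affected = NULL,
                  donors_background = NULL, ensemble = NULL,
                  ensemble_bound = NULL)
  )
}

checkNum <- function(x, key, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("config key '", key, "' must be a single number, got: ",
         deparse(x))
  if (x < lo || x > hi)
    stop("config key '", key, "' = ", x, " outside allowed range [",
         lo, ", ", hi, "]")
  x
}

mergeSection <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", section, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) in '", section, "': ",
         paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user, keep.null = TRUE)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent named list), applies
#' documented defaults, rejects unknown keys, checks parameter types
#' and ranges, and verifies that referenced input files exist.
#'
#' @param config path to a YAML file, or a named list.
#' @return the fully resolved configuration list.
#' @seealso [runPipeline()]
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML mapping or a list")
  def <- pipelineDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- def
  for (k in c("seed", "outdir", "stages"))
    if (!is.null(config[[k]])) cfg[[k]] <- config[[k]]
  for (k in c("simulate", "screen", "splicing", "psi", "struct", "inputs"))
    cfg[[k]] <- mergeSection(def[[k]], config[[k]], k)

  checkNum(cfg$seed, "seed")
  if (!is.character(cfg$outdir) || length(cfg$outdir) != 1L)
    stop("config key 'outdir' must be a single path")
  bad <- setdiff(cfg$stages, def$stages)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "))

  checkNum(cfg$screen$cutoff, "screen.cutoff", -100, 100)
  checkNum(cfg$screen$alpha, "screen.alpha", 0, 1)
  checkNum(cfg$psi$t1, "psi.t1", 1e-9, 1)
  checkNum(cfg$psi$t2, "psi.t2", 1e-9, 1)
  if (cfg$psi$t2 < cfg$psi$t1)
    stop("config key 'psi.t2' must be >= 'psi.t1'")
  checkNum(cfg$psi$max_mismatch, "psi.max_mismatch", 0, 5)
  checkNum(cfg$simulate$binder_fraction, "simulate.binder_fraction", 0, 1)
  checkNum(cfg$simulate$p_triloop, "simulate.p_triloop", 0, 1)
  checkNum(cfg$simulate$rho, "simulate.rho", 0, 1 - 1e-12)
  checkNum(cfg$simulate$cv, "simulate.cv", 0, 10)
  checkNum(cfg$simulate$sigma, "simulate.sigma", 0, 100)
  checkNum(cfg$simulate$depth, "simulate.depth", 1, Inf)
  if (!cfg$struct$selection %in% c("all_heavy", "stem_heavy", "loop_heavy"))
    stop("config key 'struct.selection' must be one of ",
         "all_heavy, stem_heavy, loop_heavy")
  if (!cfg$struct$loop_mode %in% c("com", "c1"))
    stop("config key 'struct.loop_mode' must be 'com' or 'c1'")
  for (k in names(cfg$inputs)) {
    f <- cfg$inputs[[k]]
    if (!is.null(f) && !file.exists(f))
      stop("config input '", k, "' refers to a missing file: ", f)
  }
  cfg
}

resolveInput <- function(cfg, key, filename, stage) {
  f <- cfg$inputs[[key]]
  if (is.null(f)) f <- file.path(cfg$outdir, filename)
  if (!file.exists(f))
    stop("stage '", stage, "' needs input '", key, "' but ", f,
         " does not exist (enable the simulate stage or set inputs.",
         key, ")")
  f
}

stageSimulate <- function(cfg) {
  s <- cfg$simulate
  out <- cfg$outdir
  plate <- simPlate(stageSeed(cfg$seed, "simulate.plate"),
                    nCompounds = s$n_compounds,
                    binderFraction = s$binder_fraction, cv = s$cv)
  writeTsv(plate$wells, file.path(out, "wells.tsv"))
  writeTsv(plate$truth, file.path(out, "truth_plate.tsv"))

  dose <- simDoseResponse(stageSeed(cfg$seed, "simulate.dose"), cv = s$cv)
  writeTsv(dose$data, file.path(out, "dose.tsv"))
  writeTsv(dose$truth, file.path(out, "truth_dose.tsv"))

  jt <- simJunctionTable(stageSeed(cfg$seed, "simulate.junctions"),
                         nEvents = s$n_events, nAffected = s$n_affected,
                         dPsi = s$d_psi, depth = s$depth, rho = s$rho)
  writeTsv(jt$junctions, file.path(out, "junctions.tsv"))
  writeTsv(jt$truth, file.path(out, "truth_junctions.tsv"))

  gel <- simGelBands(stageSeed(cfg$seed, "simulate.bands"),
                     trueInclusion = c(16, 72), cv = s$cv)
  writeTsv(gel$bands, file.path(out, "bands.tsv"))
  ct <- simCtTable(stageSeed(cfg$seed, "simulate.ct"))
  writeTsv(ct$ct, file.path(out, "ct.tsv"))
  probe <- simProbePanel(stageSeed(cfg$seed, "simulate.probe"))
  writeTsv(probe$panel, file.path(out, "probe.tsv"))

  cdRef <- simCdSpectrum(stageSeed(cfg$seed, "simulate.cd"), peakPos = 265)
  cdVar <- simCdSpectrum(stageSeed(cfg$seed, "simulate.cd"), peakPos = 269,
                         variant = "shifted")
  writeTsv(cdRef, file.path(out, "cd_reference.tsv"))
  writeTsv(cdVar, file.path(out, "cd.tsv"))

  don <- simDonorWindows(stageSeed(cfg$seed, "simulate.donors"),
                         nAffected = s$n_donor_affected,
                         nBackground = s$n_donor_background,
                         motif = cfg$psi$motif)
  Biostrings::writeXStringSet(don$affected,
                              file.path(out, "donors_affected.fasta"))
  Biostrings::writeXStringSet(don$background,
                              file.path(out, "donors_background.fasta"))

  free <- simHairpinEnsemble(stageSeed(cfg$seed, "simulate.ensemble"),
                             nFrames = s$n_frames,
                             pTriloop = s$p_triloop, sigma = s$sigma)
  bound <- simHairpinEnsemble(stageSeed(cfg$seed, "simulate.ensemble.bound"),
                              nFrames = s$n_frames,
                              pTriloop = s$p_triloop, sigma = s$sigma,
                              dTermShift = 2)
  writeEnsemblePDB(free$ensemble, file.path(out, "ensemble.pdb"))
  writeEnsemblePDB(bound$ensemble, file.path(out, "ensemble_bound.pdb"))
  writeTsv(free$truth, file.path(out, "truth_ensemble.tsv"))
  invisible(NULL)
}

stageScreen <- function(cfg) {
  wells <- readTsv(resolveInput(cfg, "wells", "wells.tsv", "screen"))
  res <- screenPlate(wells, cutoff = cfg$screen$cutoff,
                     alpha = cfg$screen$alpha)
  writeTsv(res$hits, file.path(cfg$outdir, "hits.tsv"))
  writeTsv(data.frame(res$qc), file.path(cfg$outdir, "qc.tsv"))
  doseFile <- cfg$inputs$dose
  if (is.null(doseFile)) doseFile <- file.path(cfg$outdir, "dose.tsv")
  if (file.exists(doseFile)) {
    d <- readTsv(doseFile)
    fit <- fit4PL(d$dose_uM, d$response)
    writeTsv(data.frame(bottom = fit@bottom, top = fit@top,
                        ec50 = fit@ec50, hill = fit@hill,
                        converged = fit@converged),
             file.path(cfg$outdir, "ec50.tsv"))
  }
  res
}

stageSplicing <- function(cfg) {
  out <- cfg$outdir
  bands <- readTsv(resolveInput(cfg, "bands", "bands.tsv", "splicing"))
  bands$percent_inclusion <- percentInclusion(bands$inc_intensity,
                                              bands$skip_intensity)
  incl <- tapply(bands$percent_inclusion, bands$condition, mean)
  ctrl <- cfg$splicing$control_condition
  if (!ctrl %in% names(incl))
    stop("control condition '", ctrl, "' absent from band table")
  splic <- data.frame(condition = names(incl),
                      percent_inclusion = unname(incl),
                      mip_vs_control = mip(unname(incl), incl[[ctrl]]),
                      stringsAsFactors = FALSE)
  writeTsv(splic, file.path(out, "splicing.tsv"))

  ct <- readTsv(resolveInput(cfg, "ct", "ct.tsv", "splicing"))
  mCt <- function(cond, ref) mean(ct$ct[ct$condition == cond &
                                          ct$is_reference == ref])
  fold <- ddctFold(mCt("treated", FALSE), mCt("treated", TRUE),
                   mCt("control", FALSE), mCt("control", TRUE))
  writeTsv(data.frame(fold_change = fold), file.path(out, "fold.tsv"))

  probe <- readTsv(resolveInput(cfg, "probe", "probe.tsv", "splicing"))
  pc <- probeDeltaCorrelation(probe,
                              reference = cfg$splicing$reference_variant)
  writeTsv(pc$deltas, file.path(out, "probe_deltas.tsv"))
  writeTsv(data.frame(r = pc$r, p = pc$p, n = pc$n),
           file.path(out, "probe_correlation.tsv"))

  cd <- readTsv(resolveInput(cfg, "cd", "cd.tsv", "splicing"))
  cdRefFile <- cfg$inputs$cd_reference
  if (is.null(cdRefFile)) cdRefFile <- file.path(out, "cd_reference.tsv")
  cdRef <- if (file.exists(cdRefFile)) readTsv(cdRefFile) else NULL
  ext <- cdExtrema(cd, reference = cdRef)
  writeTsv(data.frame(lambda_max = ext$lambda_max, mag_max = ext$mag_max,
                      lambda_min = ext$lambda_min, mag_min = ext$mag_min,
                      shift_nm = if (is.null(ext$shift_nm)) NA_real_
                                 else ext$shift_nm),
           file.path(out, "cd_extrema.tsv"))
  list(splicing = splic, fold = fold, probe = pc, cd = ext)
}

stagePsi <- function(cfg) {
  out <- cfg$outdir
  junctions <- readTsv(resolveInput(cfg, "junctions", "junctions.tsv", "psi"))
  psiTab <- computePsi(junctions)
  writeTsv(psiTab, file.path(out, "psi.tsv"))
  filt <- deltaPsiFilter(psiTab, t1 = cfg$psi$t1, t2 = cfg$psi$t2)
  writeTsv(filt$events, file.path(out, "dpsi.tsv"))

  affFile <- cfg$inputs$donors_affected
  if (is.null(affFile)) affFile <- file.path(out, "donors_affected.fasta")
  bgFile <- cfg$inputs$donors_background
  if (is.null(bgFile)) bgFile <- file.path(out, "donors_background.fasta")
  motifRes <- NULL
  if (file.exists(affFile) && file.exists(bgFile)) {
    aff <- Biostrings::readDNAStringSet(affFile)
    bg <- Biostrings::readDNAStringSet(bgFile)
    motifRes <- motifEnrichment(aff, bg, motif = cfg$psi$motif,
                                maxMismatch = cfg$psi$max_mismatch)
    writeTsv(data.frame(motif = motifRes$motif,
                        k_affected = motifRes$k_affected,
                        n_affected = motifRes$n_affected,
                        k_background = motifRes$k_background,
                        n_background = motifRes$n_background,
                        p = motifRes$p),
             file.path(out, "motif.tsv"))
  }
  list(filter = filt, motif = motifRes)
}

stageStruct <- function(cfg) {
  out <- cfg$outdir
  ens <- readEnsemblePDB(resolveInput(cfg, "ensemble", "ensemble.pdb",
                                      "struct"))
  dTerm <- residueDistanceSeries(ens, 1, nResidues(ens), "c1")
  dLoop <- residueDistanceSeries(ens, 8, 12, cfg$struct$loop_mode)
  thr <- cfg$struct$threshold
  cls <- classifyLoopState(ens, threshold = thr, mode = cfg$struct$loop_mode)
  writeTsv(data.frame(frame = seq_len(nFrames(ens)),
                      d_term = dTerm$distances, d_loop = dLoop$distances,
                      state = cls$states),
           file.path(out, "metrics.tsv"))
  rp <- rmsfProfile(ens, cfg$struct$selection)
  writeTsv(rp$residue, file.path(out, "rmsf.tsv"))
  stats <- do.call(rbind, lapply(
    c("all_heavy", "stem_heavy", "loop_heavy"),
    function(sel) {
      pb <- pairwiseBundleRmsd(ens, sel)
      data.frame(selection = sel, mean_rmsd = pb$mean, sd_rmsd = pb$sd,
                 n_pairs = pb$n_pairs, stringsAsFactors = FALSE)
    }))
  writeTsv(stats, file.path(out, "bundle_stats.tsv"))

  boundFile <- cfg$inputs$ensemble_bound
  if (is.null(boundFile)) boundFile <- file.path(out, "ensemble_bound.pdb")
  shift <- NULL
  if (file.exists(boundFile)) {
    bound <- readEnsemblePDB(boundFile)
    shift <- openingShift(ens, bound,
                          blockLength = min(cfg$struct$block_length,
                                            nFrames(ens)),
                          loopMode = cfg$struct$loop_mode,
                          seed = stageSeed(cfg$seed, "struct.boot"))
    writeTsv(data.frame(delta = shift$delta, ci_lo = shift$ci[1],
                        ci_hi = shift$ci[2], cor_free = shift$cor_free,
                        cor_bound = shift$cor_bound),
             file.path(out, "opening_shift.tsv"))
  }
  list(classification = cls, bundle = stats, shift = shift)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in the fixed order `simulate` ->
#' `screen` -> `splicing` -> `psi` -> `struct`, writing per-stage TSV
#' tables, a run log with the resolved configuration, and a
#' human-readable summary to the output directory.  Identical
#' configuration and seed reproduce byte-identical tabular outputs.
#' A stage failure aborts the run with an error naming the stage.
#'
#' @param config path to a YAML configuration file or a named list;
#'   see [validateConfig()].
#' @return list of per-stage results, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  runners <- list(simulate = stageSimulate, screen = stageScreen,
                  splicing = stageSplicing, psi = stagePsi,
                  struct = stageStruct)
  order <- intersect(names(runners), cfg$stages)
  for (stage in order) {
    results[[stage]] <- tryCatch(runners[[stage]](cfg),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
  }

  logLines <- c(
    paste("SpliceScreen", as.character(utils::packageVersion("SpliceScreen"))),
    paste("seed:", cfg$seed),
    paste("stages:", paste(order, collapse = ", ")),
    "resolved configuration:",
    strsplit(yaml::as.yaml(cfg), "\n")[[1]]
  )
  writeLines(logLines, file.path(cfg$outdir, "run_log.txt"))

  summary <- c("SpliceScreen pipeline summary", "=============================")
  if (!is.null(results$screen))
    summary <- c(summary,
      sprintf("screen: %d hits of %d compounds (Z-factor %.3f)",
              sum(results$screen$hits$is_hit), nrow(results$screen$hits),
              results$screen$qc$z_factor))
  if (!is.null(results$splicing))
    summary <- c(summary,
      sprintf("splicing: fold change %.3f; probe r = %.3f (p = %.3g); CD shift %.2f nm",
              results$splicing$fold, results$splicing$probe$r,
              results$splicing$probe$p,
              ifelse(is.null(results$splicing$cd$shift_nm), NA,
                     results$splicing$cd$shift_nm)),
      paste0("splicing: %MIP vs control: ",
             paste(sprintf("%s=%.1f", results$splicing$splicing$condition,
                           results$splicing$splicing$mip_vs_control),
                   collapse = ", ")))
  if (!is.null(results$psi)) {
    summary <- c(summary,
      sprintf("psi: %d modified events (|dPSI|>t1) in %d genes; %d strong (|dPSI|>t2)",
              results$psi$filter$n_modified, results$psi$filter$genes_modified,
              results$psi$filter$n_strong))
    if (!is.null(results$psi$motif))
      summary <- c(summary,
        sprintf("psi: motif %s enrichment p = %.3g",
                results$psi$motif$motif, results$psi$motif$p))
  }
  if (!is.null(results$struct)) {
    summary <- c(summary,
      sprintf("struct: triloop fraction %.3f; all-heavy pairwise RMSD %.3f A",
              results$struct$classification$fraction_triloop,
              results$struct$bundle$mean_rmsd[1]))
    if (!is.null(results$struct$shift))
      summary <- c(summary,
        sprintf("struct: terminal opening shift %.2f A [%.2f, %.2f]",
                results$struct$shift$delta, results$struct$shift$ci[1],
                results$struct$shift$ci[2]))
  }
  writeLines(summary, file.path(cfg$outdir, "summary.txt"))
  invisible(results)
}
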