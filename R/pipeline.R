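# End-to-end orchestration: one config drives synthetic generation (or user
# data ingest), quantification, metabolome statistics, proteome statistics
# and cytometry analytics, with per-stage seeding and a JSON run report whose
# counts are recomputable from the written artifacts.

#' Default pipeline configuration
#'
#' One nested list holding every stage constant. The analytical defaults are
#' the screen's: 5 ppm m/z tolerance, 7.5 s apex tolerance inside a 0.5 min
#' search window, blank S/N multiple 3 with floor 10,000, alpha = 0.05; the
#' generator defaults are the screen's study conditions (7 groups; 5 donors
#' for the metabolome and cytometry arms, 4 for the proteome arm; 3 blanks).
#'
#' @param seed Master RNG seed.
#' @return Named nested list; see \code{\link{validatePipelineConfig}}.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    alpha = 0.05,
    posthoc = "dunnett",
    design = list(groups = defaultGroups(), donors_metabolome = 5L,
                  donors_proteome = 4L, donors_cytometry = 5L, blanks = 3L),
    extraction = list(ppm_tol = 5, apex_tol = 7.5, search_window = 30,
                      min_scans = 1L),
    detection = list(sn_multiple = 3, floor = 10000, blank_stat = "mean"),
    metabolome = list(grid = 1, fwhm = 12, base_height = 5e5,
                      noise_cv = 0.05, rt_jitter_sd = 1, mz_jitter_ppm = 1),
    proteome = list(n_proteins = 4857L, n_affected = 400L, effect_sd = 0.5,
                    noise_cv = 0.05, donor_sd = 0.1, missing_rate = 0.01),
    cytometry = list(bins = 256L, g2_low = 1.8, g2_high = 2.2,
                     subg1_sd_mult = 3, unstained_quantile = 0.999,
                     n_events = 20000L, dna_cv = 0.05, g1_mean = 100)
  )
}

#' Validate a pipeline configuration
#'
#' @param config A configuration list
#'   (see \code{\link{defaultPipelineConfig}}).
#' @return Character vector of human-readable violations; empty when valid.
#' @export
validatePipelineConfig <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "alpha must lie in (0, 1)")
  chk(config$posthoc %in% c("dunnett", "holm"),
      "posthoc must be 'dunnett' or 'holm'")
  d <- config$design
  chk(length(d$groups) >= 2 && !anyDuplicated(d$groups),
      "design: >= 2 unique groups required (control first)")
  for (f in c("donors_metabolome", "donors_proteome", "donors_cytometry"))
    chk(is.numeric(d[[f]]) && d[[f]] >= 2, paste0("design: ", f, " must be >= 2"))
  chk(is.numeric(d$blanks) && d$blanks >= 1,
      "design: at least 1 blank run required")
  e <- config$extraction
  for (f in c("ppm_tol", "apex_tol", "search_window"))
    chk(is.numeric(e[[f]]) && e[[f]] > 0, paste0("extraction: ", f, " must be > 0"))
  chk(e$apex_tol <= e$search_window,
      "extraction: apex_tol must not exceed search_window")
  chk(config$detection$sn_multiple > 0, "detection: sn_multiple must be > 0")
  chk(config$detection$floor > 0, "detection: floor must be > 0")
  m <- config$metabolome
  chk(m$grid > 0 && m$grid <= 2, "metabolome: grid must lie in (0, 2] seconds")
  chk(m$noise_cv >= 0 && m$noise_cv <= 0.5,
      "metabolome: noise_cv must lie in [0, 0.5]")
  p <- config$proteome
  chk(p$missing_rate >= 0 && p$missing_rate < 0.5,
      "proteome: missing_rate must lie in [0, 0.5)")
  chk(p$n_affected <= p$n_proteins,
      "proteome: n_affected must not exceed n_proteins")
  cy <- config$cytometry
  chk(cy$g2_low >= 1.5 && cy$g2_high <= 2.5 && cy$g2_low < cy$g2_high,
      "cytometry: G2 window must be an interval inside [1.5, 2.5]")
  chk(cy$n_events >= 1000, "cytometry: n_events must be >= 1000")
  chk(cy$unstained_quantile > 0 && cy$unstained_quantile <= 1,
      "cytometry: unstained_quantile must lie in (0, 1]")
  v
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip through YAML unchanged (up to numeric type).
#'
#' @param config Configuration list.
#' @param path YAML file path.
#' @return \code{writePipelineConfig}: \code{path} invisibly;
#'   \code{readPipelineConfig}: the configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full pipeline
#'
#' Stages run in order (generate/ingest, quantify, metabolome statistics;
#' proteome statistics; cytometry analytics), each stage writing its outputs
#' before the next reads them. With a fixed config and seed, two runs produce
#' byte-identical outputs. In synthetic mode every input is generated from
#' the config; in data mode \code{input} must name the external inputs and a
#' missing path aborts at the stage that needs it.
#'
#' @param config Configuration list (validated first; violations abort).
#' @param outdir Output directory, created if needed.
#' @param synthetic Generate inputs from the config (default) or ingest
#'   \code{input}.
#' @param input Data-mode inputs: list with \code{mzml_dir} (mzML files +
#'   samples.csv), \code{library} (metabolite library CSV),
#'   \code{protein_matrix}, \code{protein_samples}, \code{cytometry_dir}
#'   (dna_events.csv, damage_events.csv, unstained.csv).
#' @return The run report (also written to \code{report.json}), invisibly.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir,
                        synthetic = TRUE, input = NULL) {
  viol <- validatePipelineConfig(config)
  if (length(viol))
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  report <- list(config = config, stages = list())

  ## ---- stage 1: metabolome runs -> intensity matrix --------------------
  met_dir <- file.path(outdir, "metabolome")
  dir.create(met_dir, showWarnings = FALSE)
  if (synthetic) {
    design <- StudyDesign(config$design$groups,
                          donors = config$design$donors_metabolome,
                          blanks = config$design$blanks, seed = seed)
    truth <- defaultMetaboliteTruth(
      base_height = config$metabolome$base_height,
      noise_cv = config$metabolome$noise_cv,
      rt_jitter_sd = config$metabolome$rt_jitter_sd,
      mz_jitter_ppm = config$metabolome$mz_jitter_ppm)
    sim <- simulateMetabolomeRuns(design, truth,
                                  grid = config$metabolome$grid,
                                  fwhm = config$metabolome$fwhm,
                                  floor = config$detection$floor,
                                  ppm_tol = config$extraction$ppm_tol)
    writeRunSet(sim$runs, file.path(met_dir, "mzml"))
    utils::write.csv(sim$truth, file.path(met_dir, "ground_truth.csv"),
                     row.names = FALSE)
    mzml_dir <- file.path(met_dir, "mzml")
    lib <- truth@library
  } else {
    mzml_dir <- input$mzml_dir
    if (is.null(mzml_dir) || !dir.exists(mzml_dir))
      stop("quantify stage: mzML directory missing (input$mzml_dir)")
    if (is.null(input$library) || !file.exists(input$library))
      stop("quantify stage: metabolite library missing (input$library)")
    lib <- utils::read.csv(input$library, stringsAsFactors = FALSE)
  }
  runs <- readRunSet(mzml_dir)
  ex <- config$extraction
  mset <- buildIntensityMatrix(runs, lib,
                               ExtractionConfig(ex$ppm_tol, ex$apex_tol,
                                                ex$search_window,
                                                ex$min_scans))
  thr <- computeThresholds(mset, config$detection$sn_multiple,
                           config$detection$floor,
                           config$detection$blank_stat)
  mset <- applyDetection(mset, thr)
  .writeAssayTsv(mset, "height", file.path(met_dir, "matrix.tsv"))
  .writeAssayTsv(mset, "detected", file.path(met_dir, "mask.tsv"))
  diff_met <- differentialAll(mset, alpha = config$alpha)
  utils::write.csv(diff_met, file.path(met_dir, "differential.csv"),
                   row.names = FALSE)
  ord <- clusterOrder(mset)
  jsonlite::write_json(ord, file.path(met_dir, "cluster_order.json"),
                       auto_unbox = FALSE, digits = NA)
  utils::write.csv(volcanoTable(diff_met), file.path(met_dir, "volcano.csv"),
                   row.names = FALSE)
  det <- SummarizedExperiment::assay(mset, "detected")
  role <- SummarizedExperiment::colData(mset)$role
  report$stages$metabolome <- list(
    analytes = nrow(mset), runs = ncol(mset),
    analytes_detected_any_sample =
      sum(rowSums(det[, role == "sample", drop = FALSE]) > 0),
    significant_calls = sum(diff_met$significant),
    calls_per_group = as.list(tapply(diff_met$significant, diff_met$group,
                                     sum)[unique(diff_met$group)]))

  ## ---- stage 2: proteome -----------------------------------------------
  prot_dir <- file.path(outdir, "proteome")
  dir.create(prot_dir, showWarnings = FALSE)
  if (synthetic) {
    designP <- StudyDesign(config$design$groups,
                           donors = config$design$donors_proteome,
                           blanks = 0, seed = seed)
    pr <- config$proteome
    psim <- simulateProteinMatrix(designP, n_proteins = pr$n_proteins,
                                  n_affected = pr$n_affected,
                                  effect_sd = pr$effect_sd,
                                  noise_cv = pr$noise_cv,
                                  donor_sd = pr$donor_sd,
                                  missing_rate = pr$missing_rate)
    writeProteinMatrix(psim$matrix, file.path(prot_dir, "matrix.tsv"),
                       file.path(prot_dir, "samples.csv"))
    utils::write.csv(psim$truth, file.path(prot_dir, "ground_truth.csv"),
                     row.names = FALSE)
  } else {
    if (is.null(input$protein_matrix) || !file.exists(input$protein_matrix))
      stop("proteome stage: protein matrix missing (input$protein_matrix)")
    file.copy(input$protein_matrix, file.path(prot_dir, "matrix.tsv"))
    file.copy(input$protein_samples, file.path(prot_dir, "samples.csv"))
  }
  pset <- readProteinMatrix(file.path(prot_dir, "matrix.tsv"),
                            file.path(prot_dir, "samples.csv"))
  n_ingested <- nrow(pset)
  pset <- suppressMessages(completeCaseFilter(pset))
  pset <- log2QuantileNormalize(pset)
  .writeMatrixTsv(SummarizedExperiment::assay(pset, "norm"),
                  file.path(prot_dir, "normalized.tsv"))
  qc <- qcReport(pset)
  jsonlite::write_json(
    list(cv_group_median = as.list(qc$cv_group_median),
         r2_min_within_group = .minWithinGroupR2(qc$r2,
           SummarizedExperiment::colData(pset)$group),
         sample_summary = qc$sample_summary),
    file.path(prot_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
  control <- config$design$groups[1L]
  set.seed(deriveSeed(seed, "protstats"))
  an <- anovaPosthoc(pset, control = control, alpha = config$alpha,
                     posthoc = config$posthoc)
  utils::write.csv(an$omnibus, file.path(prot_dir, "anova_omnibus.csv"),
                   row.names = FALSE)
  utils::write.csv(an$posthoc, file.path(prot_dir, "anova_posthoc.csv"),
                   row.names = FALSE)
  pw <- do.call(rbind, lapply(setdiff(config$design$groups, control),
                              function(g)
    pairwiseVsControl(pset, g, control, alpha = config$alpha)))
  utils::write.csv(pw, file.path(prot_dir, "pairwise.csv"),
                   row.names = FALSE)
  report$stages$proteome <- list(
    proteins_ingested = n_ingested, proteins_complete = nrow(pset),
    omnibus_significant = sum(an$omnibus$p_omnibus < config$alpha),
    differential_protein_group_pairs = sum(an$posthoc$differential),
    pairwise_calls_per_group =
      as.list(tapply(pw$called, pw$group, sum)[unique(pw$group)]),
    pairwise_distinct_proteins = length(unique(pw$protein[pw$called])))

  ## ---- stage 3: cytometry ----------------------------------------------
  cyto_dir <- file.path(outdir, "cytometry")
  dir.create(cyto_dir, showWarnings = FALSE)
  cy <- config$cytometry
  if (synthetic) {
    donors <- paste0("D", seq_len(config$design$donors_cytometry))
    dna <- list(); dmg <- list()
    for (g in config$design$groups) for (d in donors) {
      sid <- paste(g, d, sep = "_")
      preset <- cytometryPreset(g, dna_cv = cy$dna_cv,
                                n_events = cy$n_events)
      set.seed(deriveSeed(seed, paste0("dna_", sid)))
      ev <- simulateDnaContent(preset, g1_mean = cy$g1_mean,
                               sample_id = sid, group = g)
      dna[[sid]] <- data.frame(sample_id = sid, group = g, dna = ev$dna)
      set.seed(deriveSeed(seed, paste0("dmg_", sid)))
      ed <- simulateDamageEvents(preset, sample_id = sid, group = g)
      dmg[[sid]] <- data.frame(sample_id = sid, group = g,
                               parp = ed$parp, h2ax = ed$h2ax)
    }
    set.seed(deriveSeed(seed, "unstained"))
    unst <- simulateUnstained(cy$n_events)
    dna_tab <- do.call(rbind, dna); dmg_tab <- do.call(rbind, dmg)
    utils::write.csv(dna_tab, file.path(cyto_dir, "dna_events.csv"),
                     row.names = FALSE)
    utils::write.csv(dmg_tab, file.path(cyto_dir, "damage_events.csv"),
                     row.names = FALSE)
    utils::write.csv(unst, file.path(cyto_dir, "unstained.csv"),
                     row.names = FALSE)
  } else {
    cdir <- input$cytometry_dir
    if (is.null(cdir) || !dir.exists(cdir))
      stop("cytometry stage: event directory missing (input$cytometry_dir)")
    dna_tab <- utils::read.csv(file.path(cdir, "dna_events.csv"))
    dmg_tab <- utils::read.csv(file.path(cdir, "damage_events.csv"))
    unst <- utils::read.csv(file.path(cdir, "unstained.csv"))
  }
  fr <- lapply(split(dna_tab, dna_tab$sample_id), function(tab) {
    fit <- fitDnaContent(tab$dna, bins = cy$bins,
                         g2_window = c(cy$g2_low, cy$g2_high),
                         subg1_sd_mult = cy$subg1_sd_mult)
    data.frame(sample_id = tab$sample_id[1L], group = tab$group[1L],
               t(fractions(fit)), residual = fit@residual,
               stringsAsFactors = FALSE)
  })
  fr <- do.call(rbind, fr[order(names(fr))])
  utils::write.csv(fr, file.path(cyto_dir, "dna_fractions.csv"),
                   row.names = FALSE)
  gates <- deriveThresholds(unst, cy$unstained_quantile)
  qr <- lapply(split(dmg_tab, dmg_tab$sample_id), function(tab) {
    q <- quadrantGate(tab, gates)
    data.frame(sample_id = tab$sample_id[1L], group = tab$group[1L],
               t(quadrantPercentages(q)), stringsAsFactors = FALSE)
  })
  qr <- do.call(rbind, qr[order(names(qr))])
  utils::write.csv(qr, file.path(cyto_dir, "quadrants.csv"),
                   row.names = FALSE)
  control <- config$design$groups[1L]
  set.seed(deriveSeed(seed, "cytostats"))
  fc <- foldChangeVsControl(qr[, c("sample_id", "group", "parp_pos",
                                   "double_pos", "h2ax_pos")],
                            control = control, alpha = config$alpha,
                            posthoc = config$posthoc)
  jsonlite::write_json(
    list(gates = as.list(gates),
         statistics = lapply(fc, function(s)
           list(fold_changes = s$fold_changes, anova_p = s$anova_p,
                posthoc = s$posthoc))),
    file.path(cyto_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  subg1_by_group <- tapply(fr$sub_g1, fr$group, mean)
  report$stages$cytometry <- list(
    samples = nrow(fr),
    subg1_fold_vs_control =
      as.list(subg1_by_group / subg1_by_group[[control]]),
    parp_fold_vs_control =
      as.list(vapply(fc$parp_pos$fold_changes$fold_change, identity,
                     numeric(1)) |>
                stats::setNames(fc$parp_pos$fold_changes$group)))

  ## ---- report ----------------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir, recursive = TRUE),
                          "report.json"))
  report$outputs <- outputs
  report$fingerprint <- as.list(tools::md5sum(file.path(outdir, outputs)) |>
                                  stats::setNames(outputs))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.writeAssayTsv <- function(mset, assay, path) {
  .writeMatrixTsv(SummarizedExperiment::assay(mset, assay), path)
}

.writeMatrixTsv <- function(m, path) {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Smallest squared within-group correlation (QC headline).
.minWithinGroupR2 <- function(r2, groups) {
  vals <- unlist(lapply(unique(groups), function(g) {
    i <- which(groups == g)
    if (length(i) < 2L) return(NULL)
    r2[i, i][upper.tri(r2[i, i])]
  }))
  if (is.null(vals)) NA_real_ else min(vals)
}
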