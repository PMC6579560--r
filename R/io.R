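# Table I/O, configuration and the end-to-end pipeline runner.
#
# TSV schemas (UTF-8, tab-delimited, header row, "." decimal separator):
#   counts:      sample_id + one column per species (non-negative reads)
#   metadata:    sample_id, mouse, day, cohort, stool_mass_g, dilution
#   qpcr:        sample_id, assay, cq, is_calibration, known_copies
#                (calibration rows carry known_copies and no sample_id)
#   metabolites: compound_id, pathway_class, one column per sample

#' Default qPCR standard curve used when emitting synthetic Cq tables
#'
#' Perfect-efficiency curve Cq = 40 - log2(10) * log10(copies).
#' @return a [StandardCurve-class].
#' @export
defaultStandardCurve <- function()
  new("StandardCurve", slope = -log2(10), intercept = 40, r_squared = 1,
      n_points = 5L)

qpcrCq <- function(copies_per_g, curve, stool_mass_g, dilution) {
  copies_rxn <- copies_per_g * stool_mass_g / dilution
  curve@intercept + curve@slope * log10(copies_rxn)
}

calibrationRows <- function(assay, curve, levels = 10^(3:7)) {
  data.frame(sample_id = NA_character_, assay = assay,
             cq = curve@intercept + curve@slope * log10(levels),
             is_calibration = TRUE, known_copies = levels)
}

#' Write an observed dataset as a portable TSV study bundle
#'
#' Serializes a [observeCommunity()] SummarizedExperiment (and optionally
#' a metabolite matrix) into the documented TSV schemas. qPCR totals are
#' encoded as Cq values against the given standard curves, with five
#' calibration points per assay included so the tables are
#' self-contained.
#'
#' @param se \code{SummarizedExperiment} from [observeCommunity()].
#' @param dir output directory (created if needed).
#' @param metabolites optional compounds x samples matrix from
#'   [emitMetabolites()].
#' @param curve universal-16S standard curve.
#' @param phage_curves named list of per-phage curves (default: the
#'   universal curve for each phage assay present).
#' @return invisibly, the vector of files written.
#' @export
writeStudyTables <- function(se, dir, metabolites = NULL,
                             curve = defaultStandardCurve(),
                             phage_curves = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  counts <- t(SummarizedExperiment::assay(se, "counts"))
  counts_df <- data.frame(sample_id = cd$sample_id, counts,
                          check.names = FALSE)
  meta_df <- cd[, c("sample_id", "mouse", "day", "cohort", "stool_mass_g",
                    "dilution")]

  phage_cols <- grep("^phage_.*_per_g$", names(cd), value = TRUE)
  phage_names <- sub("^phage_(.*)_per_g$", "\\1", phage_cols)
  if (is.null(phage_curves))
    phage_curves <- setNames(rep(list(curve), length(phage_names)),
                             phage_names)

  qpcr <- calibrationRows("universal_16S", curve)
  qpcr <- rbind(qpcr, data.frame(
    sample_id = cd$sample_id, assay = "universal_16S",
    cq = qpcrCq(cd$total_16s_per_g, curve, cd$stool_mass_g, cd$dilution),
    is_calibration = FALSE, known_copies = NA_real_))
  for (k in seq_along(phage_names)) {
    pc <- phage_curves[[phage_names[k]]]
    qpcr <- rbind(qpcr, calibrationRows(phage_names[k], pc),
                  data.frame(sample_id = cd$sample_id,
                             assay = phage_names[k],
                             cq = qpcrCq(cd[[phage_cols[k]]], pc,
                                         cd$stool_mass_g, cd$dilution),
                             is_calibration = FALSE,
                             known_copies = NA_real_))
  }

  files <- file.path(dir, c("counts.tsv", "metadata.tsv", "qpcr.tsv"))
  wt <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  wt(counts_df, files[1L]); wt(meta_df, files[2L]); wt(qpcr, files[3L])
  if (!is.null(metabolites)) {
    met_df <- data.frame(
      compound_id = rownames(metabolites),
      pathway_class = attr(metabolites, "pathway_class")[rownames(metabolites)],
      metabolites, check.names = FALSE)
    f <- file.path(dir, "metabolites.tsv")
    wt(met_df, f)
    files <- c(files, f)
  }
  invisible(files)
}

readTsvChecked <- function(path, required, what) {
  if (!file.exists(path)) stopNamed("%s table not found: %s", what, path)
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  missing_c <- setdiff(required, names(df))
  if (length(missing_c))
    stopNamed("%s (%s): missing column(s) %s", what, basename(path),
              paste(missing_c, collapse = ", "))
  df
}

#' Read a TSV study bundle back into a SummarizedExperiment
#'
#' Reads and schema-validates the tables written by [writeStudyTables()]
#' (or prepared externally to the same schemas), enforcing
#' cross-referential integrity (every counts/qPCR sample id must appear in
#' the metadata). Standard curves are refit from the calibration rows of
#' each assay and the Cq values inverted to copies per gram with each
#' sample's own stool mass and dilution.
#'
#' @param dir directory containing \code{counts.tsv}, \code{metadata.tsv},
#'   \code{qpcr.tsv} and optionally \code{metabolites.tsv}.
#' @return list with \code{se} (SummarizedExperiment with assay
#'   \code{counts}, colData metadata, \code{total_16s_per_g} and
#'   \code{phage_*_per_g} columns), \code{metabolites} (matrix or NULL)
#'   and \code{curves} (refit [StandardCurve-class]s by assay).
#' @export
readStudyTables <- function(dir) {
  meta <- readTsvChecked(file.path(dir, "metadata.tsv"),
                         c("sample_id", "mouse", "day", "cohort",
                           "stool_mass_g", "dilution"), "metadata")
  if (any(meta$day < 0))
    stopNamed("metadata (%s): negative decimal day", "metadata.tsv")
  counts_df <- readTsvChecked(file.path(dir, "counts.tsv"), "sample_id",
                              "counts")
  qpcr <- readTsvChecked(file.path(dir, "qpcr.tsv"),
                         c("sample_id", "assay", "cq", "is_calibration",
                           "known_copies"), "qpcr")

  orphan <- setdiff(counts_df$sample_id, meta$sample_id)
  if (length(orphan))
    stopNamed("counts.tsv: sample(s) missing from metadata: %s",
              paste(orphan, collapse = ", "))
  qsamp <- qpcr$sample_id[!qpcr$is_calibration]
  orphan <- setdiff(qsamp, meta$sample_id)
  if (length(orphan))
    stopNamed("qpcr.tsv: sample(s) missing from metadata: %s",
              paste(orphan, collapse = ", "))

  counts <- as.matrix(counts_df[, setdiff(names(counts_df), "sample_id"),
                                drop = FALSE])
  if (any(!is.finite(counts)) || any(counts < 0)) {
    bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)[1L, ]
    stopNamed("counts.tsv: invalid count at row %d, column '%s'",
              bad[1L], colnames(counts)[bad[2L]])
  }
  rownames(counts) <- counts_df$sample_id
  counts <- t(counts[match(meta$sample_id, rownames(counts)), ,
                     drop = FALSE])

  curves <- list()
  for (a in unique(qpcr$assay)) {
    cal <- qpcr[qpcr$assay == a & qpcr$is_calibration, , drop = FALSE]
    if (nrow(cal) < 2L)
      stopNamed("qpcr.tsv: assay '%s' has insufficient calibration rows", a)
    curves[[a]] <- fitStandardCurve(cal$known_copies, cal$cq)
  }
  perG <- function(assay_name) {
    rows <- qpcr[qpcr$assay == assay_name & !qpcr$is_calibration, ,
                 drop = FALSE]
    i <- match(meta$sample_id, rows$sample_id)
    m <- meta$stool_mass_g
    quantifyCopies(rows$cq[i], curves[[assay_name]],
                   dilution_factor = meta$dilution,
                   stool_mass_g = m)
  }
  cd <- S4Vectors::DataFrame(meta)
  if (!"universal_16S" %in% names(curves))
    stopNamed("qpcr.tsv: no universal_16S assay rows")
  cd$total_16s_per_g <- perG("universal_16S")
  for (a in setdiff(names(curves), "universal_16S"))
    cd[[paste0("phage_", a, "_per_g")]] <- perG(a)

  met <- NULL
  met_path <- file.path(dir, "metabolites.tsv")
  if (file.exists(met_path)) {
    met_df <- readTsvChecked(met_path, c("compound_id", "pathway_class"),
                             "metabolites")
    met <- as.matrix(met_df[, setdiff(names(met_df),
                                      c("compound_id", "pathway_class")),
                            drop = FALSE])
    rownames(met) <- met_df$compound_id
    attr(met, "pathway_class") <- setNames(met_df$pathway_class,
                                           met_df$compound_id)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  list(se = se, metabolites = met, curves = curves)
}

pipelineDefaults <- function() {
  list(seed = 1L, scenario = "full", n_mice = 5L,
       include_dropouts = FALSE, metabolites = TRUE,
       observation = list(read_depth = 5e4, qpcr_cv = 0.25,
                          detection_limit = 1e3, stool_mass_mean = 0.05,
                          stool_mass_cv = 0.2, dilution_factor = 100),
       analysis = list(alpha = 0.05, min_weight = 0.1, network_day = 16.1,
                       perturbation_days = c(16.1, 30.1)),
       outdir = NULL)
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys (top-level and nested).
#' @param config named list, or path to a JSON configuration file.
#' @return the completed configuration list.
#' @export
validatePipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- pipelineDefaults()
  config$schema_version <- NULL   # accepted and ignored on input
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stopNamed("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  for (grp in c("observation", "analysis")) {
    bad <- setdiff(names(config[[grp]]), names(defaults[[grp]]))
    if (length(bad))
      stopNamed("unknown %s key(s): %s", grp, paste(bad, collapse = ", "))
    defaults[[grp]][names(config[[grp]])] <- config[[grp]]
  }
  config$observation <- NULL; config$analysis <- NULL
  defaults[names(config)] <- config
  if (!(identical(defaults$scenario, "full") ||
        grepl("^dropout:", defaults$scenario)))
    stopNamed('scenario must be "full" or "dropout:<species>"')
  defaults
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> observe -> write tables -> quantify (estimate +
#' impute) -> perturbation fold changes -> dropout network inference (when
#' \code{include_dropouts}) -> Bray-Curtis stability series -> metabolome
#' differential analysis, writing all outputs plus a run manifest
#' (configuration hash, seed, package version, per-stage row counts) to
#' \code{config$outdir}. Identical configuration and seed give identical
#' numerical outputs. Any stage failure aborts with the stage name after
#' writing a partial manifest.
#'
#' @param config list or JSON path accepted by [validatePipelineConfig()];
#'   \code{outdir} is required.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  cfg <- validatePipelineConfig(config)
  if (is.null(cfg$outdir)) stopNamed("config$outdir is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema_version = "1.0",
                   package_version = as.character(packageVersion("phagedyn")),
                   seed = cfg$seed, config_hash = configHash(cfg),
                   stages = list())
  stage <- function(name, code) {
    res <- tryCatch(force(code), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      writeManifest(manifest, cfg$outdir)
      stopNamed("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    res
  }
  model <- defaultConsortium()
  obs <- do.call(observationSettings,
                 c(cfg$observation, list(seed = cfg$seed)))

  dropped <- if (grepl("^dropout:", cfg$scenario))
    sub("^dropout:", "", cfg$scenario) else NULL
  sc <- if (is.null(dropped)) defaultScenario(model, cfg$n_mice) else
    dropoutScenario(model, dropped, cfg$n_mice)

  traj <- stage("simulate", simulateCommunity(model, sc))
  se <- stage("observe", observeCommunity(traj, model, obs))
  met <- if (cfg$metabolites && is.null(dropped))
    stage("metabolites", emitMetabolites(traj, seed = cfg$seed)) else NULL
  stage("write_tables", writeStudyTables(se, file.path(cfg$outdir, "tables"),
                                         metabolites = met))
  manifest$stages$observe <- list(status = "ok", n_species = nrow(se),
                                  n_samples = ncol(se))

  se <- stage("quantify", imputeNondetects(estimateConcentrations(se)))
  abun <- data.frame(
    sample_id = rep(colnames(se), each = nrow(se)),
    species = rep(rownames(se), ncol(se)),
    est_bacteria_per_g = as.numeric(SummarizedExperiment::assay(se, "concentration")),
    imputed = as.logical(SummarizedExperiment::assay(se, "imputed")))
  write.table(abun, file.path(cfg$outdir, "abundance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$quantify <- list(status = "ok", n_rows = nrow(abun))

  if (is.null(dropped)) {
    fc_all <- stage("foldchange", {
      out <- NULL
      for (pd in cfg$analysis$perturbation_days) {
        fc <- foldChange(se, pd)
        fc$perturbation_day <- pd
        out <- rbind(out, fc)
      }
      out
    })
    write.table(fc_all, file.path(cfg$outdir, "fold_changes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    agg <- aggregateFoldChange(fc_all[fc_all$perturbation_day ==
                                        cfg$analysis$perturbation_days[1L], ])
    write.table(agg, file.path(cfg$outdir, "fold_changes_aggregate.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$foldchange <- list(status = "ok", n_rows = nrow(fc_all))
  }

  if (cfg$include_dropouts && is.null(dropped)) {
    nw <- stage("network", {
      phage_free <- defaultConsortium(list(phages = emptyPhageTable()))
      drops <- list()
      for (omit in unique(phageTable(model)$target)) {
        dsc <- dropoutScenario(model, omit, cfg$n_mice)
        dtraj <- simulateCommunity(phage_free, dsc)
        dse <- observeCommunity(dtraj, model, obs)
        drops[[omit]] <- imputeNondetects(estimateConcentrations(dse))
      }
      inferNetwork(drops, se, day = cfg$analysis$network_day,
                   min_weight = cfg$analysis$min_weight)
    })
    networkToTable(nw, file.path(cfg$outdir, "network_edges.tsv"))
    jsonlite::write_json(networkEdges(nw),
                         file.path(cfg$outdir, "network.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    manifest$stages$network <- list(status = "ok",
                                    n_edges = nrow(networkEdges(nw)))
  } else if (cfg$include_dropouts) {
    message("network stage skipped: a dropout scenario has no ",
            "full-consortium reference")
  }

  stab <- stage("stability", {
    cd <- SummarizedExperiment::colData(se)
    dmice <- do.call(rbind, lapply(unique(cd$day), function(d)
      dissimilarityBetweenMice(se, d)))
    dtime <- do.call(rbind, lapply(unique(cd$mouse), function(m)
      dissimilarityOverTime(se, m)))
    list(dmice = dmice, dtime = dtime)
  })
  write.table(stab$dmice, file.path(cfg$outdir, "dissimilarity_mice.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(stab$dtime, file.path(cfg$outdir, "dissimilarity_time.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$stability <- list(status = "ok",
                                    n_rows = nrow(stab$dmice) +
                                      nrow(stab$dtime))

  if (!is.null(met)) {
    diff_tab <- stage("metabolome", {
      pairing <- metabolitePairing(se, cfg$analysis$perturbation_days[1L],
                                   elapsed = 13)
      fc <- normalizeToReference(met, pairing)
      differentialAbundance(fc, alpha = cfg$analysis$alpha)
    })
    write.table(diff_tab, file.path(cfg$outdir, "metabolome_differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$metabolome <- list(status = "ok",
                                       n_rows = nrow(diff_tab))
  }
  writeManifest(manifest, cfg$outdir)
  invisible(manifest)
}

#' Post/pre sample pairing around a perturbation
#'
#' For each mouse, pairs the sample closest to perturbation_day + elapsed
#' (post) with the reference sample immediately prior to the perturbation
#' (latest sample at or before perturbation_day - 0.5).
#'
#' @param se observed \code{SummarizedExperiment}.
#' @param perturbation_day decimal day of the perturbation.
#' @param elapsed days after the perturbation of the post sample.
#' @param tol matching tolerance for the post sample.
#' @return data.frame \code{post}, \code{pre}, \code{mouse}.
#' @export
metabolitePairing <- function(se, perturbation_day, elapsed = 13,
                              tol = 0.5) {
  cd <- SummarizedExperiment::colData(se)
  out <- NULL
  for (m in unique(cd$mouse)) {
    sel <- which(cd$mouse == m)
    days <- cd$day[sel]
    i_post <- matchDay(days, perturbation_day + elapsed, tol)
    ref_ok <- which(days <= perturbation_day - 0.5 + 1e-9)
    if (is.na(i_post) || !length(ref_ok))
      stopNamed("mouse %s cannot be paired around day %.1f", m,
                perturbation_day)
    i_pre <- ref_ok[which.max(days[ref_ok])]
    out <- rbind(out, data.frame(post = cd$sample_id[sel[i_post]],
                                 pre = cd$sample_id[sel[i_pre]], mouse = m))
  }
  out
}

# hash of the numerically relevant configuration (outdir excluded: it
# cannot affect any computed value)
configHash <- function(cfg) {
  cfg$outdir <- NULL
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg[order(names(cfg))], tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

writeManifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
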