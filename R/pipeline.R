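.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort to TSV files
#'
#' Materializes a generated cohort in the exact formats the analysis stages
#' read: `growth.tsv` (long OD600 table), `ions.tsv` + `samples.tsv`
#' (long ion table and sample sheet), `sites.tsv` (site sheet) and
#' `ground_truth.tsv` (planted truth keyed by site).
#'
#' @param config A `SyntheticCohortConfig` (see [cohortConfig()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeSyntheticCohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gg <- generateGrowthCurves(config)
  ii <- generateIonTable(config)
  paths <- c(growth = file.path(dir, "growth.tsv"),
             ions = file.path(dir, "ions.tsv"),
             samples = file.path(dir, "samples.tsv"),
             sites = file.path(dir, "sites.tsv"),
             truth = file.path(dir, "ground_truth.tsv"))
  .writeTsv(growthCurves(gg$curves), paths["growth"])
  x <- SummarizedExperiment::assay(ii$ions, "intensity")
  rd <- as.data.frame(SummarizedExperiment::rowData(ii$ions))
  cd <- as.data.frame(SummarizedExperiment::colData(ii$ions))
  cd$sample_id <- sprintf("S%04d", seq_len(nrow(cd)))
  long <- data.frame(
    ion_id = rep(rd$ion_id, times = ncol(x)),
    observed_mass = rep(rd$observed_mass, times = ncol(x)),
    sample_id = rep(cd$sample_id, each = nrow(x)),
    intensity = as.vector(x))
  .writeTsv(long, paths["ions"])
  .writeTsv(cd[, c("sample_id", "strain", "condition", "replicate")],
            paths["samples"])
  .writeTsv(siteSheet(config), paths["sites"])
  truth <- do.call(rbind, lapply(names(ii$groundTruth), function(sid) {
    g <- ii$groundTruth[[sid]]
    data.frame(site_id = sid, functional = g$functional,
               sign = ifelse(is.na(g$sign), "", g$sign),
               ko_like_mutant = ifelse(is.na(g$ko_like_mutant), "",
                                       g$ko_like_mutant),
               perturbed = paste(g$perturbed, collapse = ";"))
  }))
  .writeTsv(truth, paths["truth"])
  invisible(paths)
}

#' Default pipeline configuration
#'
#' All thresholds of the screen in one named list: growth significance
#' (`alpha` 0.05, `min_change` 0.10), metabolome significance
#' (`fc_percentile` 95, `q_alpha` 0.05), knockout correlation (`rho_min`
#' 0.4, `rho_p` 0.001) and local-network radius (`local_steps` 5).
#'
#' @param ... Named overrides of any default field.
#' @return Named list.
#' @export
pipelineDefaults <- function(...) {
  cfg <- list(alpha = 0.05, min_change = 0.10, fc_percentile = 95,
              q_alpha = 0.05, rho_min = 0.4, rho_p = 0.001, local_steps = 5,
              wt_strain = "WT", seed = 1L)
  more <- list(...)
  cfg[names(more)] <- more
  cfg
}

.validatePipelineConfig <- function(cfg) {
  need <- c("model_metabolites", "model_reactions", "growth_table",
            "ion_table", "sample_sheet", "site_sheet", "output_dir")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0L) {
    stop("pipeline config validation: missing field(s) ",
         paste(missing, collapse = ", "))
  }
  inRange <- function(x, lo, hi) is.numeric(x) && x > lo && x <= hi
  if (!inRange(cfg$alpha, 0, 1) || !inRange(cfg$q_alpha, 0, 1)) {
    stop("pipeline config validation: alpha/q_alpha must be in (0, 1]")
  }
  if (!inRange(cfg$fc_percentile, 0, 100)) {
    stop("pipeline config validation: fc_percentile must be in (0, 100]")
  }
  if (!is.numeric(cfg$rho_min) || cfg$rho_min < -1 || cfg$rho_min > 1) {
    stop("pipeline config validation: rho_min must be in [-1, 1]")
  }
  if (!inRange(cfg$rho_p, 0, 1)) {
    stop("pipeline config validation: rho_p must be in (0, 1]")
  }
  if (!is.numeric(cfg$min_change) || cfg$min_change < 0) {
    stop("pipeline config validation: min_change must be >= 0")
  }
  if (!is.numeric(cfg$local_steps) || cfg$local_steps < 0) {
    stop("pipeline config validation: local_steps must be >= 0")
  }
  for (f in c("model_metabolites", "model_reactions", "growth_table",
              "ion_table", "sample_sheet", "site_sheet")) {
    if (!file.exists(cfg[[f]])) {
      stop("pipeline config validation: file not found for ", f, ": ",
           cfg[[f]])
    }
  }
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full phosphosite-functionality pipeline
#'
#' Orchestrates model loading, growth-rate fitting and comparison, ion
#' annotation, differential profiles with the data-driven fold-change
#' cutoff, knockout correlations, evidence assembly and functionality
#' calling. All stage outputs are written as TSVs into the configured
#' output directory, together with a text report of the per-site evidence
#' grid and a JSON provenance manifest (package version, config hash,
#' per-stage row counts). The run is a pure function of its inputs and
#' configuration.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Required fields: `model_metabolites`, `model_reactions`,
#'   `growth_table`, `ion_table`, `sample_sheet`, `site_sheet`,
#'   `output_dir`; optional threshold fields default to
#'   [pipelineDefaults()].
#' @return Invisibly, a list with the main in-memory results (`network`,
#'   `growth`, `profiles`, `cutoff`, `correlations`, `evidence`, `calls`,
#'   `summary`, `paths`).
#' @export
runPipeline <- function(config) {
  configPath <- NULL
  if (is.character(config) && length(config) == 1L) {
    configPath <- config
    config <- yaml::read_yaml(config)
  }
  cfg <- pipelineDefaults()
  cfg[names(config)] <- config
  cfg <- .validatePipelineConfig(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  network <- .stage("load_model", {
    loadMetabolicNetwork(cfg$model_metabolites, cfg$model_reactions)
  })
  sites <- .stage("load_sites", {
    s <- read.delim(cfg$site_sheet, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
    need <- c("site_id", "enzyme_id", "mimetic_strain", "abolishing_strain",
              "knockout_strain")
    if (!all(need %in% names(s))) {
      stop("site sheet must have columns: ", paste(need, collapse = ", "))
    }
    s
  })
  growthRes <- .stage("growth", {
    curves <- GrowthCurveSet(read.delim(cfg$growth_table,
                                        stringsAsFactors = FALSE))
    est <- fitGrowthRates(curves)
    cmp <- growthComparisons(est, wtStrain = cfg$wt_strain,
                             alpha = cfg$alpha, minChange = cfg$min_change)
    list(estimates = est, comparisons = cmp)
  })
  ions <- .stage("ion_table", {
    readIonTable(cfg$ion_table, cfg$sample_sheet)
  })
  annotation <- .stage("annotate", annotateIons(ions, network))
  profiles <- .stage("differential", {
    strainProfiles(ions, annotation, wtStrain = cfg$wt_strain)
  })
  cutoff <- .stage("fc_cutoff", {
    globalFcCutoff(profiles, percentile = cfg$fc_percentile)
  })
  profiles <- lapply(profiles, applySignificance, cutoff = cutoff$cutoff,
                     qAlpha = cfg$q_alpha)
  correlations <- .stage("correlations", {
    conds <- unique(vapply(strsplit(names(profiles), "|", fixed = TRUE),
                           `[`, character(1), 2))
    pairs <- do.call(rbind, lapply(conds, function(cond) {
      do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
        ko <- sites$knockout_strain[i]
        if (is.na(ko)) return(NULL)
        muts <- c(sites$mimetic_strain[i], sites$abolishing_strain[i])
        muts <- muts[!is.na(muts)]
        if (length(muts) == 0L) return(NULL)
        data.frame(strain_a = muts, strain_b = ko, condition = cond)
      }))
    }))
    if (is.null(pairs) || nrow(pairs) == 0L) NULL
    else profileCorrelations(profiles, pairs = pairs)
  })
  evidence <- .stage("evidence", {
    assembleEvidence(sites, network, profiles, annotation,
                     growth = growthRes$comparisons,
                     correlations = correlations,
                     localSteps = cfg$local_steps, rhoMin = cfg$rho_min,
                     rhoPMax = cfg$rho_p)
  })
  calls <- .stage("calls", callFunctionality(evidence))
  summaryTab <- summarizeCohort(calls, evidence)

  paths <- c(growth_rates = "growth_rates.tsv",
             growth_comparisons = "growth_comparisons.tsv",
             annotation = "annotation.tsv",
             profiles = "profiles.tsv",
             correlations = "correlations.tsv",
             evidence = "evidence.tsv",
             calls = "calls.tsv",
             summary = "summary.tsv",
             report = "report.txt",
             manifest = "manifest.json")
  paths <- setNames(file.path(cfg$output_dir, paths), names(paths))
  .writeTsv(growthRes$estimates, paths["growth_rates"])
  .writeTsv(growthRes$comparisons, paths["growth_comparisons"])
  annFlat <- annotation
  annFlat$metabolite_ids <- vapply(annotation$metabolite_ids, paste,
                                   character(1), collapse = ";")
  .writeTsv(annFlat, paths["annotation"])
  .writeTsv(do.call(rbind, c(profiles, make.row.names = FALSE)),
            paths["profiles"])
  if (!is.null(correlations)) .writeTsv(correlations, paths["correlations"])
  .writeTsv(evidenceTable(evidence), paths["evidence"])
  .writeTsv(calls, paths["calls"])
  .writeTsv(summaryTab, paths["summary"])

  rpt <- c(
    "Phosphosite functionality report",
    sprintf("sites: %d | functional: %d | growth-evidenced: %d | metabolically evidenced: %d",
            summaryTab$n_sites, summaryTab$n_functional,
            summaryTab$n_growth_phenotype, summaryTab$n_metabolic_evidence),
    sprintf("global-change threshold: %s (2 x median changing metabolites %s)",
            format(summaryTab$global_threshold),
            format(summaryTab$median_n_changing)),
    "",
    sprintf("%-16s %-10s %-28s %-4s %s", "site", "functional",
            "evidence", "sign", "rationale"),
    sprintf("%-16s %-10s %-28s %-4s %s", calls$site_id, calls$functional,
            calls$evidence_classes, calls$sign, calls$rationale))
  writeLines(rpt, paths["report"])

  manifest <- list(
    package = "PhosphoScreen",
    version = as.character(packageVersion("PhosphoScreen")),
    r_version = as.character(getRversion()),
    config = cfg[setdiff(names(cfg), "output_dir")],
    config_hash = if (is.null(configPath)) NA else
      unname(tools::md5sum(configPath)),
    seed = cfg$seed,
    rows = list(
      growth_rates = nrow(growthRes$estimates),
      growth_comparisons = nrow(growthRes$comparisons),
      ions = nrow(annotation),
      profiles = sum(vapply(profiles, nrow, integer(1))),
      correlations = if (is.null(correlations)) 0L else nrow(correlations),
      evidence = nrow(evidenceTable(evidence)),
      calls = nrow(calls)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(network = network, growth = growthRes,
                 annotation = annotation, profiles = profiles,
                 cutoff = cutoff, correlations = correlations,
                 evidence = evidence, calls = calls, summary = summaryTab,
                 paths = paths))
}
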