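#' Annotate ions to metabolites by accurate deprotonated-ion mass
#'
#' An ion matches a metabolite when the ion's observed mass is within
#' `tolerance` of the metabolite's deprotonated ion mass (neutral
#' monoisotopic mass minus one proton mass, 1.007276 Da). All matches are
#' kept, so isobaric metabolites (identical formulas) yield multi-metabolite
#' annotation sets. Unmatched ions are retained and flagged unannotated.
#'
#' @param ions An [IonSet-class] (or a data.frame with `ion_id` and
#'   `observed_mass` columns).
#' @param network A [MetabolicNetwork-class] whose metabolites carry masses.
#' @param tolerance Mass tolerance in Da (default 0.001).
#' @return data.frame with columns `ion_id`, `observed_mass`, `annotated`
#'   and list-column `metabolite_ids`; attribute `tolerance`.
#' @export
annotateIons <- function(ions, network, tolerance = 0.001) {
  if (is(ions, "IonSet")) {
    rd <- as.data.frame(SummarizedExperiment::rowData(ions))
  } else {
    rd <- as.data.frame(ions)
  }
  stopifnot(all(c("ion_id", "observed_mass") %in% names(rd)))
  met <- metaboliteTable(network)
  target <- deprotonatedMass(met$monoisotopic_mass)
  ord <- order(target)
  sortedTarget <- target[ord]
  sortedIds <- met$metabolite_id[ord]
  # epsilon keeps an ion at exactly the tolerance inside the match window
  eps <- 1e-9
  sets <- lapply(rd$observed_mass, function(m) {
    lo <- findInterval(m - tolerance - eps, sortedTarget) + 1L
    hi <- findInterval(m + tolerance + eps, sortedTarget)
    if (hi < lo) character(0) else {
      hits <- lo:hi
      hits <- hits[abs(sortedTarget[hits] - m) <= tolerance + eps]
      sortedIds[hits]
    }
  })
  out <- data.frame(ion_id = rd$ion_id, observed_mass = rd$observed_mass)
  out$metabolite_ids <- sets
  out$annotated <- lengths(sets) > 0L
  attr(out, "tolerance") <- tolerance
  out
}

#' Differential ion abundance for one mutant vs the wild type
#'
#' For every ion, replicate intensities of the mutant are pooled and compared
#' to the pooled wild-type intensities: the log2 fold change is the log2
#' ratio of group means on the linear intensity scale, and a two-sided Welch
#' t-test is run on log2-transformed replicate intensities (variance
#' stabilization; set `testOnLog = FALSE` for the linear scale). p-values are
#' corrected by the Benjamini-Hochberg step-up over all annotated,
#' non-excluded ions of this profile. Ions with a zero group mean have an
#' undefined fold change and are flagged excluded.
#'
#' @param ions An [IonSet-class].
#' @param annotation Annotation table from [annotateIons()].
#' @param mutantStrain,wtStrain Strain labels in `colData(ions)$strain`.
#' @param condition Condition label; only samples of this condition are used.
#' @param testOnLog Run the Welch test on log2 intensities (default TRUE).
#' @return data.frame (one row per ion) with `strain`, `condition`,
#'   `ion_id`, `annotated`, `log2_fc`, `p_value`, `q_value`, `excluded`.
#' @export
differentialAbundance <- function(ions, annotation, mutantStrain, wtStrain,
                                  condition, testOnLog = TRUE) {
  cd <- SummarizedExperiment::colData(ions)
  mCols <- cd$strain == mutantStrain & cd$condition == condition
  wCols <- cd$strain == wtStrain & cd$condition == condition
  if (sum(mCols) < 2L || sum(wCols) < 2L) {
    stop("need >= 2 replicates per group (", mutantStrain, " vs ", wtStrain,
         ", ", condition, ")")
  }
  x <- SummarizedExperiment::assay(ions, "intensity")
  mm <- x[, mCols, drop = FALSE]
  ww <- x[, wCols, drop = FALSE]
  mMean <- rowMeans(mm)
  wMean <- rowMeans(ww)
  excluded <- mMean == 0 | wMean == 0
  log2fc <- ifelse(excluded, NA_real_, log2(mMean / wMean))
  eps <- min(x[x > 0], 1) * 1e-6  # guards log2(0) in all-zero replicates
  wres <- if (testOnLog) {
    .rowWelch(log2(pmax(mm, eps)), log2(pmax(ww, eps)))
  } else {
    .rowWelch(mm, ww)
  }
  rd <- as.data.frame(SummarizedExperiment::rowData(ions))
  ann <- annotation$annotated[match(rd$ion_id, annotation$ion_id)]
  out <- data.frame(strain = mutantStrain, condition = condition,
                    ion_id = rd$ion_id, annotated = ann,
                    log2_fc = log2fc, p_value = wres$p_value,
                    q_value = NA_real_, excluded = excluded)
  inFam <- out$annotated & !out$excluded
  out$q_value[inFam] <- p.adjust(out$p_value[inFam], method = "BH")
  rownames(out) <- NULL
  out
}

#' Differential profiles for every mutant strain
#'
#' Runs [differentialAbundance()] for each non-wild-type strain in each
#' condition it was measured in.
#'
#' @inheritParams differentialAbundance
#' @return Named list of profile data.frames, keyed `"<strain>|<condition>"`.
#' @export
strainProfiles <- function(ions, annotation, wtStrain = "WT",
                           testOnLog = TRUE) {
  cd <- SummarizedExperiment::colData(ions)
  combos <- unique(data.frame(strain = cd$strain, condition = cd$condition))
  combos <- combos[combos$strain != wtStrain, ]
  out <- list()
  for (i in seq_len(nrow(combos))) {
    key <- paste(combos$strain[i], combos$condition[i], sep = "|")
    out[[key]] <- differentialAbundance(ions, annotation, combos$strain[i],
                                        wtStrain, combos$condition[i],
                                        testOnLog = testOnLog)
  }
  out
}

#' Data-driven global fold-change cutoff
#'
#' The significance cutoff on |log2 fold change| is the given percentile
#' (default 95) of the pooled |log2 fold change| distribution over all
#' annotated ions of all strain profiles in all conditions — a data-driven
#' floor that removes the bulk of small, biologically meaningless changes.
#'
#' @param profiles List of profile data.frames from [strainProfiles()] /
#'   [differentialAbundance()].
#' @param percentile Percentile in (0, 100], default 95.
#' @param type `"linear"` (interpolation between closest ranks, default) or
#'   `"nearest"` (nearest-rank percentile).
#' @return List with `cutoff`, `percentile`, `n_values`.
#' @export
globalFcCutoff <- function(profiles, percentile = 95,
                           type = c("linear", "nearest")) {
  type <- match.arg(type)
  if (is.data.frame(profiles)) profiles <- list(profiles)
  pool <- unlist(lapply(profiles, function(p) {
    abs(p$log2_fc[p$annotated & !p$excluded & is.finite(p$log2_fc)])
  }), use.names = FALSE)
  if (length(pool) < 20L) {
    stop("need >= 20 pooled |log2FC| values, got ", length(pool))
  }
  cutoff <- unname(quantile(pool, percentile / 100,
                            type = if (type == "linear") 7 else 1))
  list(cutoff = cutoff, percentile = percentile, n_values = length(pool))
}

#' Apply the significance rule to a profile
#'
#' An ion changes significantly when |log2 fold change| exceeds the global
#' cutoff and the BH-corrected p-value is below `qAlpha`.
#'
#' @param profile Profile data.frame from [differentialAbundance()].
#' @param cutoff Numeric cutoff (e.g. `globalFcCutoff(...)$cutoff`).
#' @param qAlpha FDR level (default 0.05).
#' @return The profile with a logical `significant` column.
#' @export
applySignificance <- function(profile, cutoff, qAlpha = 0.05) {
  stopifnot(is.numeric(cutoff), cutoff >= 0)
  sig <- profile$annotated & !profile$excluded &
    abs(profile$log2_fc) > cutoff & profile$q_value < qAlpha
  profile$significant <- !is.na(sig) & sig
  profile
}

#' Count changing metabolites in a profile
#'
#' Collapses significant ions to the metabolite level: a metabolite counts as
#' changing when at least one of its ions is significant. With
#' `policy = "all"` every member of an isobaric annotation set counts
#' (default); with `policy = "once"` each distinct annotation set counts a
#' single time.
#'
#' @param profile Profile with a `significant` column
#'   (see [applySignificance()]).
#' @param annotation Annotation table from [annotateIons()].
#' @param policy `"all"` or `"once"`.
#' @return Integer count.
#' @export
countChangingMetabolites <- function(profile, annotation,
                                     policy = c("all", "once")) {
  policy <- match.arg(policy)
  sigIons <- profile$ion_id[profile$significant]
  sets <- annotation$metabolite_ids[match(sigIons, annotation$ion_id)]
  if (length(sets) == 0L) return(0L)
  if (policy == "all") {
    length(unique(unlist(sets)))
  } else {
    length(unique(vapply(sets, function(s) paste(sort(s), collapse = ";"),
                         character(1))))
  }
}

#' Spearman correlation between two strain profiles
#'
#' Average-rank Spearman correlation of the log2 fold changes over the ions
#' annotated and non-excluded in both profiles (all shared annotated ions,
#' not only significant ones), with a two-sided p-value from the
#' t-approximation. With fewer than `minShared` shared ions the result is
#' flagged not determined.
#'
#' @param profileA,profileB Profile data.frames.
#' @param minShared Minimum shared annotated ions (default 10).
#' @return List with `rho`, `p_value`, `n_shared`, `nd` (not-determined flag).
#' @export
spearmanProfileCorrelation <- function(profileA, profileB, minShared = 10) {
  a <- profileA[profileA$annotated & !profileA$excluded &
                  is.finite(profileA$log2_fc), c("ion_id", "log2_fc")]
  b <- profileB[profileB$annotated & !profileB$excluded &
                  is.finite(profileB$log2_fc), c("ion_id", "log2_fc")]
  shared <- merge(a, b, by = "ion_id")
  if (nrow(shared) < minShared) {
    return(list(rho = NA_real_, p_value = NA_real_, n_shared = nrow(shared),
                nd = TRUE))
  }
  sc <- spearmanCorrelation(shared$log2_fc.x, shared$log2_fc.y)
  list(rho = sc$rho, p_value = sc$p_value, n_shared = sc$n, nd = FALSE)
}

#' Pairwise profile correlations
#'
#' Spearman correlations for every pair of strain profiles measured in the
#' same condition (or a supplied subset of pairs).
#'
#' @param profiles Named list from [strainProfiles()].
#' @param pairs Optional data.frame with columns `strain_a`, `strain_b`,
#'   `condition`; defaults to all within-condition pairs.
#' @inheritParams spearmanProfileCorrelation
#' @return data.frame with `strain_a`, `strain_b`, `condition`, `rho`,
#'   `p_value`, `n_shared`, `nd`.
#' @export
profileCorrelations <- function(profiles, pairs = NULL, minShared = 10) {
  info <- do.call(rbind, lapply(names(profiles), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(key = k, strain = parts[1], condition = parts[2])
  }))
  if (is.null(pairs)) {
    pairs <- do.call(rbind, lapply(unique(info$condition), function(cond) {
      ss <- info$strain[info$condition == cond]
      if (length(ss) < 2L) return(NULL)
      cmb <- t(combn(ss, 2))
      data.frame(strain_a = cmb[, 1], strain_b = cmb[, 2], condition = cond)
    }))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ka <- paste(pairs$strain_a[i], pairs$condition[i], sep = "|")
    kb <- paste(pairs$strain_b[i], pairs$condition[i], sep = "|")
    if (is.null(profiles[[ka]]) || is.null(profiles[[kb]])) {
      return(data.frame(strain_a = pairs$strain_a[i],
                        strain_b = pairs$strain_b[i],
                        condition = pairs$condition[i], rho = NA_real_,
                        p_value = NA_real_, n_shared = 0L, nd = TRUE))
    }
    sc <- spearmanProfileCorrelation(profiles[[ka]], profiles[[kb]],
                                     minShared)
    data.frame(strain_a = pairs$strain_a[i], strain_b = pairs$strain_b[i],
               condition = pairs$condition[i], rho = sc$rho,
               p_value = sc$p_value, n_shared = sc$n_shared, nd = sc$nd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
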