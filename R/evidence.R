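#' Assemble per-phosphosite evidence
#'
#' Joins the three upstream result sets — growth comparisons, differential
#' metabolite profiles and profile-vs-knockout correlations — into one long
#' evidence table with a row per site x mutant type x condition:
#'
#' * `growth_sig`: significant growth phenotype of that mutant strain;
#' * `local_change`: at least one significantly changing metabolite within
#'   `localSteps` reaction steps of the mutated enzyme;
#' * `ko_corr_pass`: Spearman rho above `rhoMin` with p below `rhoPMax`
#'   against the corresponding gene-knockout profile;
#' * `n_changing`: number of changing metabolites of the profile, and
#'   `global_change`: whether it reaches the cohort-wide global threshold,
#'   defined as twice the median `n_changing` over all phosphomutant
#'   profiles (reported, but never used for the functionality ranking).
#'
#' Missing measurements propagate as `NA` ("not determined") and are never
#' treated as negative evidence. Knockout strains get their own rows
#' (`mutant_type = "knockout"`, growth only); they support sign inference
#' but do not enter the site-level functionality OR.
#'
#' @param sites data.frame with columns `site_id`, `enzyme_id`,
#'   `mimetic_strain`, `abolishing_strain`, `knockout_strain` (NA where a
#'   strain does not exist).
#' @param network A [MetabolicNetwork-class]; every site's enzyme must be
#'   resolvable in it.
#' @param profiles Named list from [strainProfiles()], after
#'   [applySignificance()].
#' @param annotation Annotation table from [annotateIons()].
#' @param growth Optional data.frame from [growthComparisons()].
#' @param correlations Optional data.frame from [profileCorrelations()].
#' @param localSteps Reaction-step radius of the local network (default 5).
#' @param rhoMin,rhoPMax Knockout-correlation thresholds (defaults 0.4 and
#'   0.001).
#' @param countPolicy Passed to [countChangingMetabolites()].
#' @param excludeCurrency Passed to [localNetwork()].
#' @return An [EvidenceSet-class].
#' @export
assembleEvidence <- function(sites, network, profiles, annotation,
                             growth = NULL, correlations = NULL,
                             localSteps = 5, rhoMin = 0.4, rhoPMax = 0.001,
                             countPolicy = "all", excludeCurrency = TRUE) {
  missingEnz <- setdiff(unique(sites$enzyme_id), enzymeIds(network))
  if (length(missingEnz) > 0L) {
    bad <- sites$site_id[sites$enzyme_id %in% missingEnz]
    stop("enzyme absent from network for site(s): ",
         paste(bad, collapse = ", "))
  }
  localCache <- new.env(parent = emptyenv())
  localSet <- function(enz) {
    if (is.null(localCache[[enz]])) {
      localCache[[enz]] <- localNetwork(network, enz, maxSteps = localSteps,
                                        excludeCurrency = excludeCurrency)
    }
    localCache[[enz]]
  }
  profInfo <- do.call(rbind, lapply(names(profiles), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(key = k, strain = parts[1], condition = parts[2])
  }))
  lookupGrowth <- function(strain, cond) {
    if (is.null(growth)) return(list(sig = NA, rel = NA_real_))
    g <- growth[growth$strain == strain & growth$condition == cond, ]
    if (nrow(g) == 0L) list(sig = NA, rel = NA_real_)
    else list(sig = g$significant[1], rel = g$relative_rate[1])
  }
  lookupCorr <- function(strainA, strainB, cond) {
    if (is.null(correlations) || is.na(strainB)) {
      return(list(pass = NA, rho = NA_real_, p = NA_real_))
    }
    cr <- correlations[
      ((correlations$strain_a == strainA & correlations$strain_b == strainB) |
       (correlations$strain_a == strainB & correlations$strain_b == strainA)) &
        correlations$condition == cond, ]
    if (nrow(cr) == 0L || isTRUE(cr$nd[1]) || is.na(cr$rho[1])) {
      return(list(pass = NA, rho = NA_real_, p = NA_real_))
    }
    list(pass = cr$rho[1] > rhoMin && cr$p_value[1] < rhoPMax,
         rho = cr$rho[1], p = cr$p_value[1])
  }
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    strains <- c(mimetic = sites$mimetic_strain[i],
                 abolishing = sites$abolishing_strain[i],
                 knockout = sites$knockout_strain[i])
    for (mt in names(strains)) {
      strain <- strains[[mt]]
      if (is.na(strain)) next
      conds <- unique(c(profInfo$condition[profInfo$strain == strain],
                        if (!is.null(growth))
                          growth$condition[growth$strain == strain]))
      for (cond in conds) {
        gr <- lookupGrowth(strain, cond)
        key <- paste(strain, cond, sep = "|")
        prof <- profiles[[key]]
        if (is.null(prof) || mt == "knockout") {
          localChange <- NA
          nChanging <- NA_integer_
        } else {
          sigIons <- prof$ion_id[prof$significant]
          sigMets <- unique(unlist(
            annotation$metabolite_ids[match(sigIons, annotation$ion_id)]))
          localChange <- length(
            intersect(sigMets, localSet(sites$enzyme_id[i]))) > 0L
          nChanging <- countChangingMetabolites(prof, annotation,
                                                policy = countPolicy)
        }
        ko <- if (mt == "knockout") list(pass = NA, rho = NA_real_,
                                         p = NA_real_)
              else lookupCorr(strain, strains[["knockout"]], cond)
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = sites$site_id[i], enzyme_id = sites$enzyme_id[i],
          mutant_type = mt, strain = strain, condition = cond,
          growth_sig = gr$sig, growth_rel_rate = gr$rel,
          local_change = localChange, ko_corr_pass = ko$pass,
          rho = ko$rho, rho_p = ko$p, n_changing = nChanging)
      }
    }
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  mutRows <- ev$mutant_type %in% c("mimetic", "abolishing") &
    !is.na(ev$n_changing)
  med <- if (any(mutRows)) median(ev$n_changing[mutRows]) else NA_real_
  thr <- 2 * med
  ev$global_change <- !is.na(ev$n_changing) & !is.na(thr) & thr > 0 &
    ev$n_changing >= thr
  new("EvidenceSet", evidence = ev,
      globalThreshold = if (is.na(thr)) NA_real_ else thr,
      medianChanging = if (is.na(med)) NA_real_ else med)
}

# per-mutant-type aggregates used by the sign rules
.mutantSummary <- function(rows, koDefectConds) {
  measured <- any(!is.na(rows$growth_sig)) || any(!is.na(rows$ko_corr_pass))
  koPass <- any(rows$ko_corr_pass, na.rm = TRUE)
  defect <- !is.na(rows$growth_sig) & rows$growth_sig &
    rows$growth_rel_rate < 1
  growthDefect <- any(defect)
  concordantDefect <- any(defect & rows$condition %in% koDefectConds)
  list(
    present = nrow(rows) > 0L,
    measured = measured,
    resemblesKo = koPass || concordantDefect,
    # "resembles wild type or grows faster": nothing measured points to the
    # knockout and no growth defect was seen
    resemblesWt = measured && !koPass && !growthDefect
  )
}

#' Infer the sign of phosphoregulation for one site
#'
#' Codifies the comparison of mimetic and abolishing mutants against the
#' gene knockout. The abolishing mutant mimics the unphosphorylated enzyme,
#' the mimetic the constitutively phosphorylated one, and the knockout the
#' fully inactive one, so:
#'
#' (a) abolishing resembles the knockout (correlated metabolic profile, or
#' a significant growth defect in a condition where the knockout is also
#' impaired) while the mimetic resembles the wild type or grows faster:
#' phosphorylation activates the enzyme, sign `"+"`;
#' (b) the mirror case: phosphorylation inhibits, sign `"-"`;
#' (c) both mutants defective, neither knockout-like, or contradictory:
#' `"undetermined"`. Rules are applied in the order a, b, c. With a single
#' available mutant the sign is called only when that mutant is
#' knockout-concordant. Not-determined entries never contribute.
#'
#' @param siteEvidence Evidence rows of one site (see [assembleEvidence()]).
#' @return One of `"+"`, `"-"`, `"undetermined"`.
#' @export
inferEffectSign <- function(siteEvidence) {
  koRows <- siteEvidence[siteEvidence$mutant_type == "knockout", ]
  koDefectConds <- koRows$condition[!is.na(koRows$growth_sig) &
                                      koRows$growth_sig &
                                      koRows$growth_rel_rate < 1]
  mi <- .mutantSummary(siteEvidence[siteEvidence$mutant_type == "mimetic", ],
                       koDefectConds)
  ab <- .mutantSummary(
    siteEvidence[siteEvidence$mutant_type == "abolishing", ], koDefectConds)
  if (mi$present && ab$present) {
    if (ab$resemblesKo && mi$resemblesWt) return("+")
    if (mi$resemblesKo && ab$resemblesWt) return("-")
    return("undetermined")
  }
  if (ab$present && !mi$present) {
    return(if (ab$resemblesKo) "+" else "undetermined")
  }
  if (mi$present && !ab$present) {
    return(if (mi$resemblesKo) "-" else "undetermined")
  }
  "undetermined"
}

#' Call phosphosite functionality
#'
#' A site is functional when any of its phosphomutants (mimetic or
#' abolishing, any condition) shows (i) a significant growth phenotype,
#' (ii) a local metabolic change within the enzyme's local network, or
#' (iii) a metabolic profile correlated with the gene knockout — an OR over
#' the three evidence classes. The global-change flag is reported alongside
#' but is never sufficient for the call. Sign inference
#' ([inferEffectSign()]) runs for functional sites only; every call carries
#' a machine-readable rationale.
#'
#' @param evidenceSet An [EvidenceSet-class] from [assembleEvidence()].
#' @return data.frame with one row per site: `site_id`, `functional`,
#'   `evidence_classes` (comma-separated subset of
#'   growth/local_change/ko_correlation), `sign` (`"+"`, `"-"`,
#'   `"undetermined"`, or `"n.d."` for non-functional sites),
#'   `global_change_any`, `max_n_changing`, `rationale`.
#' @export
callFunctionality <- function(evidenceSet) {
  ev <- evidenceTable(evidenceSet)
  rows <- lapply(unique(ev$site_id), function(sid) {
    se <- ev[ev$site_id == sid, ]
    mut <- se[se$mutant_type %in% c("mimetic", "abolishing"), ]
    growthAny <- any(mut$growth_sig, na.rm = TRUE)
    localAny <- any(mut$local_change, na.rm = TRUE)
    koAny <- any(mut$ko_corr_pass, na.rm = TRUE)
    classes <- c("growth", "local_change", "ko_correlation")[
      c(growthAny, localAny, koAny)]
    functional <- length(classes) > 0L
    sign <- if (functional) inferEffectSign(se) else "n.d."
    firing <- mut[
      (!is.na(mut$growth_sig) & mut$growth_sig) |
      (!is.na(mut$local_change) & mut$local_change) |
      (!is.na(mut$ko_corr_pass) & mut$ko_corr_pass), ]
    rationale <- if (nrow(firing) == 0L) "no evidence" else {
      paste(apply(firing, 1, function(r) {
        hits <- c(
          if (isTRUE(as.logical(r[["growth_sig"]]))) "growth",
          if (isTRUE(as.logical(r[["local_change"]]))) "local",
          if (isTRUE(as.logical(r[["ko_corr_pass"]]))) "ko_corr")
        paste0(r[["mutant_type"]], "/", r[["condition"]], ":",
               paste(hits, collapse = "+"))
      }), collapse = "; ")
    }
    data.frame(site_id = sid, functional = functional,
               evidence_classes = paste(classes, collapse = ","),
               sign = sign,
               global_change_any = any(mut$global_change, na.rm = TRUE),
               max_n_changing = if (all(is.na(mut$n_changing))) NA_integer_
                                else max(mut$n_changing, na.rm = TRUE),
               rationale = rationale)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a cohort of functionality calls
#'
#' @param calls data.frame from [callFunctionality()].
#' @param evidenceSet The matching [EvidenceSet-class].
#' @return One-row data.frame with cohort counts: total and functional
#'   sites, sites with a growth phenotype, metabolically evidenced sites,
#'   phenotypically silent but metabolically evidenced sites, the median
#'   number of changing metabolites and the global-change threshold.
#' @export
summarizeCohort <- function(calls, evidenceSet) {
  hasGrowth <- grepl("growth", calls$evidence_classes)
  hasMetab <- grepl("local_change|ko_correlation", calls$evidence_classes)
  data.frame(
    n_sites = nrow(calls),
    n_functional = sum(calls$functional),
    n_growth_phenotype = sum(hasGrowth),
    n_metabolic_evidence = sum(hasMetab),
    n_silent_metabolic = sum(hasMetab & !hasGrowth),
    median_n_changing = evidenceSet@medianChanging,
    global_threshold = evidenceSet@globalThreshold
  )
}
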