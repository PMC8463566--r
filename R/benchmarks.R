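#' Null-cohort calibration benchmark
#'
#' Generates an effect-free cohort (every site null), runs the full
#' metabolome arm of the screen — annotation, differential profiles,
#' data-driven cutoff, significance, knockout correlations, evidence,
#' functionality calls — and reports the false-positive behaviour: the mean
#' fraction of significant ions per profile and the fraction of (truly
#' null) sites called functional.
#'
#' @param network A [MetabolicNetwork-class]; defaults to
#'   [syntheticNetwork()], matching the annotation scale of the screen
#'   (hundreds of metabolites, so a five-step neighbourhood is local).
#' @param nSites Number of null sites (default 30).
#' @param nReplicates Replicates per mutant strain (default 4); the
#'   wild-type reference keeps the generator's larger pool.
#' @param seed Cohort seed.
#' @return List with `mean_sig_fraction`, `false_call_rate`, `cutoff`,
#'   `n_profiles`.
#' @export
benchmarkNullCohort <- function(network = syntheticNetwork(), nSites = 30,
                                nReplicates = 4, seed = 1L) {
  sites <- syntheticSites(network, 0, nSites)
  cfg <- cohortConfig(network, sites, nReplicates = nReplicates, seed = seed)
  ion <- suppressMessages(generateIonTable(cfg))
  ann <- annotateIons(ion$ions, network)
  profs <- strainProfiles(ion$ions, ann)
  cut <- globalFcCutoff(profs)
  profs <- lapply(profs, applySignificance, cutoff = cut$cutoff)
  fracs <- vapply(profs, function(p) {
    fam <- p$annotated & !p$excluded
    if (!any(fam)) return(0)
    sum(p$significant[fam]) / sum(fam)
  }, numeric(1))
  corr <- profileCorrelations(profs, pairs = .koPairs(cfg))
  ev <- assembleEvidence(siteSheet(cfg), network, profs, ann,
                         correlations = corr)
  calls <- callFunctionality(ev)
  list(mean_sig_fraction = mean(fracs),
       false_call_rate = mean(calls$functional),
       cutoff = cut$cutoff,
       n_profiles = length(profs))
}

# mutant-vs-knockout correlation pairs of a cohort configuration
.koPairs <- function(cfg) {
  st <- siteSheet(cfg)
  st <- st[!is.na(st$knockout_strain), ]
  if (nrow(st) == 0L) return(NULL)
  do.call(rbind, lapply(cfg$conditions, function(cond) {
    data.frame(
      strain_a = c(st$mimetic_strain, st$abolishing_strain),
      strain_b = rep(st$knockout_strain, 2),
      condition = cond)
  }))
}

#' Planted-effect recovery benchmark
#'
#' Generates a cohort with planted functional sites — local metabolite
#' effects around each mutated enzyme, knockout-concordant phosphomutant
#' profiles and knockout-like growth defects of the concordant mutant —
#' alongside null sites, runs both the growth and the metabolome arm end
#' to end and scores recovery against the planted ground truth.
#'
#' @inheritParams benchmarkNullCohort
#' @param nFunctional,nNull Numbers of planted functional and null sites.
#' @param effectSize Planted |log2 FC| (default 1.5).
#' @param radius Planting radius in reaction steps (default 3).
#' @param concordance Knockout-concordance factor (default 1).
#' @param noiseSigmaLog2 Replicate noise (default 0.25).
#' @return List with `sensitivity` (fraction of functional sites called),
#'   `false_calls` (null sites called functional), `sign_correct` (functional
#'   sites whose planted sign was recovered), `cutoff`.
#' @export
benchmarkRecoveryCohort <- function(network = syntheticNetwork(),
                                    nFunctional = 10, nNull = 10,
                                    effectSize = 1.5, radius = 3,
                                    concordance = 1, nReplicates = 6,
                                    noiseSigmaLog2 = 0.25, seed = 1L) {
  sites <- syntheticSites(network, nFunctional, nNull,
                          effectSize = effectSize, radius = radius)
  cfg <- cohortConfig(network, sites, nReplicates = nReplicates,
                      noiseSigmaLog2 = noiseSigmaLog2,
                      concordance = concordance, duration = 10,
                      muNoiseSd = 0.01, seed = seed)
  ion <- suppressMessages(generateIonTable(cfg))
  ann <- annotateIons(ion$ions, network)
  profs <- strainProfiles(ion$ions, ann)
  cut <- globalFcCutoff(profs)
  profs <- lapply(profs, applySignificance, cutoff = cut$cutoff)
  corr <- profileCorrelations(profs, pairs = .koPairs(cfg))
  growth <- growthComparisons(fitGrowthRates(generateGrowthCurves(cfg)$curves))
  ev <- assembleEvidence(siteSheet(cfg), network, profs, ann,
                         growth = growth, correlations = corr)
  calls <- callFunctionality(ev)
  truth <- ion$groundTruth
  isFun <- vapply(truth, `[[`, logical(1), "functional")
  calls <- calls[match(names(truth), calls$site_id), ]
  sens <- mean(calls$functional[isFun])
  falseCalls <- sum(calls$functional[!isFun])
  signTruth <- vapply(truth, `[[`, character(1), "sign")
  signOk <- sum(calls$functional[isFun] &
                  calls$sign[isFun] == signTruth[isFun])
  list(sensitivity = sens, false_calls = falseCalls,
       sign_correct = signOk, cutoff = cut$cutoff)
}

#' Growth-screen detection benchmark
#'
#' Plants growth-rate reductions on mutant strains (one strain per
#' reduction), generates replicate microplate curves with between-replicate
#' rate noise, fits exponential rates through the standard window-selection
#' fit and applies the wild-type comparison rule. Returns, per planted
#' reduction, whether the strain was flagged.
#'
#' @inheritParams benchmarkNullCohort
#' @param reductions Numeric vector of fractional growth-rate reductions
#'   (e.g. `c(0.15, 0.05)`).
#' @param muNoiseSd Between-replicate growth-rate sd, 1/h (default 0.02).
#' @return Logical vector parallel to `reductions`.
#' @export
benchmarkGrowthScreen <- function(network = syntheticNetwork(), reductions,
                                  muNoiseSd = 0.02, nReplicates = 6,
                                  seed = 1L) {
  enz <- sort(enzymeIds(network))[seq_along(reductions)]
  sites <- data.frame(
    site_id = paste0(enz, "_S", seq_along(reductions)),
    enzyme_id = enz,
    functional = FALSE, sign = NA_character_, effect_size = 0, radius = 3,
    has_knockout = FALSE,
    rel_mu_mimetic = 1 - reductions,
    rel_mu_abolishing = 1,
    rel_mu_knockout = 1)
  cfg <- cohortConfig(network, sites, nReplicates = nReplicates,
                      wtReplicates = nReplicates, muNoiseSd = muNoiseSd,
                      odNoiseSd = 0.002, duration = 10, seed = seed)
  gg <- generateGrowthCurves(cfg)
  est <- fitGrowthRates(gg$curves)
  cmp <- growthComparisons(est)
  flagged <- cmp$significant[match(paste0(sites$site_id, "E"), cmp$strain)]
  as.logical(flagged)
}
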