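# evaluate code under a given seed, then restore the caller's RNG state
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a genome-scale-like synthetic metabolic network
#'
#' Builds a metabolic model at the annotation scale of a genome-wide
#' reconstruction (hundreds of metabolites), structured as several parallel
#' pathway chains with occasional cross-links — so a five-reaction-step
#' neighbourhood stays genuinely local (a few percent of the network), as
#' it is in a real reconstruction. Each reaction consumes the chain
#' metabolite and about a third additionally turn over a cofactor pair
#' (excluded from traversal as currency). Metabolite formulas are drawn
#' over C/H/N/O/P/S with neutral masses inside the instrument's 50-1000 Da
#' window; duplicated formulas yield naturally isobaric annotation sets.
#' The model is a pure function of `seed`.
#'
#' @param nMetabolites Number of non-currency metabolites (default 420).
#' @param nChains Number of parallel pathway chains (default 14).
#' @param crossLinkEvery Insert a cross-link reaction about every this many
#'   chain positions (default 15).
#' @param seed Integer seed.
#' @return A [MetabolicNetwork-class].
#' @export
syntheticNetwork <- function(nMetabolites = 420, nChains = 14,
                             crossLinkEvery = 15, seed = 20L) {
  .withSeed(seed, {
    ids <- sprintf("sm%04d", seq_len(nMetabolites))
    formulas <- character(nMetabolites)
    for (i in seq_len(nMetabolites)) {
      repeat {
        counts <- c(C = sample(3:18, 1), H = 0, N = sample(0:4, 1),
                    O = sample(1:9, 1), P = sample(0:2, 1),
                    S = sample(0:1, 1))
        counts["H"] <- max(1L, counts[["C"]] + sample(-1:6, 1))
        mass <- sum(counts * MONOISOTOPIC_MASSES[names(counts)])
        if (mass > 60 && mass < 950) break
      }
      parts <- counts[counts > 0]
      formulas[i] <- paste0(names(parts), parts, collapse = "")
    }
    currency <- data.frame(
      metabolite_id = c("atp", "adp", "nad", "nadh", "nadp", "nadph",
                        "coa", "pi", "h2o", "co2"),
      name = c("ATP", "ADP", "NAD+", "NADH", "NADP+", "NADPH",
               "coenzyme A", "orthophosphate", "water", "carbon dioxide"),
      formula = c("C10H16N5O13P3", "C10H15N5O10P2", "C21H27N7O14P2",
                  "C21H28N7O14P2", "C21H28N7O17P3", "C21H29N7O17P3",
                  "C21H36N7O16P3S", "H3O4P", "H2O", "CO2"),
      is_currency = TRUE)
    mets <- rbind(
      data.frame(metabolite_id = ids,
                 name = paste("synthetic metabolite", seq_len(nMetabolites)),
                 formula = formulas, is_currency = FALSE),
      currency)
    # parallel chains m1 -> m2 -> ... with one enzyme per reaction
    chain <- rep(seq_len(nChains), length.out = nMetabolites)
    subs <- list(); prods <- list(); k <- 0L
    for (ch in seq_len(nChains)) {
      members <- ids[chain == ch]
      for (j in seq_len(length(members) - 1L)) {
        k <- k + 1L
        s <- members[j]; p <- members[j + 1L]
        if (k %% 3 == 0) { # cofactor turnover on every third reaction
          s <- c(s, "atp"); p <- c(p, "adp")
        }
        subs[[k]] <- s; prods[[k]] <- p
      }
    }
    # sparse cross-links between chains
    nLinks <- max(1L, floor(nMetabolites / crossLinkEvery / nChains) *
                    nChains)
    from <- sample(ids, nLinks)
    to <- sample(ids, nLinks)
    for (j in seq_len(nLinks)) {
      if (from[j] == to[j]) next
      k <- k + 1L
      subs[[k]] <- from[j]; prods[[k]] <- to[j]
    }
    rxns <- data.frame(
      reaction_id = sprintf("sr%04d", seq_len(k)),
      enzyme_id = sprintf("enz%04d", seq_len(k)),
      reversible = rep(c(TRUE, FALSE), length.out = k))
    rxns$substrates <- subs
    rxns$products <- prods
    MetabolicNetwork(mets, rxns)
  })
}

#' Build a planted phosphosite table for a synthetic cohort
#'
#' Picks enzymes spread evenly across the network's sorted enzyme list (a
#' pure function of the network, and spacing keeps the sites' local
#' networks from piling onto the same pathway segment). The first
#' `nFunctional` become planted functional sites with alternating signs,
#' the rest null sites with no planted effect.
#'
#' @param network A [MetabolicNetwork-class].
#' @param nFunctional,nNull Numbers of functional and null sites.
#' @param effectSize Planted |log2 fold change| on perturbed metabolites.
#' @param radius Locality radius (reaction steps) of the planted effects.
#' @param withKnockout Give every site a knockout strain (default TRUE).
#' @return data.frame of site specs accepted by [cohortConfig()].
#' @export
syntheticSites <- function(network, nFunctional, nNull, effectSize = 1.5,
                           radius = 3, withKnockout = TRUE) {
  enz <- sort(enzymeIds(network))
  need <- nFunctional + nNull
  if (length(enz) < need) {
    stop("network has only ", length(enz), " enzymes; ", need, " needed")
  }
  enz <- enz[unique(round(seq(1, length(enz), length.out = need)))]
  if (length(enz) < need) enz <- sort(enzymeIds(network))[seq_len(need)]
  functional <- rep(c(TRUE, FALSE), c(nFunctional, nNull))
  data.frame(
    site_id = paste0(enz[seq_len(need)], "_S", 100 + seq_len(need)),
    enzyme_id = enz[seq_len(need)],
    functional = functional,
    sign = ifelse(functional,
                  rep_len(c("+", "-"), need), NA_character_),
    effect_size = ifelse(functional, effectSize, 0),
    radius = radius,
    has_knockout = withKnockout
  )
}

#' Configuration of a synthetic phosphosite cohort
#'
#' Bundles the network, the planted site table and all generator parameters.
#' Defaults mirror a microplate/FIA-MS screen: six replicates, log-normal
#' ion intensities with sigma 0.25 log2 units, OD600 sampled every 10 min
#' for 18 h with logistic saturation.
#'
#' @param network A [MetabolicNetwork-class].
#' @param sites Site table as from [syntheticSites()]; optional columns
#'   `rel_mu_mimetic`, `rel_mu_abolishing`, `rel_mu_knockout` override the
#'   planted relative growth rates (defaults: knockout-like mutant 0.85,
#'   other mutant 1.0, knockout 0.75 for functional sites; all 1.0 for null
#'   sites).
#' @param nReplicates Replicates per mutant strain and condition (default 6).
#' @param wtReplicates Replicates of the wild-type reference (default
#'   `6 * nReplicates`): the reference strain is cultivated and measured
#'   alongside every mutant batch, so it accumulates far more replicates
#'   than any single mutant. A large reference pool also keeps the
#'   shared-reference correlation between mutant fold-change profiles small
#'   (with equal group sizes, two profiles computed against the same
#'   reference replicates would correlate at rho ~ 0.5 even without any
#'   biological signal).
#' @param noiseSigmaLog2 Replicate noise of log2 intensities (default 0.25).
#' @param conditions Character vector of condition labels.
#' @param concordance Scaling of the knockout's planted effect vector on the
#'   knockout-like phosphomutant (default 1 = identical effects).
#' @param wtMu Wild-type growth rate, 1/h (default 0.65).
#' @param od0 Inoculation OD600 (default 0.02).
#' @param capacity Carrying capacity OD600 of the logistic cap (default 1.2).
#' @param samplingInterval Sampling interval in h (default 1/6 = 10 min).
#' @param duration Total cultivation time in h (default 18).
#' @param odNoiseSd Additive OD600 noise sd (default 0.005).
#' @param muNoiseSd Between-replicate sd of the growth rate itself, 1/h
#'   (default 0; biological replicate-to-replicate rate variation).
#' @param decoyFraction Fraction of decoy ions with masses > 0.005 Da from
#'   any model metabolite (default 0.1).
#' @param baselineRange Range of baseline log2 intensities (default 10-20).
#' @param seed Integer seed; all generated tables are pure functions of the
#'   configuration including this seed.
#' @return Object of class `SyntheticCohortConfig` (a validated list).
#' @export
cohortConfig <- function(network, sites, nReplicates = 6,
                         wtReplicates = 6 * nReplicates,
                         noiseSigmaLog2 = 0.25, conditions = "glucose",
                         concordance = 1, wtMu = 0.65, od0 = 0.02,
                         capacity = 1.2, samplingInterval = 1 / 6,
                         duration = 18, odNoiseSd = 0.005, muNoiseSd = 0,
                         decoyFraction = 0.1, baselineRange = c(10, 20),
                         seed = 1L) {
  sites <- as.data.frame(sites)
  stopifnot(nReplicates >= 2, wtReplicates >= 2, all(sites$effect_size >= 0),
            noiseSigmaLog2 >= 0, wtMu > 0, od0 > 0, capacity > od0,
            decoyFraction >= 0, concordance >= 0)
  bad <- setdiff(sites$enzyme_id, enzymeIds(network))
  if (length(bad) > 0L) {
    stop("site enzyme(s) absent from network: ", paste(bad, collapse = ", "))
  }
  if (!"rel_mu_mimetic" %in% names(sites)) {
    koLikeIsMimetic <- sites$functional & !is.na(sites$sign) &
      sites$sign == "-"
    koLikeIsAbol <- sites$functional & !is.na(sites$sign) & sites$sign == "+"
    sites$rel_mu_mimetic <- ifelse(koLikeIsMimetic, 0.85, 1)
    sites$rel_mu_abolishing <- ifelse(koLikeIsAbol, 0.85, 1)
    sites$rel_mu_knockout <- ifelse(sites$functional, 0.75, 1)
  }
  structure(list(network = network, sites = sites,
                 nReplicates = nReplicates, wtReplicates = wtReplicates,
                 noiseSigmaLog2 = noiseSigmaLog2,
                 conditions = conditions, concordance = concordance,
                 wtMu = wtMu, od0 = od0, capacity = capacity,
                 samplingInterval = samplingInterval, duration = duration,
                 odNoiseSd = odNoiseSd, muNoiseSd = muNoiseSd,
                 decoyFraction = decoyFraction,
                 baselineRange = baselineRange, seed = as.integer(seed)),
            class = "SyntheticCohortConfig")
}

# strain labels: mimetic <site>_E, abolishing <site>_A, knockout <enzyme>_KO
.strainTable <- function(config) {
  s <- config$sites
  data.frame(
    site_id = s$site_id,
    enzyme_id = s$enzyme_id,
    mimetic_strain = paste0(s$site_id, "E"),
    abolishing_strain = paste0(s$site_id, "A"),
    knockout_strain = ifelse(s$has_knockout, paste0(s$enzyme_id, "_KO"),
                             NA_character_)
  )
}

#' Site sheet of a synthetic cohort
#'
#' The site table in the form [assembleEvidence()] expects (site, enzyme and
#' the mimetic/abolishing/knockout strain labels).
#'
#' @param config A `SyntheticCohortConfig`.
#' @return data.frame.
#' @export
siteSheet <- function(config) .strainTable(config)

# planted per-strain effect vectors (log2 units) over all metabolites.
# The knockout carries the full effect vector of its enzyme's functional
# site; the knockout-like mutant (abolishing for "+", mimetic for "-")
# carries concordance * that vector; the other mutant is unperturbed.
.plantedEffects <- function(config) {
  net <- config$network
  met <- metaboliteTable(net)$metabolite_id
  s <- config$sites
  st <- .strainTable(config)
  effects <- list()
  truth <- list()
  for (i in seq_len(nrow(s))) {
    v <- setNames(numeric(length(met)), met)
    perturbed <- character(0)
    if (s$functional[i] && s$effect_size[i] > 0) {
      perturbed <- localNetwork(net, s$enzyme_id[i], maxSteps = s$radius[i])
      if (length(perturbed) > 0L) {
        dirs <- sample(c(-1, 1), length(perturbed), replace = TRUE)
        v[perturbed] <- dirs * s$effect_size[i]
      }
    }
    koLike <- if (!s$functional[i] || is.na(s$sign[i])) NA_character_
              else if (s$sign[i] == "+") "abolishing" else "mimetic"
    effects[[st$mimetic_strain[i]]] <-
      if (identical(koLike, "mimetic")) config$concordance * v else 0 * v
    effects[[st$abolishing_strain[i]]] <-
      if (identical(koLike, "abolishing")) config$concordance * v else 0 * v
    if (!is.na(st$knockout_strain[i]) &&
        is.null(effects[[st$knockout_strain[i]]])) {
      effects[[st$knockout_strain[i]]] <- v
    }
    truth[[s$site_id[i]]] <- list(
      functional = s$functional[i], sign = s$sign[i],
      perturbed = perturbed, ko_like_mutant = koLike)
  }
  list(effects = effects, truth = truth)
}

#' Generate a synthetic ion intensity cohort
#'
#' One ion per model metabolite at its exact deprotonated mass, plus a
#' configurable fraction of decoy ions more than 0.005 Da away from any
#' model metabolite (these exercise the no-annotation path). Replicate
#' intensities are log-normal: log2 intensity = metabolite baseline +
#' planted effect + N(0, noiseSigmaLog2), exponentiated to the linear scale.
#' The knockout and its concordant phosphomutant share the same planted
#' effect vector (scaled by `concordance`), so knockout-profile correlation
#' is inducible. Fully reproducible from the configuration seed.
#'
#' @param config A `SyntheticCohortConfig`.
#' @return List with `ions` (an [IonSet-class]) and `groundTruth` (per-site
#'   planted truth: functional flag, sign, perturbed metabolite ids, which
#'   mutant is knockout-like).
#' @export
generateIonTable <- function(config) {
  .withSeed(config$seed + 1L, {
    net <- config$network
    met <- metaboliteTable(net)
    nMet <- nrow(met)
    baseline <- runif(nMet, config$baselineRange[1], config$baselineRange[2])
    pe <- .plantedEffects(config)
    strains <- c("WT", names(pe$effects))
    samples <- do.call(rbind, lapply(strains, function(strain) {
      nrep <- if (strain == "WT") config$wtReplicates else config$nReplicates
      expand.grid(replicate = seq_len(nrep),
                  condition = config$conditions,
                  strain = strain,
                  stringsAsFactors = FALSE)
    }))
    samples <- samples[, c("strain", "condition", "replicate")]
    nDecoy <- round(config$decoyFraction * nMet)
    targets <- deprotonatedMass(met$monoisotopic_mass)
    decoyMass <- numeric(0)
    while (length(decoyMass) < nDecoy) {
      cand <- runif(nDecoy * 2, 50, 1000)
      ok <- vapply(cand, function(m) all(abs(m - targets) > 0.005),
                   logical(1))
      decoyMass <- c(decoyMass, cand[ok])
    }
    decoyMass <- decoyMass[seq_len(nDecoy)]
    decoyBase <- runif(nDecoy, config$baselineRange[1],
                       config$baselineRange[2])
    nIon <- nMet + nDecoy
    log2mat <- matrix(NA_real_, nIon, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      eff <- if (samples$strain[j] == "WT") 0 else
        pe$effects[[samples$strain[j]]]
      log2mat[, j] <- c(baseline + eff, decoyBase) +
        rnorm(nIon, 0, config$noiseSigmaLog2)
    }
    intensity <- 2^log2mat
    rownames(intensity) <- c(paste0("ion_", met$metabolite_id),
                             sprintf("decoy_%03d", seq_len(nDecoy)))
    ions <- IonSet(intensity, c(targets, decoyMass), samples)
    list(ions = ions, groundTruth = pe$truth)
  })
}

#' Generate synthetic microplate growth curves
#'
#' OD600 follows logistic growth
#' `OD(t) = K od0 exp(mu t) / (K + od0 (exp(mu t) - 1))` — exponential at
#' rate mu early, saturating at carrying capacity K — plus additive Gaussian
#' noise, sampled on a regular grid. Each strain's mu is the wild-type rate
#' scaled by its planted relative rate. Reproducible from the seed.
#'
#' @param config A `SyntheticCohortConfig`.
#' @return List with `curves` (a [GrowthCurveSet-class]) and `groundTruth`
#'   (data.frame of planted mu per strain).
#' @export
generateGrowthCurves <- function(config) {
  .withSeed(config$seed + 2L, {
    s <- config$sites
    st <- .strainTable(config)
    rel <- c(WT = 1)
    for (i in seq_len(nrow(s))) {
      rel[st$mimetic_strain[i]] <- s$rel_mu_mimetic[i]
      rel[st$abolishing_strain[i]] <- s$rel_mu_abolishing[i]
      if (!is.na(st$knockout_strain[i]) &&
          !st$knockout_strain[i] %in% names(rel)) {
        rel[st$knockout_strain[i]] <- s$rel_mu_knockout[i]
      }
    }
    tt <- seq(0, config$duration, by = config$samplingInterval)
    rows <- vector("list", length(rel) * length(config$conditions) *
                     config$nReplicates)
    k <- 0L
    for (strain in names(rel)) {
      muStrain <- config$wtMu * rel[[strain]]
      nrep <- if (strain == "WT") config$wtReplicates else
        config$nReplicates
      for (cond in config$conditions) {
        for (r in seq_len(nrep)) {
          mu <- muStrain + rnorm(1, 0, config$muNoiseSd)
          base <- config$capacity * config$od0 * exp(mu * tt) /
            (config$capacity + config$od0 * (exp(mu * tt) - 1))
          od <- base + rnorm(length(tt), 0, config$odNoiseSd)
          k <- k + 1L
          rows[[k]] <- data.frame(strain = strain, condition = cond,
                                  replicate = r, time_h = tt,
                                  od600 = pmax(od, 1e-4))
        }
      }
    }
    gt <- data.frame(strain = names(rel),
                     relative_mu = unname(unlist(rel)),
                     mu = config$wtMu * unname(unlist(rel)))
    list(curves = GrowthCurveSet(do.call(rbind, rows)), groundTruth = gt)
  })
}

#' Generate synthetic in vitro assay traces
#'
#' A thermal-shift melt curve (sigmoid centred at `tmTrue`) and a kinetic
#' trace (linear at `slopeTrue` until `plateauTime`, then flat), both with
#' seeded Gaussian noise.
#'
#' @param tmTrue True melting temperature, degrees C; must lie inside
#'   `tempRange`.
#' @param slopeTrue True initial rate, AU/min.
#' @param noiseSd Noise sd on both traces (same units as the signal).
#' @param seed Integer seed.
#' @param tempRange,tempStep Temperature scan range and step (degrees C).
#' @param meltWidth Sigmoid width parameter (degrees C).
#' @param amplitude Fluorescence amplitude of the melt transition.
#' @param kineticDuration,kineticStep Kinetic trace length and step (min).
#' @param plateauTime Time at which the kinetic trace plateaus (min).
#' @param proteinConc Protein concentration (mg/mL) recorded on the trace.
#' @return List with `melt` (data.frame `temperature_c`, `fluorescence`) and
#'   `kinetic` (data.frame `time_min`, `absorbance`, `protein_mg_ml`).
#' @export
generateAssayTraces <- function(tmTrue, slopeTrue, noiseSd = 0, seed = 1L,
                                tempRange = c(25, 95), tempStep = 0.5,
                                meltWidth = 2, amplitude = 1,
                                kineticDuration = 10, kineticStep = 0.1,
                                plateauTime = 5, proteinConc = 1) {
  stopifnot(tmTrue > tempRange[1], tmTrue < tempRange[2])
  .withSeed(seed, {
    temp <- seq(tempRange[1], tempRange[2], by = tempStep)
    fluor <- amplitude / (1 + exp(-(temp - tmTrue) / meltWidth)) +
      rnorm(length(temp), 0, noiseSd)
    tmin <- seq(0, kineticDuration, by = kineticStep)
    absb <- slopeTrue * pmin(tmin, plateauTime) +
      rnorm(length(tmin), 0, noiseSd)
    list(melt = data.frame(temperature_c = temp, fluorescence = fluor),
         kinetic = data.frame(time_min = tmin, absorbance = absb,
                              protein_mg_ml = proteinConc))
  })
}
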