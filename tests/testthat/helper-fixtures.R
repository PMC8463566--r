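# Shared fixtures and independent oracles.

ccmNetwork <- local({
  net <- NULL
  function() {
    if (is.null(net)) {
      net <<- loadMetabolicNetwork(
        system.file("extdata", "ecoli_ccm_metabolites.tsv",
                    package = "PhosphoScreen"),
        system.file("extdata", "ecoli_ccm_reactions.tsv",
                    package = "PhosphoScreen"))
    }
    net
  }
})

# linear chain M0 -R1-> M1 -R2-> ... -R6-> M6, one enzyme per reaction
chainNetwork <- function(n = 6) {
  mets <- data.frame(
    metabolite_id = paste0("M", 0:n),
    name = paste0("metabolite ", 0:n),
    formula = "C6H12O6",
    is_currency = FALSE)
  rxns <- data.frame(
    reaction_id = paste0("R", seq_len(n)),
    enzyme_id = paste0("E", seq_len(n)),
    substrates = paste0("M", seq_len(n) - 1),
    products = paste0("M", seq_len(n)),
    reversible = FALSE)
  MetabolicNetwork(mets, rxns)
}

# random small network for oracle comparisons
randomNetwork <- function(nRxn, nMet = 8, currencyFrac = 0) {
  mets <- data.frame(
    metabolite_id = paste0("m", seq_len(nMet)),
    name = paste0("met ", seq_len(nMet)),
    formula = "C3H4O3",
    is_currency = seq_len(nMet) <= round(currencyFrac * nMet))
  subs <- prods <- vector("list", nRxn)
  for (i in seq_len(nRxn)) {
    picks <- sample(nMet, sample(2:3, 1))
    k <- sample(seq_len(length(picks) - 1), 1)
    subs[[i]] <- paste0("m", picks[seq_len(k)])
    prods[[i]] <- paste0("m", picks[-seq_len(k)])
  }
  rxns <- data.frame(
    reaction_id = paste0("r", seq_len(nRxn)),
    enzyme_id = paste0("e", seq_len(nRxn)),
    reversible = sample(c(TRUE, FALSE), nRxn, replace = TRUE))
  rxns$substrates <- subs
  rxns$products <- prods
  MetabolicNetwork(mets, rxns)
}

# exhaustive simple-path enumeration over reaction sequences: the number of
# reactions in the shortest connecting path, independent of any graph library
enumDistances <- function(net, enzymeId, excludeCurrency = TRUE) {
  rxn <- reactionTable(net)
  met <- metaboliteTable(net)
  drop <- if (excludeCurrency) met$metabolite_id[met$is_currency]
          else character(0)
  parts <- lapply(seq_len(nrow(rxn)), function(i) {
    setdiff(union(rxn$substrates[[i]], rxn$products[[i]]), drop)
  })
  names(parts) <- rxn$reaction_id
  best <- setNames(rep(Inf, nrow(met)), met$metabolite_id)
  recurse <- function(path) {
    current <- path[length(path)]
    k <- length(path)
    for (m in parts[[current]]) best[[m]] <<- min(best[[m]], k)
    for (j in names(parts)) {
      if (j %in% path) next
      if (length(intersect(parts[[current]], parts[[j]])) > 0) {
        recurse(c(path, j))
      }
    }
  }
  start <- rxn$reaction_id[rxn$enzyme_id == enzymeId]
  for (r in start) recurse(r)
  best
}

# Benjamini-Hochberg step-up by explicit sort / scale / cummin
bhBrute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# tiny complete cohort (ions + correlations + evidence), used by several tests
makeDemoCohort <- function(nFunctional = 2, nNull = 1, nReplicates = 4,
                           seed = 11, effectSize = 1.5, radius = 3,
                           noise = 0.25, concordance = 1,
                           conditions = "glucose") {
  net <- ccmNetwork()
  sites <- syntheticSites(net, nFunctional, nNull, effectSize = effectSize,
                          radius = radius)
  cfg <- cohortConfig(net, sites, nReplicates = nReplicates,
                      noiseSigmaLog2 = noise, concordance = concordance,
                      conditions = conditions, seed = seed)
  ion <- generateIonTable(cfg)
  ann <- annotateIons(ion$ions, net)
  profs <- strainProfiles(ion$ions, ann)
  cut <- globalFcCutoff(profs)
  profs <- lapply(profs, applySignificance, cutoff = cut$cutoff)
  corr <- profileCorrelations(profs)
  ev <- assembleEvidence(siteSheet(cfg), net, profs, ann,
                         correlations = corr)
  list(net = net, cfg = cfg, ion = ion, ann = ann, profiles = profs,
       cutoff = cut, corr = corr, evidence = ev,
       calls = callFunctionality(ev))
}
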