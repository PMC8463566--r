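test_that("generation is a pure function of the configuration seed", {
  net <- ccmNetwork()
  sites <- syntheticSites(net, 2, 1)
  cfg <- cohortConfig(net, sites, nReplicates = 3, seed = 99)
  a <- suppressMessages(generateIonTable(cfg))
  b <- suppressMessages(generateIonTable(cfg))
  expect_identical(SummarizedExperiment::assay(a$ions),
                   SummarizedExperiment::assay(b$ions))
  expect_identical(a$groundTruth, b$groundTruth)
  ga <- generateGrowthCurves(cfg)
  gb <- generateGrowthCurves(cfg)
  expect_identical(growthCurves(ga$curves), growthCurves(gb$curves))
  # a different seed changes the data
  cfg2 <- cohortConfig(net, sites, nReplicates = 3, seed = 100)
  c2 <- suppressMessages(generateIonTable(cfg2))
  expect_false(identical(SummarizedExperiment::assay(a$ions),
                         SummarizedExperiment::assay(c2$ions)))
})

test_that("planted effects stay within the configured locality radius", {
  net <- ccmNetwork()
  sites <- syntheticSites(net, 4, 0, radius = 3)
  cfg <- cohortConfig(net, sites, nReplicates = 2, seed = 5)
  gt <- suppressMessages(generateIonTable(cfg))$groundTruth
  for (sid in names(gt)) {
    enz <- sites$enzyme_id[sites$site_id == sid]
    expect_true(all(gt[[sid]]$perturbed %in% localNetwork(net, enz, 3)))
  }
  # null sites carry no perturbation
  nullSites <- syntheticSites(net, 0, 3)
  cfgN <- cohortConfig(net, nullSites, nReplicates = 2, seed = 5)
  gtN <- suppressMessages(generateIonTable(cfgN))$groundTruth
  expect_true(all(vapply(gtN, function(g) length(g$perturbed) == 0,
                         logical(1))))
})

test_that("noiseless growth curves are log-linear at the planted rate", {
  net <- ccmNetwork()
  sites <- syntheticSites(net, 1, 0)
  sites$rel_mu_mimetic <- 0.85
  sites$rel_mu_abolishing <- 1
  sites$rel_mu_knockout <- 0.75
  cfg <- cohortConfig(net, sites, nReplicates = 2, wtMu = 0.6,
                      odNoiseSd = 0, duration = 12, capacity = 50, seed = 3)
  gg <- generateGrowthCurves(cfg)
  cc <- growthCurves(gg$curves)
  wt <- cc[cc$strain == "WT" & cc$replicate == 1, ]
  early <- wt$time_h <= 4 # far from the logistic cap
  fit <- lm(log(od600) ~ time_h, wt[early, ])
  expect_equal(unname(coef(fit)[2]), 0.6, tolerance = 0.01)
  # planted relative rate is recovered through the fitting module
  est <- fitGrowthRates(gg$curves)
  mims <- est$mu[est$strain == paste0(sites$site_id, "E")]
  wts <- est$mu[est$strain == "WT"]
  expect_equal(mean(mims) / mean(wts), 0.85, tolerance = 0.02)
})

test_that("planted log2 effects are recovered in the fold changes", {
  net <- ccmNetwork()
  sites <- syntheticSites(net, 1, 0, effectSize = 2, radius = 1)
  cfg <- cohortConfig(net, sites, nReplicates = 6, noiseSigmaLog2 = 0.1,
                      seed = 21)
  ion <- suppressMessages(generateIonTable(cfg))
  ann <- annotateIons(ion$ions, net)
  gt <- ion$groundTruth[[sites$site_id]]
  koStrain <- paste0(sites$enzyme_id, "_KO")
  prof <- differentialAbundance(ion$ions, ann, koStrain, "WT", "glucose")
  for (m in gt$perturbed) {
    fc <- prof$log2_fc[prof$ion_id == paste0("ion_", m)]
    expect_equal(abs(fc), 2, tolerance = 0.2)
  }
})

test_that("full concordance makes mutant and knockout profiles correlate", {
  net <- ccmNetwork()
  sites <- syntheticSites(net, 1, 0, effectSize = 2, radius = 3)
  cfg <- cohortConfig(net, sites, nReplicates = 6, noiseSigmaLog2 = 0.02,
                      concordance = 1, seed = 8)
  ion <- suppressMessages(generateIonTable(cfg))
  ann <- annotateIons(ion$ions, net)
  profs <- strainProfiles(ion$ions, ann)
  gt <- ion$groundTruth[[sites$site_id]]
  koLikeStrain <- paste0(sites$site_id,
                         if (gt$ko_like_mutant == "mimetic") "E" else "A")
  sc <- spearmanProfileCorrelation(
    profs[[paste(koLikeStrain, "glucose", sep = "|")]],
    profs[[paste0(sites$enzyme_id, "_KO|glucose")]])
  expect_gt(sc$rho, 0.4)
  expect_lt(sc$p_value, 0.001)
})

test_that("decoy ions receive no annotation", {
  co <- makeDemoCohort()
  decoys <- grepl("^decoy_", co$ann$ion_id)
  expect_true(any(decoys))
  expect_false(any(co$ann$annotated[decoys]))
})

test_that("assay traces recover their planted parameters when noiseless", {
  tr <- generateAssayTraces(tmTrue = 55, slopeTrue = 0.04, noiseSd = 0)
  tm <- estimateTm(tr$melt$temperature_c, tr$melt$fluorescence)
  expect_equal(tm$tm, 55, tolerance = 1e-6)
  expect_false(tm$boundary)
  ir <- initialRate(tr$kinetic$time_min, tr$kinetic$absorbance,
                    tr$kinetic$protein_mg_ml)
  expect_equal(ir$rate, 0.04, tolerance = 1e-8)
})
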