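# hand-built evidence rows for rule-level tests
evRow <- function(site = "s1", mt = "mimetic", cond = "glucose",
                  growth = NA, rel = NA_real_, local = NA, ko = NA,
                  n = NA_integer_) {
  data.frame(site_id = site, enzyme_id = "tpiA", mutant_type = mt,
             strain = paste0(site, "_", mt), condition = cond,
             growth_sig = growth, growth_rel_rate = rel,
             local_change = local, ko_corr_pass = ko,
             rho = NA_real_, rho_p = NA_real_, n_changing = n,
             global_change = FALSE)
}

mkEvidenceSet <- function(rows, thr = 8, med = 4) {
  new("EvidenceSet", evidence = rows, globalThreshold = thr,
      medianChanging = med)
}

test_that("functionality is the OR of growth, local and knockout evidence", {
  growthOnly <- mkEvidenceSet(rbind(
    evRow(growth = TRUE, rel = 0.8, local = FALSE, ko = FALSE),
    evRow(mt = "abolishing", growth = FALSE, rel = 1, local = FALSE,
          ko = FALSE)))
  call <- callFunctionality(growthOnly)
  expect_true(call$functional)
  expect_equal(call$evidence_classes, "growth")

  silentButMetabolic <- mkEvidenceSet(rbind(
    evRow(growth = FALSE, rel = 1, local = TRUE, ko = TRUE),
    evRow(mt = "abolishing", growth = FALSE, rel = 1, local = FALSE,
          ko = FALSE)))
  call <- callFunctionality(silentButMetabolic)
  expect_true(call$functional)
  expect_equal(call$evidence_classes, "local_change,ko_correlation")

  nothing <- mkEvidenceSet(rbind(
    evRow(growth = FALSE, rel = 1, local = FALSE, ko = NA),
    evRow(mt = "abolishing")))
  call <- callFunctionality(nothing)
  expect_false(call$functional)
  expect_equal(call$sign, "n.d.")
})

test_that("n.d. entries never act as evidence and global change never ranks", {
  allNd <- mkEvidenceSet(rbind(evRow(), evRow(mt = "abolishing")))
  expect_false(callFunctionality(allNd)$functional)

  globalOnly <- mkEvidenceSet({
    r <- evRow(growth = FALSE, rel = 1, local = FALSE, ko = FALSE, n = 30)
    r$global_change <- TRUE
    r
  })
  call <- callFunctionality(globalOnly)
  expect_false(call$functional) # many distant changes alone do not rank
  expect_true(call$global_change_any)
})

test_that("adding evidence never flips a functional site to non-functional", {
  base <- rbind(
    evRow(growth = TRUE, rel = 0.8, local = FALSE, ko = FALSE),
    evRow(mt = "abolishing", growth = FALSE, rel = 1, local = NA, ko = NA))
  expect_true(callFunctionality(mkEvidenceSet(base))$functional)
  # flip every NA cell to positive evidence, one at a time and all at once
  more <- base
  more$local_change[2] <- TRUE
  more$ko_corr_pass[2] <- TRUE
  more$growth_sig[2] <- TRUE
  more$growth_rel_rate[2] <- 0.7
  expect_true(callFunctionality(mkEvidenceSet(more))$functional)
})

test_that("sign inference follows the knockout-resemblance precedence", {
  # abolishing behaves like the knockout, mimetic like wild type: activating
  plus <- rbind(
    evRow(mt = "abolishing", growth = TRUE, rel = 0.8, local = TRUE,
          ko = TRUE),
    evRow(mt = "mimetic", growth = FALSE, rel = 1.02, local = FALSE,
          ko = FALSE))
  expect_equal(inferEffectSign(plus), "+")
  # the mirror case: inhibitory phosphorylation
  minus <- rbind(
    evRow(mt = "mimetic", growth = TRUE, rel = 0.6, local = TRUE, ko = TRUE),
    evRow(mt = "abolishing", growth = FALSE, rel = 0.99, local = FALSE,
          ko = FALSE))
  expect_equal(inferEffectSign(minus), "-")
  # both mutants defective without knockout data: undetermined
  both <- rbind(
    evRow(mt = "mimetic", growth = TRUE, rel = 0.8, local = TRUE, ko = NA),
    evRow(mt = "abolishing", growth = TRUE, rel = 0.7, local = TRUE,
          ko = NA))
  expect_equal(inferEffectSign(both), "undetermined")
})

test_that("sign inference is anti-symmetric under swapping the mutants", {
  swapTypes <- function(rows) {
    rows$mutant_type <- c(mimetic = "abolishing",
                          abolishing = "mimetic",
                          knockout = "knockout")[rows$mutant_type]
    rows
  }
  set.seed(91)
  opposite <- c("+" = "-", "-" = "+", undetermined = "undetermined")
  for (i in 1:30) {
    rows <- rbind(
      evRow(mt = "mimetic", growth = sample(c(TRUE, FALSE, NA), 1),
            rel = runif(1, 0.5, 1.2),
            local = sample(c(TRUE, FALSE, NA), 1),
            ko = sample(c(TRUE, FALSE, NA), 1)),
      evRow(mt = "abolishing", growth = sample(c(TRUE, FALSE, NA), 1),
            rel = runif(1, 0.5, 1.2),
            local = sample(c(TRUE, FALSE, NA), 1),
            ko = sample(c(TRUE, FALSE, NA), 1)))
    expect_equal(inferEffectSign(swapTypes(rows)),
                 unname(opposite[inferEffectSign(rows)]))
  }
})

test_that("a single knockout-concordant mutant decides the sign alone", {
  onlyAbol <- evRow(mt = "abolishing", growth = FALSE, rel = 1, local = TRUE,
                    ko = TRUE)
  expect_equal(inferEffectSign(onlyAbol), "+")
  onlyMim <- evRow(mt = "mimetic", growth = FALSE, rel = 1, local = TRUE,
                   ko = TRUE)
  expect_equal(inferEffectSign(onlyMim), "-")
  # a lone mutant with no knockout concordance cannot be signed
  lone <- evRow(mt = "abolishing", growth = TRUE, rel = 0.8, local = TRUE,
                ko = FALSE)
  expect_equal(inferEffectSign(lone), "undetermined")
})

test_that("growth-concordance with a knockout counts as resemblance", {
  rows <- rbind(
    evRow(mt = "abolishing", growth = TRUE, rel = 0.7, local = FALSE,
          ko = NA),
    evRow(mt = "mimetic", growth = FALSE, rel = 1.0, local = FALSE,
          ko = NA),
    evRow(mt = "knockout", growth = TRUE, rel = 0.6))
  expect_equal(inferEffectSign(rows), "+")
  # without a knockout growth defect the same data are not concordant
  rows$growth_sig[3] <- FALSE
  rows$growth_rel_rate[3] <- 1
  expect_equal(inferEffectSign(rows), "undetermined")
})

test_that("evidence assembly applies the distance and correlation rules", {
  co <- makeDemoCohort(nFunctional = 2, nNull = 1, seed = 23)
  ev <- evidenceTable(co$evidence)
  sites <- siteSheet(co$cfg)
  gt <- co$ion$groundTruth
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    truth <- gt[[sid]]
    rows <- ev[ev$site_id == sid & ev$mutant_type != "knockout", ]
    if (truth$functional) {
      koLike <- rows[rows$mutant_type == truth$ko_like_mutant, ]
      expect_true(any(koLike$local_change) || any(koLike$ko_corr_pass))
    }
  }
  # the global threshold is twice the median changing-metabolite count
  mutRows <- ev$mutant_type != "knockout" & !is.na(ev$n_changing)
  expect_equal(globalThreshold(co$evidence),
               2 * median(ev$n_changing[mutRows]))
  # unknown enzyme fails loudly
  badSites <- sites
  badSites$enzyme_id[1] <- "unknownEnz"
  expect_error(
    assembleEvidence(badSites, co$net, co$profiles, co$ann,
                     correlations = co$corr),
    badSites$site_id[1])
})

test_that("planted cohorts are called and signed correctly end to end", {
  co <- makeDemoCohort(nFunctional = 3, nNull = 2, nReplicates = 6,
                       seed = 41)
  truthFun <- vapply(co$ion$groundTruth, `[[`, logical(1), "functional")
  truthSign <- vapply(co$ion$groundTruth, `[[`, character(1), "sign")
  calls <- co$calls[match(names(truthFun), co$calls$site_id), ]
  expect_equal(sum(calls$functional & truthFun), 3)
  expect_lte(sum(calls$functional & !truthFun), 1)
  signed <- truthFun & calls$functional
  expect_gte(sum(calls$sign[signed] == truthSign[signed]), 2)
  smry <- summarizeCohort(co$calls, co$evidence)
  expect_equal(smry$n_sites, 5)
  expect_gte(smry$n_functional, 3)
})
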