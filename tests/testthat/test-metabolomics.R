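test_that("accurate-mass annotation applies the 0.001 Da rule", {
  net <- ccmNetwork()
  glcMH <- neutralMonoisotopicMass("C6H12O6") - PROTON_MASS
  expect_equal(glcMH, 179.05611, tolerance = 1e-5)
  ions <- data.frame(
    ion_id = c("hit", "edge", "miss"),
    observed_mass = c(glcMH, glcMH + 0.001, glcMH + 0.0019))
  ann <- annotateIons(ions, net)
  # hexoses are isobaric: glucose and fructose both match
  expect_setequal(ann$metabolite_ids[[1]], c("glc", "fru"))
  expect_true(ann$annotated[2])  # exactly at tolerance still matches
  expect_false(ann$annotated[3]) # 0.0019 Da away does not
})

test_that("fold changes and Welch tests follow the pooled-replicate rules", {
  intensity <- rbind(
    ion1 = c(8, 8, 8, 2, 2, 2),
    ion2 = c(4, 5, 6, 4, 5, 6),
    ion3 = c(0, 0, 0, 2, 2, 2))
  samples <- data.frame(
    strain = rep(c("mut", "WT"), each = 3),
    condition = "glucose", replicate = rep(1:3, 2))
  ions <- IonSet(intensity, rep(179.05611, 3), samples)
  ann <- annotateIons(ions, ccmNetwork())
  prof <- differentialAbundance(ions, ann, "mut", "WT", "glucose")
  expect_equal(prof$log2_fc[prof$ion_id == "ion1"], 2)
  # identical groups: fc 0, degenerate p 1 per replicate-pairing convention
  expect_equal(prof$log2_fc[prof$ion_id == "ion2"], 0)
  expect_equal(prof$p_value[prof$ion_id == "ion2"], 1)
  # zero group mean: undefined fc, excluded from the profile
  expect_true(prof$excluded[prof$ion_id == "ion3"])
  expect_true(is.na(prof$log2_fc[prof$ion_id == "ion3"]))
})

test_that("BH correction matches the hand step-up and a brute-force oracle", {
  expect_equal(p.adjust(c(0.005, 0.01, 0.03, 0.04), method = "BH"),
               c(0.02, 0.02, 0.04, 0.04))
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(p.adjust(p, method = "BH"), bhBrute(p), tolerance = 1e-12)
  }
})

test_that("log2 fold changes are anti-symmetric in the group order", {
  co <- makeDemoCohort()
  key <- names(co$profiles)[1]
  strain <- strsplit(key, "|", fixed = TRUE)[[1]][1]
  fwd <- co$profiles[[key]]
  # swap roles: wild type "mutant" against the strain as reference
  rev <- differentialAbundance(co$ion$ions, co$ann, "WT", strain, "glucose")
  ok <- !fwd$excluded & !rev$excluded
  expect_equal(fwd$log2_fc[ok], -rev$log2_fc[ok], tolerance = 1e-12)
})

test_that("the percentile cutoff uses linear interpolation and is monotone", {
  mk <- function(v) data.frame(strain = "s", condition = "c",
                               ion_id = paste0("i", seq_along(v)),
                               annotated = TRUE, log2_fc = v,
                               p_value = 0.5, q_value = 0.5,
                               excluded = FALSE)
  expect_equal(globalFcCutoff(mk(rep(0.5, 30)))$cutoff, 0.5)
  pool <- seq(0, 0.99, by = 0.01)
  expect_equal(globalFcCutoff(mk(pool))$cutoff, 0.9405)
  # nearest-rank alternative
  expect_equal(globalFcCutoff(mk(pool), type = "nearest")$cutoff, 0.94)
  # adding values below the cutoff never raises it
  set.seed(4)
  for (i in 1:10) {
    v <- abs(rnorm(60))
    c1 <- globalFcCutoff(mk(v))$cutoff
    extra <- runif(20, 0, c1 * 0.99)
    c2 <- globalFcCutoff(mk(c(v, extra)))$cutoff
    expect_lte(c2, c1 + 1e-12)
  }
  expect_error(globalFcCutoff(mk(rep(0.1, 5))), ">= 20")
})

test_that("significance needs both the fold-change and the FDR condition", {
  prof <- data.frame(strain = "s", condition = "c",
                     ion_id = c("a", "b", "c"),
                     annotated = TRUE,
                     log2_fc = c(0.5, 0.5, 0.2),
                     p_value = c(0.001, 0.1, 1e-5),
                     q_value = c(0.01, 0.2, 0.001),
                     excluded = FALSE)
  out <- applySignificance(prof, cutoff = 0.38)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
})

test_that("changing-metabolite counts follow the isobaric-set policy", {
  ann <- data.frame(ion_id = c("i1", "i2", "i3"))
  ann$metabolite_ids <- list(c("glc", "fru"), "pyr", c("glc", "fru"))
  ann$annotated <- TRUE
  prof <- data.frame(ion_id = c("i1", "i2", "i3"),
                     significant = c(TRUE, TRUE, TRUE))
  expect_equal(countChangingMetabolites(prof, ann, "all"), 3)
  expect_equal(countChangingMetabolites(prof, ann, "once"), 2)
  prof$significant <- FALSE
  expect_equal(countChangingMetabolites(prof, ann), 0L)
})

test_that("Spearman correlation matches rank-then-Pearson including ties", {
  expect_equal(spearmanCorrelation(c(1, 2, 3), c(2, 4, 9))$rho, 1)
  expect_equal(spearmanCorrelation(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(rank(c(1, 2, 2, 4)), c(1, 2.5, 2.5, 4))
  set.seed(12)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    x <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01)
    y <- sample(1:8, n, replace = TRUE)
    sc <- spearmanCorrelation(x, y)
    expect_equal(sc$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_gte(sc$rho, -1)
    expect_lte(sc$rho, 1)
  }
  # invariant under strictly increasing transforms
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(spearmanCorrelation(exp(x), y)$rho,
               spearmanCorrelation(x, y)$rho)
})

test_that("profile correlation uses shared annotated ions and flags n.d.", {
  co <- makeDemoCohort()
  keys <- names(co$profiles)
  sc <- spearmanProfileCorrelation(co$profiles[[keys[1]]],
                                   co$profiles[[keys[2]]])
  expect_false(sc$nd)
  expect_gte(sc$n_shared, 10)
  tiny <- co$profiles[[keys[1]]][1:5, ]
  expect_true(spearmanProfileCorrelation(tiny, co$profiles[[keys[2]]])$nd)
})

test_that("rescaling all intensities leaves every fold change unchanged", {
  co <- makeDemoCohort()
  scaled <- IonSet(SummarizedExperiment::assay(co$ion$ions) * 37,
                   SummarizedExperiment::rowData(co$ion$ions)$observed_mass,
                   as.data.frame(SummarizedExperiment::colData(co$ion$ions)))
  p1 <- co$profiles[[1]]
  p2 <- differentialAbundance(scaled, co$ann, p1$strain[1], "WT", "glucose")
  expect_equal(p1$log2_fc, p2$log2_fc, tolerance = 1e-12)
})
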