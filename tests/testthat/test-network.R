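test_that("monoisotopic masses match hand-computed values", {
  expect_equal(neutralMonoisotopicMass("C6H12O6"), 180.06339, tolerance = 1e-7)
  expect_equal(neutralMonoisotopicMass("H2O"), 18.010565, tolerance = 1e-7)
  # count aggregation and implicit count of 1
  expect_equal(neutralMonoisotopicMass("CH3COOH"),
               neutralMonoisotopicMass("C2H4O2"))
  expect_error(neutralMonoisotopicMass(""), "formula")
  expect_error(neutralMonoisotopicMass("C6H12Xx2"), "Xx")
})

test_that("model loading preserves counts and rejects dangling references", {
  net <- ccmNetwork()
  expect_s4_class(net, "MetabolicNetwork")
  expect_equal(nrow(metaboliteTable(net)), 56)
  expect_equal(nrow(reactionTable(net)), 51)
  expect_true(all(c("tpiA", "gnd", "pykF", "pta") %in% enzymeIds(net)))
  # isobaric groups share masses computed from identical formulas
  mt <- metaboliteTable(net)
  expect_equal(mt$monoisotopic_mass[mt$metabolite_id == "glc"],
               mt$monoisotopic_mass[mt$metabolite_id == "fru"])

  mets <- data.frame(metabolite_id = c("a", "b"), name = c("a", "b"),
                     formula = "H2O", is_currency = FALSE)
  rxns <- data.frame(reaction_id = "r1", enzyme_id = "e1",
                     substrates = "a", products = "X99", reversible = FALSE)
  expect_error(MetabolicNetwork(mets, rxns), "X99")
})

test_that("chain distances follow the reaction-step definition", {
  net <- chainNetwork(6)
  d <- reactionStepDistance(net, "E1")
  expect_equal(d[["M0"]], 1) # own substrate
  expect_equal(d[["M1"]], 1) # own product
  expect_equal(d[["M2"]], 2)
  expect_equal(d[["M6"]], 6)
  expect_equal(reactionStepDistance(net, "E1", "M2"), 2)
  expect_setequal(localNetwork(net, "E1", maxSteps = 5),
                  paste0("M", 0:5))
  expect_length(localNetwork(net, "E1", maxSteps = 0), 0)
  expect_error(reactionStepDistance(net, "nope"), "unknown enzyme")
  expect_error(reactionStepDistance(net, "E1", "nope"), "unknown metabolite")
})

test_that("currency exclusion severs cofactor-only connections", {
  mets <- data.frame(
    metabolite_id = c("a", "b", "atp", "c", "d"),
    name = c("a", "b", "ATP", "c", "d"),
    formula = "C3H4O3",
    is_currency = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  rxns <- data.frame(reaction_id = c("r1", "r2"),
                     enzyme_id = c("e1", "e2"),
                     substrates = c("a;atp", "c;atp"),
                     products = c("b", "d"),
                     reversible = FALSE)
  net <- MetabolicNetwork(mets, rxns)
  expect_equal(reactionStepDistance(net, "e1", "d"), Inf)
  expect_equal(reactionStepDistance(net, "e1", "d",
                                    excludeCurrency = FALSE), 2)
  # the currency species itself is outside the traversed graph
  expect_equal(reactionStepDistance(net, "e1", "atp"), Inf)
})

test_that("distance is symmetric under reversal of all reactions", {
  set.seed(42)
  for (i in 1:10) {
    net <- randomNetwork(sample(3:7, 1))
    rev <- reactionTable(net)
    tmp <- rev$substrates; rev$substrates <- rev$products
    rev$products <- tmp
    netRev <- MetabolicNetwork(metaboliteTable(net), rev)
    for (e in enzymeIds(net)) {
      expect_equal(reactionStepDistance(net, e),
                   reactionStepDistance(netRev, e))
    }
  }
})

test_that("adding a reaction never increases a finite distance", {
  set.seed(7)
  for (i in 1:10) {
    net <- randomNetwork(5)
    rxn <- reactionTable(net)
    extra <- rxn[1, ]
    extra$reaction_id <- "rX"
    extra$enzyme_id <- "eX"
    extra$substrates <- list(sample(metaboliteTable(net)$metabolite_id, 1))
    extra$products <- list(sample(metaboliteTable(net)$metabolite_id, 1))
    net2 <- MetabolicNetwork(metaboliteTable(net), rbind(rxn, extra))
    for (e in enzymeIds(net)) {
      d1 <- reactionStepDistance(net, e)
      d2 <- reactionStepDistance(net2, e)
      expect_true(all(d2 <= d1 + 1e-9))
    }
  }
})

test_that("local networks are nested in the radius", {
  net <- ccmNetwork()
  for (e in c("tpiA", "gnd", "icd")) {
    for (k in 0:5) {
      expect_true(all(localNetwork(net, e, k) %in%
                        localNetwork(net, e, k + 1)))
    }
  }
  # saturation: in a fully connected toy net every non-currency metabolite
  # is local
  toy <- MetabolicNetwork(
    data.frame(metabolite_id = c("a", "b", "c"), name = c("a", "b", "c"),
               formula = "H2O", is_currency = FALSE),
    data.frame(reaction_id = c("r1", "r2"), enzyme_id = c("e1", "e2"),
               substrates = c("a", "b"), products = c("b;c", "c"),
               reversible = TRUE))
  expect_setequal(localNetwork(toy, "e1", 5), c("a", "b", "c"))
})

test_that("directed mode respects irreversibility", {
  net <- chainNetwork(4) # all irreversible, M0 -> M4
  dUndir <- reactionStepDistance(net, "E4")
  expect_equal(dUndir[["M0"]], 4)
  dDir <- reactionStepDistance(net, "E4", directed = TRUE)
  expect_equal(dDir[["M4"]], 1)
  expect_equal(dDir[["M0"]], Inf) # cannot walk upstream
})
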