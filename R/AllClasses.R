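#' @import methods
#' @importFrom stats quantile rnorm runif setNames median cor pt p.adjust
#'   var sd
#' @importFrom utils read.delim write.table packageVersion combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Default currency metabolite names
#'
#' Ubiquitous cofactors excluded from network traversal by default, so that
#' shortest paths do not tunnel through shared cofactor pools (every
#' ATP-consuming reaction would otherwise be two steps from every other).
#' Matching is by metabolite name or id, case-insensitive.
#'
#' @export
DEFAULT_CURRENCY <- c(
  "atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "coa", "co2",
  "h2o", "h", "pi", "ppi", "nh4", "o2"
)

#' MetabolicNetwork: bipartite metabolite-reaction model
#'
#' Container for a small genome-scale style metabolic reconstruction: a
#' metabolite table (with elemental formulas and monoisotopic masses), a
#' reaction table (substrate and product id sets, reversibility, catalyzing
#' enzyme), and an enzyme index mapping enzyme/gene labels to their
#' reactions. It is the substrate for accurate-mass ion annotation and for
#' reaction-step distances defining an enzyme's "local network".
#'
#' @slot metabolites data.frame with columns `metabolite_id`, `name`,
#'   `formula`, `monoisotopic_mass`, `is_currency`.
#' @slot reactions data.frame with columns `reaction_id`, `enzyme_id`,
#'   `reversible` and list-columns `substrates`, `products` holding
#'   character vectors of metabolite ids.
#' @slot enzymeIndex named list: enzyme_id -> character vector of
#'   reaction_ids.
#' @export
setClass("MetabolicNetwork",
  slots = c(
    metabolites = "data.frame",
    reactions = "data.frame",
    enzymeIndex = "list"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  needMet <- c("metabolite_id", "name", "formula", "monoisotopic_mass",
               "is_currency")
  needRxn <- c("reaction_id", "enzyme_id", "substrates", "products",
               "reversible")
  if (!all(needMet %in% names(met))) {
    return(paste("metabolite table must have columns:",
                 paste(needMet, collapse = ", ")))
  }
  if (!all(needRxn %in% names(rxn))) {
    return(paste("reaction table must have columns:",
                 paste(needRxn, collapse = ", ")))
  }
  if (anyDuplicated(met$metabolite_id)) {
    msgs <- c(msgs, "duplicated metabolite ids")
  }
  if (anyDuplicated(rxn$reaction_id)) {
    msgs <- c(msgs, "duplicated reaction ids")
  }
  if (any(met$monoisotopic_mass <= 0)) {
    msgs <- c(msgs, "monoisotopic masses must be > 0")
  }
  # mass must agree with the formula it was declared with
  recomputed <- vapply(met$formula, function(f) {
    tryCatch(neutralMonoisotopicMass(f), error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(recomputed)) {
    msgs <- c(msgs, paste("unparseable formula(s):",
                          paste(met$metabolite_id[is.na(recomputed)],
                                collapse = ", ")))
  } else if (any(abs(recomputed - met$monoisotopic_mass) > 1e-6)) {
    bad <- met$metabolite_id[abs(recomputed - met$monoisotopic_mass) > 1e-6]
    msgs <- c(msgs, paste("mass inconsistent with formula for:",
                          paste(bad, collapse = ", ")))
  }
  for (i in seq_len(nrow(rxn))) {
    if (length(rxn$substrates[[i]]) == 0L || length(rxn$products[[i]]) == 0L) {
      msgs <- c(msgs, paste0("reaction ", rxn$reaction_id[i],
                             " has empty substrate or product set"))
    }
  }
  refs <- unique(c(unlist(rxn$substrates), unlist(rxn$products)))
  dangling <- setdiff(refs, met$metabolite_id)
  if (length(dangling) > 0L) {
    bad <- rxn$reaction_id[vapply(seq_len(nrow(rxn)), function(i) {
      any(c(rxn$substrates[[i]], rxn$products[[i]]) %in% dangling)
    }, logical(1))]
    msgs <- c(msgs, paste0("dangling metabolite reference(s) ",
                           paste(dangling, collapse = ", "),
                           " in reaction(s) ", paste(bad, collapse = ", ")))
  }
  # enzyme index must mirror the reaction table
  want <- split(rxn$reaction_id, rxn$enzyme_id)
  have <- object@enzymeIndex
  if (!setequal(names(want), names(have)) ||
      !all(vapply(names(want), function(e) {
        setequal(want[[e]], have[[e]])
      }, logical(1)))) {
    msgs <- c(msgs, "enzyme index inconsistent with reaction table")
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' GrowthCurveSet: microplate OD600 time series
#'
#' Long-format container of growth curves: one OD600 reading per row, keyed
#' by strain, condition and replicate. Times must be strictly increasing
#' within each replicate curve.
#'
#' @slot curves data.frame with columns `strain`, `condition`, `replicate`,
#'   `time_h`, `od600`.
#' @export
setClass("GrowthCurveSet", slots = c(curves = "data.frame"))

setValidity("GrowthCurveSet", function(object) {
  cc <- object@curves
  need <- c("strain", "condition", "replicate", "time_h", "od600")
  if (!all(need %in% names(cc))) {
    return(paste("curves must have columns:", paste(need, collapse = ", ")))
  }
  key <- paste(cc$strain, cc$condition, cc$replicate, sep = "\r")
  ok <- vapply(split(cc$time_h, key), function(t) all(diff(t) > 0), logical(1))
  if (!all(ok)) return("times must be strictly increasing within a replicate")
  TRUE
})

#' IonSet: ion intensity matrix with sample annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one `intensity`
#' assay (ions x samples). `rowData` carries `ion_id` and `observed_mass`
#' (neutralized deprotonated-ion convention: the reported value is the m/z of
#' the singly charged [M-H]- ion, directly comparable to neutral mass minus
#' one proton mass). `colData` carries `strain`, `condition`, `replicate`.
#'
#' @export
setClass("IonSet", contains = "SummarizedExperiment")

setValidity("IonSet", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object)) {
    return("IonSet needs an 'intensity' assay")
  }
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("ion_id", "observed_mass") %in% names(rd))) {
    return("rowData needs 'ion_id' and 'observed_mass'")
  }
  if (!all(c("strain", "condition", "replicate") %in% names(cd))) {
    return("colData needs 'strain', 'condition', 'replicate'")
  }
  if (any(SummarizedExperiment::assay(object, "intensity") < 0, na.rm = TRUE)) {
    return("intensities must be nonnegative")
  }
  TRUE
})

#' EvidenceSet: per-phosphosite evidence grid
#'
#' Long-format evidence table (one row per site x mutant type x condition)
#' plus the cohort-level global-change threshold (twice the median number of
#' changing metabolites over all phosphomutant profiles).
#'
#' @slot evidence data.frame, see [assembleEvidence()].
#' @slot globalThreshold numeric scalar.
#' @slot medianChanging numeric scalar.
#' @export
setClass("EvidenceSet",
  slots = c(
    evidence = "data.frame",
    globalThreshold = "numeric",
    medianChanging = "numeric"
  )
)

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork with", nrow(object@metabolites), "metabolites (",
      sum(object@metabolites$is_currency), "currency ),",
      nrow(object@reactions), "reactions,",
      length(object@enzymeIndex), "enzymes\n")
})

setMethod("show", "GrowthCurveSet", function(object) {
  cc <- object@curves
  cat("GrowthCurveSet:", length(unique(cc$strain)), "strains,",
      length(unique(cc$condition)), "condition(s),",
      nrow(cc), "OD600 readings\n")
})

setMethod("show", "EvidenceSet", function(object) {
  cat("EvidenceSet:", length(unique(object@evidence$site_id)), "sites,",
      nrow(object@evidence), "evidence rows; global-change threshold",
      object@globalThreshold, "(2 x median", object@medianChanging, ")\n")
})

# ---- accessors ----

#' @rdname MetabolicNetwork-class
#' @param object,x A `MetabolicNetwork`.
#' @export
setGeneric("metaboliteTable", function(object) standardGeneric("metaboliteTable"))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("metaboliteTable", "MetabolicNetwork", function(object) {
  object@metabolites
})

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("reactionTable", function(object) standardGeneric("reactionTable"))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("reactionTable", "MetabolicNetwork", function(object) {
  object@reactions
})

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("enzymeIds", function(object) standardGeneric("enzymeIds"))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("enzymeIds", "MetabolicNetwork", function(object) {
  names(object@enzymeIndex)
})

#' @rdname GrowthCurveSet-class
#' @param object A `GrowthCurveSet`.
#' @export
setGeneric("growthCurves", function(object) standardGeneric("growthCurves"))

#' @rdname GrowthCurveSet-class
#' @export
setMethod("growthCurves", "GrowthCurveSet", function(object) object@curves)

#' @rdname EvidenceSet-class
#' @param object An `EvidenceSet`.
#' @export
setGeneric("evidenceTable", function(object) standardGeneric("evidenceTable"))

#' @rdname EvidenceSet-class
#' @export
setMethod("evidenceTable", "EvidenceSet", function(object) object@evidence)

#' @rdname EvidenceSet-class
#' @export
setGeneric("globalThreshold", function(object) standardGeneric("globalThreshold"))

#' @rdname EvidenceSet-class
#' @export
setMethod("globalThreshold", "EvidenceSet", function(object) {
  object@globalThreshold
})

#' Construct a GrowthCurveSet
#'
#' @param curves data.frame with columns `strain`, `condition`, `replicate`,
#'   `time_h`, `od600`.
#' @return A [GrowthCurveSet-class] object.
#' @export
GrowthCurveSet <- function(curves) {
  curves <- as.data.frame(curves)
  new("GrowthCurveSet", curves = curves)
}

#' Construct an IonSet
#'
#' @param intensity Numeric matrix, ions x samples.
#' @param observedMass Numeric vector of neutralized [M-H]- ion masses (Da),
#'   one per row.
#' @param sampleInfo data.frame with columns `strain`, `condition`,
#'   `replicate`, one row per column of `intensity`.
#' @param massWindow Length-2 numeric; ions outside this mass window are
#'   dropped (instrument acquisition range).
#' @return An [IonSet-class].
#' @export
IonSet <- function(intensity, observedMass, sampleInfo,
                   massWindow = c(50, 1000)) {
  intensity <- as.matrix(intensity)
  if (length(observedMass) != nrow(intensity)) {
    stop("observedMass must have one value per intensity row")
  }
  if (nrow(sampleInfo) != ncol(intensity)) {
    stop("sampleInfo must have one row per intensity column")
  }
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- sprintf("ion%04d", seq_len(nrow(intensity)))
  }
  keep <- observedMass >= massWindow[1] & observedMass <= massWindow[2]
  if (!all(keep)) {
    message(sum(!keep), " ion(s) outside the ", massWindow[1], "-",
            massWindow[2], " Da window dropped")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity[keep, , drop = FALSE]),
    rowData = S4Vectors::DataFrame(
      ion_id = rownames(intensity)[keep],
      observed_mass = observedMass[keep]
    ),
    colData = S4Vectors::DataFrame(sampleInfo)
  )
  new("IonSet", se)
}

#' Read an ion intensity table and sample sheet
#'
#' Ion table: long-format TSV `ion_id  observed_mass  sample_id  intensity`;
#' sample sheet: TSV `sample_id  strain  condition  replicate`.
#'
#' @param ionFile,sampleFile Paths to the two TSV files.
#' @param massWindow Passed to [IonSet()].
#' @return An [IonSet-class].
#' @export
readIonTable <- function(ionFile, sampleFile, massWindow = c(50, 1000)) {
  long <- read.delim(ionFile, stringsAsFactors = FALSE)
  samples <- read.delim(sampleFile, stringsAsFactors = FALSE)
  need <- c("ion_id", "observed_mass", "sample_id", "intensity")
  if (!all(need %in% names(long))) {
    stop("ion table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("sample_id", "strain", "condition", "replicate") %in%
           names(samples))) {
    stop("sample sheet must have columns: sample_id, strain, condition, replicate")
  }
  ions <- unique(long[, c("ion_id", "observed_mass")])
  if (anyDuplicated(ions$ion_id)) {
    stop("inconsistent observed_mass for the same ion_id")
  }
  mat <- matrix(NA_real_, nrow(ions), nrow(samples),
                dimnames = list(ions$ion_id, samples$sample_id))
  idx <- cbind(match(long$ion_id, ions$ion_id),
               match(long$sample_id, samples$sample_id))
  if (anyNA(idx[, 2])) stop("ion table references sample_id absent from sheet")
  mat[idx] <- long$intensity
  rownames(samples) <- samples$sample_id
  IonSet(mat, ions$observed_mass,
         samples[, c("strain", "condition", "replicate")],
         massWindow = massWindow)
}
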