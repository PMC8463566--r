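#' Build a MetabolicNetwork from tables
#'
#' @param metabolites data.frame with columns `metabolite_id`, `name`,
#'   `formula`, `is_currency` and optionally `monoisotopic_mass` (filled from
#'   the formula when absent or NA).
#' @param reactions data.frame with columns `reaction_id`, `enzyme_id`,
#'   `reversible` and either list-columns `substrates`/`products` or
#'   semicolon-separated character columns of metabolite ids.
#' @return A [MetabolicNetwork-class] object; all class invariants are
#'   checked at construction.
#' @export
MetabolicNetwork <- function(metabolites, reactions) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (!"monoisotopic_mass" %in% names(metabolites)) {
    metabolites$monoisotopic_mass <- NA_real_
  }
  fill <- is.na(metabolites$monoisotopic_mass)
  if (any(fill)) {
    metabolites$monoisotopic_mass[fill] <-
      vapply(metabolites$formula[fill], neutralMonoisotopicMass, numeric(1))
  }
  metabolites$is_currency <- as.logical(metabolites$is_currency)
  for (col in c("substrates", "products")) {
    if (!is.list(reactions[[col]])) {
      reactions[[col]] <- strsplit(as.character(reactions[[col]]), ";",
                                   fixed = TRUE)
      reactions[[col]] <- lapply(reactions[[col]], trimws)
    }
  }
  reactions$reversible <- as.logical(reactions$reversible)
  enzymeIndex <- split(reactions$reaction_id, reactions$enzyme_id)
  enzymeIndex <- lapply(enzymeIndex, as.character)
  new("MetabolicNetwork",
      metabolites = metabolites,
      reactions = reactions,
      enzymeIndex = enzymeIndex)
}

#' Load a metabolic model from TSV tables
#'
#' Metabolite table: TSV with header
#' `metabolite_id  name  formula  is_currency`;
#' reaction table: TSV with header
#' `reaction_id  enzyme_id  substrates  products  reversible`, substrates and
#' products being semicolon-separated metabolite ids. Monoisotopic masses are
#' computed from the formulas.
#'
#' @param metaboliteFile,reactionFile Paths to the two TSV files.
#' @return A [MetabolicNetwork-class].
#' @examples
#' met <- system.file("extdata", "ecoli_ccm_metabolites.tsv",
#'                    package = "PhosphoScreen")
#' rxn <- system.file("extdata", "ecoli_ccm_reactions.tsv",
#'                    package = "PhosphoScreen")
#' net <- loadMetabolicNetwork(met, rxn)
#' net
#' @export
loadMetabolicNetwork <- function(metaboliteFile, reactionFile) {
  met <- read.delim(metaboliteFile, stringsAsFactors = FALSE)
  rxn <- read.delim(reactionFile, stringsAsFactors = FALSE)
  MetabolicNetwork(met, rxn)
}

# Bipartite igraph: metabolite vertices "m|id", reaction vertices "r|id".
# Undirected by default; directed mode adds substrate->reaction->product arcs
# (plus the reverse for reversible reactions).
.networkGraph <- function(network, excludeCurrency = TRUE, directed = FALSE) {
  met <- network@metabolites
  rxn <- network@reactions
  drop <- if (excludeCurrency) met$metabolite_id[met$is_currency] else character()
  mkeep <- setdiff(met$metabolite_id, drop)
  rvert <- paste0("r|", rxn$reaction_id)
  pairCol <- function(mets, rxns, metFirst) {
    keep <- lengths(mets) > 0L
    if (!any(keep)) return(character(0))
    m <- paste0("m|", unlist(mets[keep]))
    r <- rep(rxns[keep], lengths(mets[keep]))
    if (metFirst) as.vector(rbind(m, r)) else as.vector(rbind(r, m))
  }
  subs <- lapply(rxn$substrates, setdiff, y = drop)
  prods <- lapply(rxn$products, setdiff, y = drop)
  edges <- c(pairCol(subs, rvert, TRUE), pairCol(prods, rvert, FALSE))
  if (directed && any(rxn$reversible)) {
    rev <- rxn$reversible
    edges <- c(edges,
               pairCol(prods[rev], rvert[rev], TRUE),
               pairCol(subs[rev], rvert[rev], FALSE))
  }
  g <- igraph::make_empty_graph(n = 0, directed = directed)
  g <- igraph::add_vertices(g,
    length(mkeep) + nrow(rxn),
    name = c(paste0("m|", mkeep), rvert))
  if (length(edges)) {
    g <- igraph::add_edges(g, match(edges, igraph::V(g)$name))
  }
  g
}

.checkEnzyme <- function(network, enzymeId) {
  if (!enzymeId %in% names(network@enzymeIndex)) {
    stop("unknown enzyme_id: ", enzymeId)
  }
}

#' Reaction-step distances from an enzyme
#'
#' Number of reactions on the shortest path between an enzyme's reaction(s)
#' and each metabolite, on the bipartite metabolite-reaction graph.
#' Substrates and products of the enzyme's own reaction(s) are at distance 1;
#' every additional reaction traversed adds 1. Reactions are traversed
#' undirected regardless of their reversibility flag (perturbations propagate
#' both with and against flux); a directed mode respecting irreversibility is
#' available via `directed = TRUE`. For enzymes catalyzing several reactions
#' the distance is the minimum over those reactions. Currency metabolites are
#' removed from the graph before traversal when `excludeCurrency` is set, and
#' get distance `Inf` themselves.
#'
#' @param network A [MetabolicNetwork-class].
#' @param enzymeId Enzyme/gene label present in the network's enzyme index.
#' @param metaboliteId Optional single metabolite id; when given, a scalar
#'   distance is returned.
#' @param excludeCurrency Drop currency metabolites from traversal
#'   (default TRUE).
#' @param directed Respect irreversibility (default FALSE, undirected).
#' @return Named numeric vector of distances over all metabolites (`Inf` for
#'   unreachable ones), or a scalar when `metaboliteId` is given.
#' @export
reactionStepDistance <- function(network, enzymeId, metaboliteId = NULL,
                                 excludeCurrency = TRUE, directed = FALSE) {
  .checkEnzyme(network, enzymeId)
  allMet <- network@metabolites$metabolite_id
  if (!is.null(metaboliteId) && !metaboliteId %in% allMet) {
    stop("unknown metabolite_id: ", metaboliteId)
  }
  g <- .networkGraph(network, excludeCurrency, directed)
  rxnIds <- network@enzymeIndex[[enzymeId]]
  from <- paste0("r|", rxnIds)
  vnames <- igraph::V(g)$name
  metVerts <- vnames[startsWith(vnames, "m|")]
  d <- igraph::distances(g, v = from, to = metVerts,
                         mode = if (directed) "out" else "all")
  # bipartite path length 2k-1 from a reaction vertex crosses k reactions
  steps <- (d + 1) / 2
  best <- if (nrow(steps) > 1L) apply(steps, 2, min) else steps[1, ]
  out <- setNames(rep(Inf, length(allMet)), allMet)
  out[sub("^m\\|", "", metVerts)] <- best
  if (!is.null(metaboliteId)) out[[metaboliteId]] else out
}

#' Local metabolic network of an enzyme
#'
#' Metabolites within `maxSteps` reaction steps of the enzyme, i.e. exactly
#' those with [reactionStepDistance()] at most `maxSteps`. The enzyme's own
#' reactants (distance 1) are always included for `maxSteps >= 1`;
#' `maxSteps = 0` yields the empty set since no metabolite has distance 0.
#'
#' @inheritParams reactionStepDistance
#' @param maxSteps Maximum number of reaction steps (default 5).
#' @return Character vector of metabolite ids.
#' @export
localNetwork <- function(network, enzymeId, maxSteps = 5,
                         excludeCurrency = TRUE, directed = FALSE) {
  stopifnot(maxSteps >= 0)
  d <- reactionStepDistance(network, enzymeId,
                            excludeCurrency = excludeCurrency,
                            directed = directed)
  names(d)[d <= maxSteps]
}
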