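#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing
#' at least k pathway compounds among n drawn significant compounds, when
#' the pathway holds K of the N universe compounds.
#'
#' @param k observed hits in the pathway
#' @param K pathway size within the universe
#' @param n number of significant compounds drawn
#' @param N universe size
#' @return exact upper-tail probability in (0, 1]
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric arguments: need 0 <= k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Assemble a pathway library
#'
#' @param pathways named list of character vectors (compound ids per
#'   pathway), e.g. from \code{\link{read_gmt}}
#' @param universe character vector of compounds measurable on the platform
#'   and mappable to the library
#' @param graphs optional named list of \code{igraph} graphs (nodes =
#'   compounds, edges = reactions), one per pathway, for topology impact
#' @return object of class \code{pathway_library}; pathway members outside
#'   the universe are recorded under \code{unmapped} and excluded from
#'   testing
#' @export
pathway_library <- function(pathways, universe, graphs = NULL) {
  stopifnot(is.list(pathways), length(names(pathways)) == length(pathways))
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(as.character(universe))
  unmapped <- lapply(pathways, function(p) setdiff(p, universe))
  n_un <- sum(lengths(unmapped))
  if (n_un > 0)
    message(sprintf("pathway_library: %d pathway compound(s) outside the universe (excluded)", n_un))
  trimmed <- lapply(pathways, function(p) intersect(unique(p), universe))
  structure(list(pathways = trimmed, universe = universe,
                 graphs = graphs, unmapped = unmapped),
            class = "pathway_library")
}

#' Pathway over-representation analysis
#'
#' One-sided hypergeometric test per pathway: are the significant
#' ("hit") compounds over-represented among the pathway's compounds,
#' relative to the measurable universe? P-values are adjusted across
#' pathways by Benjamini-Hochberg. When a pathway graph is available, the
#' topology impact of the hits (\code{\link{pathway_impact}}) is reported.
#'
#' @param hits character vector of significant compound ids; entries
#'   outside the universe are dropped with a message
#' @param library a \code{\link{pathway_library}}
#' @return data.frame sorted by p: pathway, k (hits in pathway), K
#'   (pathway size), n (hits in universe), N (universe size), p_hyper,
#'   fdr_bh, impact (NA when no graph)
#' @export
run_ora <- function(hits, library) {
  stopifnot(inherits(library, "pathway_library"))
  hits <- unique(as.character(hits))
  off <- setdiff(hits, library$universe)
  if (length(off))
    message(sprintf("run_ora: %d hit(s) outside the universe dropped", length(off)))
  hits <- intersect(hits, library$universe)
  N <- length(library$universe)
  n <- length(hits)
  keep <- lengths(library$pathways) > 0
  pw <- library$pathways[keep]
  res <- data.frame(
    pathway = names(pw),
    k = vapply(pw, function(p) length(intersect(p, hits)), integer(1)),
    K = lengths(pw),
    n = n, N = N,
    row.names = NULL, stringsAsFactors = FALSE)
  res$p_hyper <- mapply(hypergeom_upper, res$k, res$K, res$n, res$N)
  res$fdr_bh <- stats::p.adjust(res$p_hyper, method = "BH")
  res$impact <- vapply(res$pathway, function(nm) {
    g <- library$graphs[[nm]]
    if (is.null(g)) NA_real_ else pathway_impact(g, hits)
  }, numeric(1))
  res[order(res$p_hyper), , drop = FALSE]
}

#' Topology impact of hits within a pathway graph
#'
#' Node importance is relative betweenness: each node's betweenness
#' centrality divided by the pathway's total, so importances sum to 1
#' whenever any node has positive betweenness (and are all 0 otherwise).
#' The pathway impact is the summed importance of the hit nodes, in [0, 1].
#'
#' @param graph an undirected \code{igraph} graph of the pathway's
#'   compounds
#' @param hits character vector of compound ids (nodes absent from the
#'   graph contribute nothing)
#' @return impact in [0, 1]
#' @export
pathway_impact <- function(graph, hits) {
  stopifnot(inherits(graph, "igraph"))
  btw <- igraph::betweenness(graph, directed = FALSE)
  tot <- sum(btw)
  if (tot <= 0) return(0)
  imp <- btw / tot
  sum(imp[names(imp) %in% as.character(hits)])
}
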