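#' Bipartite species-reaction digraph of a mechanism
#'
#' Builds the directed bipartite graph with one node per species and one node
#' per reaction. An arc runs from species \eqn{A_k} to reaction \eqn{B_j} iff
#' \eqn{\alpha_{jk} > 0} (A_k is a reactant of B_j) and from \eqn{B_j} to
#' \eqn{A_i} iff \eqn{\beta_{ji} > 0} (A_i is a product). Arc weights are the
#' stoichiometric coefficients (1 when not stated explicitly).
#'
#' @param mech A \code{mechanism}.
#' @return A \code{species_reaction_graph} object: a list with the parsed
#'   \code{mechanism}, the \code{alpha}/\code{beta} coefficient matrices, the
#'   per-species outgoing reactions (\code{out_edges}, a list of integer
#'   vectors), and an \code{arcs} data frame (columns \code{from}, \code{to},
#'   \code{weight}, with species named \code{A<i>}-style by their name and
#'   reactions by rate label).
#' @export
build_graph <- function(mech) {
  stopifnot(inherits(mech, "mechanism"))
  alpha <- mech$alpha
  beta <- mech$beta
  n <- n_species(mech)
  m <- n_reactions(mech)
  out_edges <- lapply(seq_len(n), function(i) which(alpha[, i] > 0L))
  sr <- which(alpha > 0L, arr.ind = TRUE)  # (reaction, species)
  rs <- which(beta > 0L, arr.ind = TRUE)
  arcs <- data.frame(
    from = c(mech$species[sr[, 2L]], mech$rate_labels[rs[, 1L]]),
    to = c(mech$rate_labels[sr[, 1L]], mech$species[rs[, 2L]]),
    weight = c(alpha[sr], beta[rs]),
    stringsAsFactors = FALSE)
  structure(
    list(mechanism = mech, alpha = alpha, beta = beta,
         n_species = n, n_reactions = m,
         out_edges = out_edges, arcs = arcs),
    class = "species_reaction_graph")
}

#' @export
print.species_reaction_graph <- function(x, ...) {
  cat(sprintf(
    "Bipartite species-reaction digraph: %d species, %d reactions, %d arcs\n",
    x$n_species, x$n_reactions, nrow(x$arcs)))
  invisible(x)
}

#' Weight of an edge of the bipartite digraph
#'
#' An edge \eqn{[A_k, B_j]} exists iff \eqn{\alpha_{jk} > 0} and carries the
#' negative weight \eqn{K_E = -\alpha_{jk}^2}. The square comes from the
#' Jacobian entry \eqn{\partial w_j u_k^{-\alpha}/\partial u_k} evaluated at
#' mass-action rates: the diagonal contribution of a reactant carries
#' \eqn{\alpha_{jk}^2} (one factor from the stoichiometric loss, one from the
#' derivative), and the edges-only subgraphs must reproduce it. The
#' convention is pinned empirically by the characteristic-polynomial identity
#' on mechanisms with coefficient-2 reactants.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param species,reaction 1-based indices of the species and reaction.
#' @return Negative integer weight.
#' @export
edge_weight <- function(graph, species, reaction) {
  a <- graph$alpha[reaction, species]
  if (a <= 0L) {
    stop(sprintf("no edge: species %d is not a reactant of reaction %d",
                 species, reaction), call. = FALSE)
  }
  -a * a
}

#' Weight of a directed path through one reaction
#'
#' A positive path \eqn{[A_k, B_j, A_i]} (production of A_i from A_k) has
#' weight \eqn{\alpha_{jk}\beta_{ji}}; a negative path
#' \eqn{[A_k, B_j, \bar{A_i}]} (A_k and A_i co-reacting, \eqn{k \ne i}) has
#' weight \eqn{-\alpha_{jk}\alpha_{ji}}. The two orientations of a negative
#' path are distinct paths with equal weight. A positive self-loop
#' \eqn{[A, B, A]} is allowed (autocatalysis); a species is not a negative
#' path partner of itself.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param start,reaction,end 1-based indices.
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @return Nonzero integer weight.
#' @export
path_weight <- function(graph, start, reaction, end,
                        polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  a <- graph$alpha[reaction, start]
  if (a <= 0L) {
    stop("path start is not a reactant of the reaction", call. = FALSE)
  }
  if (polarity == "positive") {
    b <- graph$beta[reaction, end]
    if (b <= 0L) stop("no positive path: end is not a product",
                      call. = FALSE)
    a * b
  } else {
    if (start == end) {
      stop("no negative path: start and end species must differ",
           call. = FALSE)
    }
    a2 <- graph$alpha[reaction, end]
    if (a2 <= 0L) stop("no negative path: end is not a co-reactant",
                       call. = FALSE)
    -a * a2
  }
}

# Internal path record: integer vector c(start, reaction, end, polarity,
# weight), polarity +1/-1. Kept flat for speed.
path_rec <- function(start, reaction, end, polarity, weight) {
  c(start = start, reaction = reaction, end = end, polarity = polarity,
    weight = weight)
}

# Canonical form of a cycle given as a list of path records: rotate so the
# smallest start species comes first. Returns list(paths=, key=, species=,
# reactions=, weight=, order=).
canonical_cycle <- function(paths) {
  starts <- vapply(paths, `[[`, 0, "start")
  rot <- which.min(starts)
  if (rot > 1L) {
    paths <- c(paths[rot:length(paths)], paths[seq_len(rot - 1L)])
    starts <- vapply(paths, `[[`, 0, "start")
  }
  key <- paste(vapply(paths, function(p) {
    paste(p[["start"]], p[["reaction"]], p[["end"]], p[["polarity"]],
          sep = ".")
  }, character(1)), collapse = ";")
  list(paths = paths, key = key, species = starts,
       reactions = vapply(paths, `[[`, 0, "reaction"),
       weight = prod(vapply(paths, `[[`, 0, "weight")),
       order = length(paths))
}

#' Weight of a cycle
#'
#' A cycle is a chain of paths in which the end species of each path is the
#' start species of the next and the start species are pairwise distinct. Its
#' weight is the product of the constituent path weights; the cycle is
#' positive iff it contains an even number of negative paths.
#'
#' @param cycle A cycle as returned by [enumerate_cycles()].
#' @return Nonzero integer weight.
#' @export
cycle_weight <- function(cycle) {
  cycle$weight
}

#' Export the bipartite digraph in DOT format
#'
#' Species nodes are drawn as circles, reaction nodes as boxes, for external
#' rendering with Graphviz.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param path Optional file path; if \code{NULL} the DOT text is returned.
#' @return Character vector of DOT lines (invisibly when written to a file).
#' @export
export_dot <- function(graph, path = NULL) {
  mech <- graph$mechanism
  lines <- c(
    "digraph mechanism {",
    paste0("  \"", mech$species, "\" [shape=circle];"),
    paste0("  \"", mech$rate_labels, "\" [shape=box];"),
    sprintf("  \"%s\" -> \"%s\" [label=%d];",
            graph$arcs$from, graph$arcs$to, graph$arcs$weight),
    "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
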