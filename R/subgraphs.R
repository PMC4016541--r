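# Subgraph enumeration for one fragment.
#
# Every subgraph of a fragment induces an edges-only assignment of the
# fragment: each species starts exactly one component (an edge, or the path
# it contributes to a cycle), and that component runs through one reaction
# the species is a reactant of. Subgraphs are therefore enumerated per
# assignment: for each edges-only assignment of the key, the admissible paths
# form a path graph whose pruned elementary circuits are the cycles, and
# every set of pairwise species-disjoint cycles (a clique of the cycle graph,
# including the empty clique) completed by the paired edges of the uncovered
# species is a subgraph. Subgraph sets of distinct assignments are disjoint
# (the induced assignment is recoverable from the subgraph), so the union
# over assignments enumerates each subgraph of the fragment exactly once;
# results are nevertheless deduplicated by canonical form.

# All positive paths and expanded negative paths of one assignment. A node is
# identified by (start, reaction, end, polarity); the two traversals of a
# negative path are distinct nodes. Each species' paths run through its
# paired reaction only.
assignment_paths <- function(graph, key, assign_rxns) {
  nodes <- list()
  for (s in seq_along(key$species)) {
    i <- key$species[s]
    j <- assign_rxns[s]
    a <- graph$alpha[j, i]
    for (l in key$species) {
      b <- graph$beta[j, l]
      if (b > 0L) {
        nodes[[length(nodes) + 1L]] <- path_rec(i, j, l, 1L, a * b)
      }
      if (l != i && graph$alpha[j, l] > 0L) {
        nodes[[length(nodes) + 1L]] <-
          path_rec(i, j, l, -1L, -a * graph$alpha[j, l])
      }
    }
  }
  nodes
}

# Elementary circuits of the path graph whose paths have pairwise-distinct
# start species. Johnson-style anchored depth-first search: each circuit is
# found once, anchored at its smallest node index, and a branch is abandoned
# as soon as a start species would repeat (the pruning happens during the
# search, never post hoc, so invalid closed walks are never materialized).
path_graph_circuits <- function(nodes) {
  P <- length(nodes)
  if (P == 0L) return(list())
  starts <- vapply(nodes, `[[`, 0, "start")
  ends <- vapply(nodes, `[[`, 0, "end")
  res <- list()
  for (a in seq_len(P)) {
    dfs <- function(chain, used_species) {
      cur <- chain[length(chain)]
      e <- ends[cur]
      if (e == starts[a]) {
        res[[length(res) + 1L]] <<- chain
        return(invisible(NULL))  # any extension would revisit the anchor
      }
      for (q in seq_len(P)) {
        if (q <= a || starts[q] != e || starts[q] %in% used_species) next
        dfs(c(chain, q), c(used_species, starts[q]))
      }
    }
    dfs(a, starts[a])
  }
  res
}

#' Lookup table of subgraph components of a fragment
#'
#' For each fragment species, all components the species can start in some
#' subgraph of the fragment: its edges, positive paths and negative paths
#' through the reactions it is paired with in the fragment's edges-only
#' assignments, with path ends restricted to the fragment's species set.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param key A fragment key (\code{list(species =, reactions =)}).
#' @return Named list (one entry per fragment species, named by species
#'   name); each entry is a data frame with columns \code{type}
#'   (\code{"edge"}, \code{"positive_path"}, \code{"negative_path"}),
#'   \code{start}, \code{reaction}, \code{end} (NA for edges) and
#'   \code{weight}. Species with no admissible component get an empty table
#'   (such a fragment has no subgraphs and weight 0).
#' @export
component_table <- function(graph, key) {
  assigns <- fragment_assignments(graph, key)
  tabs <- lapply(seq_along(key$species), function(s) {
    recs <- list()
    seen <- character(0)
    for (asg in assigns) {
      i <- key$species[s]
      j <- asg[s]
      ek <- paste0("E", j)
      if (!ek %in% seen) {
        seen <- c(seen, ek)
        recs[[length(recs) + 1L]] <- data.frame(
          type = "edge", start = i, reaction = j, end = NA_integer_,
          weight = -graph$alpha[j, i]^2)
      }
      for (p in assignment_paths(graph,
                                 list(species = key$species,
                                      reactions = key$reactions),
                                 asg)) {
        if (p[["start"]] != i) next
        pk <- paste(p[["reaction"]], p[["end"]], p[["polarity"]], sep = ".")
        if (pk %in% seen) next
        seen <- c(seen, pk)
        recs[[length(recs) + 1L]] <- data.frame(
          type = if (p[["polarity"]] > 0) "positive_path"
                 else "negative_path",
          start = i, reaction = p[["reaction"]], end = p[["end"]],
          weight = p[["weight"]])
      }
    }
    if (length(recs) == 0L) {
      data.frame(type = character(0), start = integer(0),
                 reaction = integer(0), end = integer(0),
                 weight = numeric(0))
    } else {
      do.call(rbind, recs)
    }
  })
  names(tabs) <- graph$mechanism$species[key$species]
  tabs
}

#' Enumerate the cycles of a fragment
#'
#' All cycles of the bipartite digraph supported on the fragment: elementary
#' circuits of the fragment's path graphs with pairwise-distinct start
#' species, mapped back to cycles and deduplicated by rotation-invariant
#' canonical form.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param key A fragment key.
#' @return List of cycles sorted by canonical key; each cycle is a list with
#'   \code{paths} (list of path records), \code{species}, \code{reactions}
#'   (one per constituent path, with multiplicity), \code{weight},
#'   \code{order} and \code{key}.
#' @export
enumerate_cycles <- function(graph, key) {
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (asg in fragment_assignments(graph, key)) {
    nodes <- assignment_paths(graph, key, asg)
    for (chain in path_graph_circuits(nodes)) {
      cyc <- canonical_cycle(nodes[chain])
      assign(cyc$key, cyc, envir = seen)
    }
  }
  out <- mget(sort(ls(seen)), envir = seen)
  names(out) <- NULL
  out
}

# Subgraphs of one assignment: cliques of the cycle graph (including the
# empty clique) completed by the paired edges of the uncovered species.
assignment_subgraphs <- function(graph, key, assign_rxns) {
  nodes <- assignment_paths(graph, key, assign_rxns)
  cycles <- lapply(path_graph_circuits(nodes),
                   function(ch) canonical_cycle(nodes[ch]))
  nc <- length(cycles)
  cliques <- list(integer(0))
  if (nc == 1L) {
    cliques <- c(cliques, list(1L))
  } else if (nc > 1L) {
    adj <- matrix(FALSE, nc, nc)
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        adj[i, j] <- adj[j, i] <-
          !any(cycles[[i]]$species %in% cycles[[j]]$species)
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cliques <- c(cliques,
                 lapply(igraph::cliques(g, min = 1L), as.integer))
  }
  lapply(cliques, function(cl) {
    covered <- unlist(lapply(cycles[cl], `[[`, "species"))
    rem <- if (is.null(covered)) seq_along(key$species)
           else which(!(key$species %in% covered))
    edges <- if (length(rem)) {
      data.frame(species = key$species[rem],
                 reaction = assign_rxns[rem],
                 weight = -graph$alpha[cbind(assign_rxns[rem],
                                             key$species[rem])]^2)
    } else {
      data.frame(species = integer(0), reaction = integer(0),
                 weight = numeric(0))
    }
    cyc <- cycles[cl]
    w <- (-1)^length(cyc) *
      prod(vapply(cyc, `[[`, 0, "weight")) *
      prod(-edges$weight)
    skey <- paste(sort(c(
      vapply(cyc, `[[`, "", "key"),
      if (nrow(edges)) sprintf("E%05d.%05d", edges$species, edges$reaction)
    )), collapse = "|")
    list(cycles = cyc, edges = edges, weight = w, key = skey)
  })
}

#' Enumerate all subgraphs of a fragment
#'
#' A subgraph is a species-disjoint collection of cycles and edges in which
#' every fragment species starts exactly one component and the consumed
#' reaction multiset (one reaction per edge, one per constituent path of each
#' cycle) equals the fragment's reaction multiset.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param key A fragment key.
#' @return List of subgraphs sorted by canonical key; each subgraph is a list
#'   with \code{cycles} (list of cycles), \code{edges} (data frame with
#'   columns \code{species}, \code{reaction}, \code{weight} = \eqn{K_E}),
#'   \code{weight} (\eqn{K_g}) and \code{key}.
#' @export
enumerate_subgraphs <- function(graph, key) {
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (asg in fragment_assignments(graph, key)) {
    for (g in assignment_subgraphs(graph, key, asg)) {
      assign(g$key, g, envir = seen)
    }
  }
  out <- mget(sort(ls(seen)), envir = seen)
  names(out) <- NULL
  out
}

#' Weight of a subgraph
#'
#' \eqn{K_g = (-1)^c \prod_{C \in g} K_C \prod_{E \in g} (-K_E)} where c is
#' the number of cycles in the subgraph.
#'
#' @param g A subgraph as returned by [enumerate_subgraphs()].
#' @return Integer weight.
#' @export
subgraph_weight <- function(g) {
  (-1)^length(g$cycles) *
    prod(vapply(g$cycles, `[[`, 0, "weight")) *
    prod(-g$edges$weight)
}

#' Weight and criticality of a fragment
#'
#' The fragment weight is the sum of its subgraph weights; the fragment is
#' critical iff the weight is negative. Critical fragments are the structures
#' whose existence is necessary for multistability (at order = rank of the
#' stoichiometric matrix) and for Turing instability (at order below the
#' number of species).
#'
#' @param graph A \code{species_reaction_graph}.
#' @param key A fragment key.
#' @param keep_subgraphs If \code{TRUE} the subgraph list is retained in the
#'   result.
#' @return List with \code{key}, \code{order}, \code{weight},
#'   \code{critical}, \code{n_subgraphs} and (optionally) \code{subgraphs}.
#' @export
fragment_weight <- function(graph, key, keep_subgraphs = FALSE) {
  sgs <- enumerate_subgraphs(graph, key)
  w <- if (length(sgs)) sum(vapply(sgs, `[[`, 0, "weight")) else 0
  out <- list(key = key, order = length(key$species), weight = w,
              critical = w < 0, n_subgraphs = length(sgs))
  if (keep_subgraphs) out$subgraphs <- sgs
  out
}
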