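# Fragment keys. A fragment of order k is identified by a set of k distinct
# species indices together with a multiset of k reaction indices; the pairing
# between species and reactions is NOT part of the identity (two edges-only
# assignments inducing the same species set and reaction multiset are the
# same fragment, and merging them is what makes each fragment correspond to
# exactly one monomial of the characteristic-polynomial coefficient).

fragment_key_string <- function(species, reactions) {
  paste(paste(species, collapse = ","), paste(reactions, collapse = ","),
        sep = "|")
}

new_fragment_key <- function(species, reactions) {
  list(species = as.integer(species),
       reactions = as.integer(sort(reactions)))
}

# All edges-only assignments realizing a key: ways to pair each fragment
# species with one reaction it is a reactant of, consuming the reaction
# multiset exactly. Returns a list of integer vectors aligned with
# key$species; empty list if the key is not realizable. Species are processed
# fewest-options-first (fail-fast backtracking).
fragment_assignments <- function(graph, key) {
  k <- length(key$species)
  counts <- table(key$reactions)
  rxn_ids <- as.integer(names(counts))
  avail <- as.integer(counts)
  opts <- lapply(key$species, function(i) {
    which(rxn_ids %in% graph$out_edges[[i]])
  })
  ord <- order(lengths(opts))
  res <- list()
  assign_vec <- integer(k)
  recurse <- function(pos) {
    if (pos > k) {
      res[[length(res) + 1L]] <<- rxn_ids[assign_vec]
      return(invisible(NULL))
    }
    s <- ord[pos]
    for (o in opts[[s]]) {
      if (avail[o] > 0L) {
        avail[o] <<- avail[o] - 1L
        assign_vec[s] <<- o
        recurse(pos + 1L)
        avail[o] <<- avail[o] + 1L
      }
    }
  }
  recurse(1L)
  res
}

#' Enumerate all fragments of a given order
#'
#' Uses the one-to-one correspondence between fragments and their edges-only
#' subgraphs: for every k-subset of species and every choice of one outgoing
#' edge per species, the induced (species set, reaction multiset) pair is a
#' fragment key. Distinct choices can induce the same key; keys are
#' deduplicated, so each fragment is emitted exactly once, in lexicographic
#' order (by species set, then reaction multiset). Keys are produced one
#' species subset at a time, so the full candidate list is never materialized.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param k Fragment order, between 1 and the number of species.
#' @return List of fragment keys, each \code{list(species =, reactions =)}
#'   with \code{species} an increasing integer vector of length k and
#'   \code{reactions} a sorted integer vector of length k (possibly with
#'   repeats).
#' @export
enumerate_fragments <- function(graph, k) {
  n <- graph$n_species
  if (k < 1L || k > n) {
    stop(sprintf("order k must be between 1 and %d", n), call. = FALSE)
  }
  out <- list()
  for (subset in species_subsets(graph, k)) {
    keys <- new.env(parent = emptyenv(), hash = TRUE)
    choice_grid_apply(graph$out_edges[subset], function(rxns) {
      srt <- sort(rxns)
      # zero-padded name so that string sort == numeric lexicographic order
      assign(paste(sprintf("%05d", srt), collapse = ","), srt, envir = keys)
    })
    for (kk in sort(ls(keys))) {
      out[[length(out) + 1L]] <- new_fragment_key(subset, get(kk, keys))
    }
  }
  out
}

# k-subsets of species that have at least one outgoing edge, in lexicographic
# order; a species with no outgoing edge can start no component so no
# fragment contains it.
species_subsets <- function(graph, k) {
  eligible <- which(lengths(graph$out_edges) > 0L)
  if (length(eligible) < k) return(list())
  if (k == 1L) return(as.list(eligible))
  combos <- utils::combn(eligible, k, simplify = FALSE)
  combos
}

# Apply f to every element of the cartesian product of the integer vectors in
# `sets` without building the whole grid (odometer loop).
choice_grid_apply <- function(sets, f) {
  k <- length(sets)
  lens <- lengths(sets)
  if (any(lens == 0L)) return(invisible(0L))
  idx <- rep(1L, k)
  count <- 0L
  repeat {
    f(vapply(seq_len(k), function(s) sets[[s]][idx[s]], integer(1)))
    count <- count + 1L
    pos <- k
    while (pos >= 1L) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= lens[pos]) break
      idx[pos] <- 1L
      pos <- pos - 1L
    }
    if (pos < 1L) break
  }
  invisible(count)
}

#' Combinatorial baseline enumeration of fragments
#'
#' Generates every pairing of a k-subset of species (in increasing order)
#' with an ordered k-tuple of reactions, keeps the pairings in which each
#' species is a reactant of its paired reaction, and collapses the survivors
#' to deduplicated fragment keys. This is the brute-force oracle for
#' [enumerate_fragments()] and the cost baseline; it is guarded by a cap on
#' the candidate count.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param k Fragment order.
#' @param cap Maximum number of raw candidates \eqn{\binom{N}{k} R^k} allowed.
#' @return List of fragment keys (same format as [enumerate_fragments()]).
#' @export
combinatorial_fragments <- function(graph, k, cap = 1e6) {
  n <- graph$n_species
  m <- graph$n_reactions
  if (k < 1L || k > n) {
    stop(sprintf("order k must be between 1 and %d", n), call. = FALSE)
  }
  total <- choose(n, k) * m^k
  if (total > cap) {
    stop(sprintf(
      "combinatorial enumeration would generate %.3g candidates (cap %.3g)",
      total, cap), call. = FALSE)
  }
  out <- list()
  for (subset in utils::combn(seq_len(n), k, simplify = FALSE)) {
    keys <- new.env(parent = emptyenv(), hash = TRUE)
    choice_grid_apply(rep(list(seq_len(m)), k), function(rxns) {
      ok <- all(graph$alpha[cbind(rxns, subset)] > 0L)
      if (ok) {
        srt <- sort(rxns)
        assign(paste(sprintf("%05d", srt), collapse = ","), srt,
               envir = keys)
      }
    })
    for (kk in sort(ls(keys))) {
      out[[length(out) + 1L]] <- new_fragment_key(subset, get(kk, keys))
    }
  }
  out
}

#' Raw candidate counts of the two fragment generators
#'
#' Number of raw candidates generated before deduplication and filtering:
#' \eqn{\binom{N}{k} R^k} for the combinatorial method, and the number of
#' edges-only assignments (the k-th elementary symmetric function of the
#' species out-degrees) for the correspondence method. Used for cost
#' reporting; the correspondence count is a lower bound of the combinatorial
#' count by construction.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param k Fragment order.
#' @param method \code{"combinatorial"} or \code{"correspondence"}.
#' @return Numeric count.
#' @export
count_generated <- function(graph, k,
                            method = c("combinatorial", "correspondence")) {
  method <- match.arg(method)
  n <- graph$n_species
  if (k < 1L || k > n) {
    stop(sprintf("order k must be between 1 and %d", n), call. = FALSE)
  }
  if (method == "combinatorial") {
    choose(n, k) * graph$n_reactions^k
  } else {
    deg <- lengths(graph$out_edges)
    # elementary symmetric polynomial e_k(deg) via the recurrence on
    # prod (1 + deg_i x)
    e <- c(1, rep(0, k))
    for (d in deg) {
      e[2:(k + 1)] <- e[2:(k + 1)] + d * e[1:k]
    }
    e[k + 1]
  }
}
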