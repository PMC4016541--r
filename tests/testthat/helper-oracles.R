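# Independent brute-force oracles used by the property tests. These follow
# the definitions directly (generate everything, then filter), deliberately
# avoiding the path-graph / cycle-graph machinery they are checking.

# Multiset-wide component list of a fragment: for each fragment species, all
# edges / positive paths / negative paths through ANY reaction of the key's
# multiset, with path ends inside the key's species set.
oracle_components <- function(graph, key) {
  lapply(seq_along(key$species), function(s) {
    i <- key$species[s]
    out <- list()
    for (j in unique(key$reactions)) {
      a <- graph$alpha[j, i]
      if (a <= 0L) next
      out[[length(out) + 1L]] <-
        list(kind = "edge", start = i, rxn = j, end = NA_integer_,
             w = -a * a)
      for (l in key$species) {
        if (graph$beta[j, l] > 0L) {
          out[[length(out) + 1L]] <- list(kind = "pos", start = i, rxn = j,
                                          end = l, w = a * graph$beta[j, l])
        }
        if (l != i && graph$alpha[j, l] > 0L) {
          out[[length(out) + 1L]] <- list(kind = "neg", start = i, rxn = j,
                                          end = l,
                                          w = -a * graph$alpha[j, l])
        }
      }
    }
    out
  })
}

# Same canonical keys as the package uses, so sets can be compared directly.
oracle_cycle_key <- function(recs) {
  starts <- vapply(recs, `[[`, 0, "start")
  rot <- which.min(starts)
  if (rot > 1L) recs <- c(recs[rot:length(recs)], recs[seq_len(rot - 1L)])
  paste(vapply(recs, function(p) {
    paste(p$start, p$rxn, p$end, if (p$kind == "pos") 1 else -1, sep = ".")
  }, character(1)), collapse = ";")
}

# Combinatorial subgraph oracle: pick one component per species, keep the
# choices whose reaction consumption equals the key multiset and whose chosen
# paths close into cycles (the end species are exactly the path starts, each
# once). Returns a data frame of canonical keys and weights.
oracle_subgraphs <- function(graph, key) {
  comps <- oracle_components(graph, key)
  empty <- data.frame(key = character(0), weight = numeric(0))
  if (any(lengths(comps) == 0L)) return(empty)
  grid <- expand.grid(lapply(comps, seq_along))
  keys <- character(0)
  weights <- numeric(0)
  for (r in seq_len(nrow(grid))) {
    chosen <- lapply(seq_along(comps),
                     function(s) comps[[s]][[grid[r, s]]])
    rxns <- sort(vapply(chosen, `[[`, 0, "rxn"))
    if (!identical(as.integer(rxns), key$reactions)) next
    is_path <- vapply(chosen, function(cc) cc$kind != "edge", TRUE)
    path_sp <- key$species[is_path]
    ends <- vapply(chosen[is_path], `[[`, 0, "end")
    if (length(path_sp)) {
      if (anyDuplicated(ends) || !setequal(ends, path_sp)) next
    }
    # decompose the start -> end permutation into cycles
    cyc_keys <- character(0)
    n_cycles <- 0L
    visited <- integer(0)
    for (st in sort(path_sp)) {
      if (st %in% visited) next
      n_cycles <- n_cycles + 1L
      recs <- list()
      cur <- st
      repeat {
        rec <- chosen[[match(cur, key$species)]]
        recs[[length(recs) + 1L]] <- rec
        visited <- c(visited, cur)
        cur <- rec$end
        if (cur == st) break
      }
      cyc_keys <- c(cyc_keys, oracle_cycle_key(recs))
    }
    edge_keys <- vapply(chosen[!is_path], function(cc) {
      sprintf("E%05d.%05d", cc$start, cc$rxn)
    }, character(1))
    w <- (-1)^n_cycles *
      prod(vapply(chosen[is_path], `[[`, 0, "w")) *
      prod(vapply(chosen[!is_path], function(cc) -cc$w, 0))
    keys <- c(keys, paste(sort(c(cyc_keys, edge_keys)), collapse = "|"))
    weights <- c(weights, w)
  }
  out <- data.frame(key = keys, weight = weights,
                    stringsAsFactors = FALSE)
  out[order(out$key), , drop = FALSE]
}

# All elementary circuits (distinct nodes) of a directed graph given as an
# adjacency list, by plain depth-first search anchored at each node in turn.
naive_circuits <- function(adj_list) {
  P <- length(adj_list)
  res <- list()
  for (a in seq_len(P)) {
    dfs <- function(chain) {
      for (q in adj_list[[chain[length(chain)]]]) {
        if (q == a) {
          res[[length(res) + 1L]] <<- chain
        } else if (q > a && !q %in% chain) {
          dfs(c(chain, q))
        }
      }
    }
    dfs(a)
  }
  res
}

# Naive cycle oracle: full elementary-circuit enumeration on the
# multiset-wide path graph, then post-hoc filtering: pairwise-distinct start
# species, reaction use within the key multiset, and extendability (the
# species outside the cycle can still consume the remaining reactions via
# edges, i.e. the cycle occurs in at least one edges-only assignment).
oracle_cycles <- function(graph, key) {
  comps <- oracle_components(graph, key)
  paths <- Filter(function(cc) cc$kind != "edge",
                  do.call(c, c(comps, list())))
  P <- length(paths)
  if (P == 0L) return(character(0))
  starts <- vapply(paths, `[[`, 0, "start")
  ends <- vapply(paths, `[[`, 0, "end")
  adj_list <- lapply(seq_len(P), function(p) which(starts == ends[p]))
  circuits <- naive_circuits(adj_list)
  keys <- character(0)
  key_counts <- table(key$reactions)
  for (vs in circuits) {
    vs <- as.integer(vs)
    st <- starts[vs]
    if (anyDuplicated(st)) next
    used <- table(vapply(paths[vs], `[[`, 0, "rxn"))
    if (any(!names(used) %in% names(key_counts)) ||
        any(used > key_counts[names(used)])) next
    # extendability: remaining species can consume the remaining multiset
    rem_sp <- setdiff(key$species, st)
    rem_rx <- key$reactions
    for (rx in vapply(paths[vs], `[[`, 0, "rxn")) {
      rem_rx <- rem_rx[-match(rx, rem_rx)]
    }
    if (!oracle_matchable(graph, rem_sp, rem_rx)) next
    # circuits come in rotations from different anchors only once from
    # igraph, but canonicalize anyway before dedup
    keys <- c(keys, oracle_cycle_key(paths[vs]))
  }
  sort(unique(keys))
}

# Can each species take one reaction it is a reactant of, consuming the
# multiset exactly? (brute-force matching)
oracle_matchable <- function(graph, species, reactions) {
  if (length(species) == 0L) return(length(reactions) == 0L)
  i <- species[1L]
  for (pos in which(reactions %in% graph$out_edges[[i]])) {
    if (oracle_matchable(graph, species[-1L], reactions[-pos])) return(TRUE)
  }
  FALSE
}

# Exact rank oracles: Gaussian elimination over GF(p), and floating QR.
rank_mod_p <- function(A, p) {
  A <- matrix(as.numeric(A) %% p, nrow(A), ncol(A))
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(A))) {
    if (row > nrow(A)) break
    piv <- which(A[row:nrow(A), col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) A[c(piv, row), ] <- A[c(row, piv), ]
    # modular inverse via Fermat (p prime, entries small): a^(p-2) mod p
    inv <- pow_mod(A[row, col], p - 2, p)
    A[row, ] <- (A[row, ] * inv) %% p
    if (row < nrow(A)) {
      rows <- (row + 1L):nrow(A)
      A[rows, ] <- (A[rows, ] - outer(A[rows, col], A[row, ])) %% p
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

pow_mod <- function(a, e, p) {
  r <- 1
  a <- a %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * a) %% p
    a <- (a * a) %% p
    e <- e %/% 2
  }
  r
}

# Random fragment key of a graph (realizable by construction), or NULL.
random_key <- function(graph, k) {
  eligible <- which(lengths(graph$out_edges) > 0L)
  if (length(eligible) < k) return(NULL)
  sp <- sort(eligible[sample.int(length(eligible), k)])
  rx <- vapply(sp, function(i) {
    oe <- graph$out_edges[[i]]
    oe[sample.int(length(oe), 1L)]
  }, integer(1))
  list(species = sp, reactions = sort(rx))
}
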