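# Symbolic verification layer.
#
# Every entry of the mass-action Jacobian parametrized by equilibrium
# concentrations u and equilibrium rate values w is a sum of terms
# c * w_j / u_k with integer c, so every quantity handled here (entries,
# minors, characteristic-polynomial coefficients) lives in the ring of
# integer combinations of monomials  w_{j1}...w_{jk} / (u_{i1}...u_{ik})
# with the w's a multiset and the u's a set. A "sympoly" is a list of terms
# list(c = integer, w = sorted integer vector, u = sorted integer vector);
# no general-purpose CAS is needed.

sympoly_zero <- function() list()

sympoly_term <- function(c, w = integer(0), u = integer(0)) {
  list(list(c = c, w = as.integer(sort(w)), u = as.integer(sort(u))))
}

term_key <- function(t) {
  paste(paste(t$w, collapse = "."), paste(t$u, collapse = "."), sep = "/")
}

# Combine like terms, drop zeros, sort by monomial key.
sympoly_normalize <- function(p) {
  if (length(p) == 0L) return(p)
  keys <- vapply(p, term_key, character(1))
  out <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    c_sum <- sum(vapply(p[idx], `[[`, 0, "c"))
    if (c_sum != 0) {
      t <- p[[idx[1L]]]
      t$c <- c_sum
      out[[length(out) + 1L]] <- t
    }
  }
  if (length(out)) out[order(vapply(out, term_key, character(1)))] else out
}

sympoly_add <- function(p, q) sympoly_normalize(c(p, q))

sympoly_neg <- function(p) lapply(p, function(t) {
  t$c <- -t$c
  t
})

sympoly_mul <- function(p, q) {
  if (length(p) == 0L || length(q) == 0L) return(sympoly_zero())
  out <- vector("list", length(p) * length(q))
  i <- 0L
  for (a in p) {
    for (b in q) {
      i <- i + 1L
      out[[i]] <- list(c = a$c * b$c, w = sort(c(a$w, b$w)),
                       u = sort(c(a$u, b$u)))
    }
  }
  sympoly_normalize(out)
}

sympoly_equal <- function(p, q) {
  p <- sympoly_normalize(p)
  q <- sympoly_normalize(q)
  if (length(p) != length(q)) return(FALSE)
  if (length(p) == 0L) return(TRUE)
  all(vapply(seq_along(p), function(i) {
    identical(p[[i]]$w, q[[i]]$w) && identical(p[[i]]$u, q[[i]]$u) &&
      p[[i]]$c == q[[i]]$c
  }, logical(1)))
}

#' Format a symbolic coefficient for display
#'
#' @param p A symbolic expression (list of terms) as returned by
#'   [charpoly_coefficient()] or [graph_coefficient()].
#' @return Character scalar like \code{"w1*w3*w6/(u1*u2*u4) - ..."}; "0" for
#'   the zero expression.
#' @export
format_sympoly <- function(p) {
  p <- sympoly_normalize(p)
  if (length(p) == 0L) return("0")
  pieces <- vapply(p, function(t) {
    mono <- paste0(
      if (length(t$w)) paste0("w", t$w, collapse = "*") else "1",
      if (length(t$u))
        paste0("/(", paste0("u", t$u, collapse = "*"), ")") else "")
    cf <- abs(t$c)
    paste0(if (t$c < 0) " - " else " + ",
           if (cf != 1) paste0(cf, "*") else "", mono)
  }, character(1))
  sub("^ \\+ ", "", sub("^ - ", "-", paste(pieces, collapse = "")))
}

#' Symbolic Jacobian of a mass-action mechanism
#'
#' Entry \eqn{(i, k)} of the Jacobian of \eqn{\dot u = S w(u)}, parametrized
#' by the equilibrium concentrations \eqn{u} and equilibrium rate values
#' \eqn{w}, is \eqn{\sum_j S_{ji} \alpha_{jk} w_j / u_k}.
#'
#' @param mech A \code{mechanism}.
#' @return An n x n matrix of symbolic expressions stored as a list-matrix;
#'   index with \code{J[[i, k]]}.
#' @export
symbolic_jacobian <- function(mech) {
  n <- n_species(mech)
  S <- stoichiometric_matrix(mech)
  J <- matrix(list(), n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      terms <- list()
      for (j in seq_len(n_reactions(mech))) {
        cc <- S[i, j] * mech$alpha[j, k]
        if (cc != 0L) {
          terms <- c(terms, sympoly_term(cc, w = j, u = k))
        }
      }
      J[[i, k]] <- sympoly_normalize(terms)
    }
  }
  J
}

# Determinant of a square list-matrix of sympolys by Laplace expansion with
# dynamic programming over column subsets (bitmask): O(2^k k) polynomial
# operations instead of k!.
sympoly_det <- function(M) {
  k <- nrow(M)
  if (k == 0L) return(sympoly_term(1))
  D <- vector("list", bitwShiftL(1L, k))
  D[[1L]] <- sympoly_term(1)  # empty minor
  for (mask in seq_len(bitwShiftL(1L, k) - 1L)) {
    r <- sum(bitwAnd(bitwShiftR(mask, 0:(k - 1L)), 1L))  # row = popcount
    acc <- sympoly_zero()
    pos <- 0L
    for (col in seq_len(k)) {
      bit <- bitwShiftL(1L, col - 1L)
      if (bitwAnd(mask, bit) == 0L) next
      pos <- pos + 1L  # position of col among the set bits
      entry <- M[[r, col]]
      if (length(entry)) {
        sub <- D[[bitwXor(mask, bit) + 1L]]
        prod_ <- sympoly_mul(entry, sub)
        if ((pos + r) %% 2L == 1L) prod_ <- sympoly_neg(prod_)
        acc <- sympoly_add(acc, prod_)
      }
    }
    D[[mask + 1L]] <- acc
  }
  D[[bitwShiftL(1L, k)]]
}

#' Characteristic-polynomial coefficient from principal minors
#'
#' The coefficient \eqn{a_k(u, w)} is computed as the sum of all k x k
#' principal minors of \eqn{-J(u, w)}; in particular \eqn{a_n = det(-J)}.
#' With this sign convention every critical fragment contributes a negative
#' monomial to \eqn{a_k}.
#'
#' @param J Symbolic Jacobian from [symbolic_jacobian()].
#' @param k Coefficient order, between 1 and n.
#' @return A symbolic expression (list of terms); see [format_sympoly()].
#' @export
charpoly_coefficient <- function(J, k) {
  n <- nrow(J)
  if (k < 1L || k > n) {
    stop(sprintf("k must be between 1 and %d", n), call. = FALSE)
  }
  negJ <- matrix(lapply(J, sympoly_neg), n, n)
  acc <- sympoly_zero()
  for (subset in utils::combn(seq_len(n), k, simplify = FALSE)) {
    acc <- sympoly_add(acc, sympoly_det(negJ[subset, subset, drop = FALSE]))
  }
  acc
}

#' Characteristic-polynomial coefficient from the bipartite digraph
#'
#' Reconstructs \eqn{a_k(u, w)} from the enumerated fragments of order k:
#' each fragment with species \eqn{\{i_1..i_k\}}, reaction multiset
#' \eqn{\{j_1..j_k\}} and weight \eqn{K_{S_k}} contributes the single term
#' \eqn{K_{S_k} \, w_{j_1} \cdots w_{j_k} / (u_{i_1} \cdots u_{i_k})}.
#'
#' @param graph A \code{species_reaction_graph}.
#' @param k Coefficient order.
#' @return A symbolic expression (list of terms).
#' @export
graph_coefficient <- function(graph, k) {
  terms <- list()
  for (key in enumerate_fragments(graph, k)) {
    wf <- fragment_weight(graph, key)
    if (wf$weight != 0) {
      terms <- c(terms,
                 sympoly_term(wf$weight, w = key$reactions,
                              u = key$species))
    }
  }
  sympoly_normalize(terms)
}

#' Verify the fragment / coefficient identity of a mechanism
#'
#' Checks symbolically, for each order k, that the characteristic-polynomial
#' coefficient computed from principal minors of \eqn{-J} equals the one
#' reconstructed from the fragment weights of the bipartite digraph. This is
#' the master correctness check of the whole enumeration (and pins down the
#' sign conventions of the edge and path weights).
#'
#' @param mech A \code{mechanism}.
#' @param k_max Largest order to check (default: number of species).
#' @param n_guard Refuse mechanisms with more species than this (symbolic
#'   expansion grows quickly).
#' @return Data frame with columns \code{k}, \code{equal},
#'   \code{n_terms} and \code{mismatch} (first offending monomial, "" if
#'   none).
#' @export
verify_identity <- function(mech, k_max = n_species(mech), n_guard = 9L) {
  n <- n_species(mech)
  if (n > n_guard) {
    stop(sprintf("mechanism has %d species; symbolic guard is %d", n,
                 n_guard), call. = FALSE)
  }
  J <- symbolic_jacobian(mech)
  graph <- build_graph(mech)
  rows <- lapply(seq_len(min(k_max, n)), function(k) {
    a_min <- sympoly_normalize(charpoly_coefficient(J, k))
    a_gra <- sympoly_normalize(graph_coefficient(graph, k))
    eq <- sympoly_equal(a_min, a_gra)
    mismatch <- ""
    if (!eq) {
      keys_min <- vapply(a_min, term_key, character(1))
      keys_gra <- vapply(a_gra, term_key, character(1))
      bad <- c(setdiff(keys_min, keys_gra), setdiff(keys_gra, keys_min))
      if (length(bad) == 0L) {
        shared <- intersect(keys_min, keys_gra)
        coeffs_differ <- shared[vapply(shared, function(kk) {
          a_min[[match(kk, keys_min)]]$c != a_gra[[match(kk, keys_gra)]]$c
        }, logical(1))]
        bad <- coeffs_differ
      }
      mismatch <- if (length(bad)) bad[1L] else "<structural>"
    }
    data.frame(k = k, equal = eq, n_terms = length(a_min),
               mismatch = mismatch, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
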