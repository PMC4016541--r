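#' Parse a plain-text reaction mechanism
#'
#' Reads a mass-action mechanism written one elementary reaction per line in
#' the form \code{"LHS -> RHS ; label"}. Terms on each side are joined by
#' \code{"+"}; a term is \code{"[coeff] name"} with \code{coeff} a positive
#' integer defaulting to 1. An empty side (or the single token \code{"0"})
#' denotes the empty complex, so \code{"A1 -> ; k1"} is an outflow and
#' \code{"-> A1 ; k2"} an inflow. \code{"#"} starts a comment; blank lines are
#' ignored. Reversible reactions are written as two lines and become two
#' reactions.
#'
#' Species are numbered 1-based in order of first appearance (left side before
#' right side, left to right); reactions are numbered in file order.
#'
#' @param text Character scalar (entire file contents) or character vector of
#'   lines.
#' @return A \code{mechanism} object: a list with elements
#'   \item{species}{character vector of species names; the index of a species
#'     is its position.}
#'   \item{alpha}{m x n integer matrix of reactant stoichiometric coefficients
#'     \eqn{\alpha_{ji}}.}
#'   \item{beta}{m x n integer matrix of product coefficients
#'     \eqn{\beta_{ji}}.}
#'   \item{rate_labels}{character vector of the m rate-constant labels.}
#' @seealso [read_mechanism()], [serialize_mechanism()],
#'   [stoichiometric_matrix()]
#' @export
parse_mechanism <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("#.*$", "", text)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0L) {
    stop("mechanism file contains no reactions", call. = FALSE)
  }

  species <- character(0)
  sp_index <- function(name) {
    i <- match(name, species)
    if (is.na(i)) {
      species <<- c(species, name)
      i <- length(species)
    }
    i
  }

  parse_side <- function(side, lineno) {
    side <- trimws(side)
    if (side == "" || side == "0") {
      return(integer(0))
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
    out <- integer(0)
    for (term in terms) {
      m <- regmatches(term,
        regexec("^([0-9]+[ \t]+)?([A-Za-z_][A-Za-z0-9_]*)$", term))[[1L]]
      if (length(m) == 0L) {
        stop(sprintf("line %d: malformed term '%s'", lineno, term),
             call. = FALSE)
      }
      coeff <- if (m[2L] == "") 1L else as.integer(trimws(m[2L]))
      if (is.na(coeff) || coeff < 1L) {
        stop(sprintf("line %d: invalid coefficient in term '%s'", lineno,
                     term), call. = FALSE)
      }
      i <- sp_index(m[3L])
      if (i > length(out)) out[length(out) + 1L:(i - length(out))] <- 0L
      out[i] <- out[i] + coeff
    }
    out
  }

  rxns <- vector("list", length(keep))
  labels <- character(length(keep))
  for (r in seq_along(keep)) {
    lineno <- keep[r]
    line <- trimws(lines[lineno])
    semi <- regexpr(";", line, fixed = TRUE)
    if (semi < 0L) {
      stop(sprintf("line %d: missing ';' before rate label", lineno),
           call. = FALSE)
    }
    label <- trimws(substring(line, semi + 1L))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", label)) {
      stop(sprintf("line %d: invalid rate label '%s'", lineno, label),
           call. = FALSE)
    }
    body <- substring(line, 1L, semi - 1L)
    arrow <- regexpr("->", body, fixed = TRUE)
    if (arrow < 0L) {
      stop(sprintf("line %d: missing '->'", lineno), call. = FALSE)
    }
    lhs <- parse_side(substring(body, 1L, arrow - 1L), lineno)
    rhs <- parse_side(substring(body, arrow + 2L), lineno)
    if (length(lhs) == 0L && length(rhs) == 0L) {
      stop(sprintf("line %d: reaction with empty reactants and products",
                   lineno), call. = FALSE)
    }
    rxns[[r]] <- list(lhs = lhs, rhs = rhs)
    labels[r] <- label
  }
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate rate label '%s'",
                 labels[duplicated(labels)][1L]), call. = FALSE)
  }

  n <- length(species)
  m <- length(rxns)
  alpha <- matrix(0L, m, n, dimnames = list(labels, species))
  beta <- matrix(0L, m, n, dimnames = list(labels, species))
  for (r in seq_len(m)) {
    lhs <- rxns[[r]]$lhs
    rhs <- rxns[[r]]$rhs
    if (length(lhs)) alpha[r, seq_along(lhs)] <- lhs
    if (length(rhs)) beta[r, seq_along(rhs)] <- rhs
  }

  structure(
    list(species = species, alpha = alpha, beta = beta,
         rate_labels = labels),
    class = "mechanism")
}

#' Read a mechanism from a file
#'
#' @param path Path to a mechanism text file (see [parse_mechanism()] for the
#'   dialect).
#' @return A \code{mechanism} object.
#' @export
read_mechanism <- function(path) {
  parse_mechanism(readLines(path, warn = FALSE))
}

#' Serialize a mechanism to the canonical text dialect
#'
#' Produces text that [parse_mechanism()] maps back to an identical
#' mechanism (round-trip identity). Coefficients equal to 1 are omitted and
#' an empty side is written as nothing (e.g. \code{"A1 -> ; k1"}).
#'
#' @param mech A \code{mechanism}.
#' @return Character vector, one reaction per line.
#' @export
serialize_mechanism <- function(mech) {
  side_txt <- function(coeffs) {
    idx <- which(coeffs > 0L)
    if (length(idx) == 0L) return("")
    paste(ifelse(coeffs[idx] > 1L,
                 paste(coeffs[idx], mech$species[idx]),
                 mech$species[idx]),
          collapse = " + ")
  }
  vapply(seq_len(n_reactions(mech)), function(j) {
    lhs <- side_txt(mech$alpha[j, ])
    rhs <- side_txt(mech$beta[j, ])
    body <- trimws(paste(lhs, "->", rhs))
    paste(body, ";", mech$rate_labels[j])
  }, character(1))
}

#' Number of species / reactions of a mechanism
#' @param mech A \code{mechanism}.
#' @return Integer scalar.
#' @export
n_species <- function(mech) length(mech$species)

#' @rdname n_species
#' @export
n_reactions <- function(mech) nrow(mech$alpha)

#' @export
print.mechanism <- function(x, ...) {
  cat(sprintf("Mass-action mechanism: %d species, %d reactions\n",
              n_species(x), n_reactions(x)))
  cat(paste0("  ", serialize_mechanism(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a mechanism
#'
#' Entry \eqn{(i, j)} is \eqn{\beta_{ji} - \alpha_{ji}}, the net production of
#' species i by reaction j, so the mass-action model reads
#' \eqn{\dot u = S w(u)}.
#'
#' @param mech A \code{mechanism}.
#' @return An n x m integer matrix (species in rows, reactions in columns).
#' @export
stoichiometric_matrix <- function(mech) {
  t(mech$beta - mech$alpha)
}

#' Exact rank of an integer matrix
#'
#' Rank over the rationals by fraction-free (Bareiss) Gaussian elimination:
#' all intermediate values are integers, so the result does not depend on a
#' floating-point tolerance. The rank gates the multistability criterion
#' (critical fragments are sought at order \code{rank(S)}), hence exactness.
#'
#' @param S Integer matrix, e.g. from [stoichiometric_matrix()].
#' @return Integer rank.
#' @export
stoich_rank <- function(S) {
  A <- matrix(as.numeric(S), nrow(S), ncol(S))
  n <- nrow(A)
  m <- ncol(A)
  rank <- 0L
  prev <- 1
  row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    piv <- which(A[row:n, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) A[c(piv, row), ] <- A[c(row, piv), ]
    if (row < n) {
      rows <- (row + 1L):n
      # Bareiss update: exact integer division by the previous pivot
      A[rows, ] <- (A[row, col] * A[rows, , drop = FALSE] -
                      outer(A[rows, col], A[row, ])) / prev
    }
    prev <- A[row, col]
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

#' Validate structural assumptions of a mechanism
#'
#' The screening theory assumes every species is both consumed and produced in
#' at least one true reaction, i.e. a reaction that is neither a pure inflow
#' (empty reactants) nor a pure outflow (empty products). Violations are
#' reported as warnings but do not block the analysis.
#'
#' @param mech A \code{mechanism}.
#' @return Character vector of warning messages (empty if none).
#' @export
validate_mechanism <- function(mech) {
  true_rxn <- rowSums(mech$alpha) > 0L & rowSums(mech$beta) > 0L
  warnings <- character(0)
  for (i in seq_len(n_species(mech))) {
    consumed <- any(mech$alpha[true_rxn, i] > 0L)
    produced <- any(mech$beta[true_rxn, i] > 0L)
    if (!consumed || !produced) {
      what <- c(if (!consumed) "consumed", if (!produced) "produced")
      warnings <- c(warnings, sprintf(
        "species %s (index %d) is not %s in any true reaction",
        mech$species[i], i, paste(what, collapse = " or ")))
    }
  }
  warnings
}
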