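#' Load a packaged example mechanism
#'
#' The package ships the mechanisms used throughout the documentation and
#' tests: a reversible substrate inhibition scheme, a
#' glycolysis-gluconeogenesis switch, the yeast Cdc42 cell-polarity network
#' (in two variants: exactly as published, where reaction 12 is the null
#' self-map RDIm -> RDIm, and with the plausible correction
#' RDIm -> RDIc), and single- and double-layer MAPK phosphorylation
#' cascades.
#'
#' @param name One of \code{"reversible_substrate_inhibition"},
#'   \code{"glycolysis_gluconeogenesis"}, \code{"cdc42_as_printed"},
#'   \code{"cdc42_corrected_b12"}, \code{"mapk_single"},
#'   \code{"mapk_double"}.
#' @return A \code{mechanism}.
#' @export
load_fixture <- function(name) {
  choices <- c("reversible_substrate_inhibition",
               "glycolysis_gluconeogenesis", "cdc42_as_printed",
               "cdc42_corrected_b12", "mapk_single", "mapk_double")
  name <- match.arg(name, choices)
  path <- system.file("extdata", paste0(name, ".txt"), package = "critfrag",
                      mustWork = TRUE)
  read_mechanism(path)
}

#' Path of a packaged example mechanism file
#'
#' @inheritParams load_fixture
#' @return File path of the installed mechanism file.
#' @export
fixture_path <- function(name) {
  choices <- c("reversible_substrate_inhibition",
               "glycolysis_gluconeogenesis", "cdc42_as_printed",
               "cdc42_corrected_b12", "mapk_single", "mapk_double")
  name <- match.arg(name, choices)
  system.file("extdata", paste0(name, ".txt"), package = "critfrag",
              mustWork = TRUE)
}

#' Generate a random mass-action mechanism
#'
#' Draws a mechanism for property-based testing: each reaction takes up to
#' two distinct reactant species and up to two distinct product species with
#' stoichiometric coefficients in \code{1:max_stoich}; with probability
#' \code{p_io} a reaction is instead a pure inflow or outflow. Any species
#' left unused is attached to a random reaction so the mechanism invariant
#' (every species appears somewhere) holds. Generation is deterministic
#' given \code{seed}.
#'
#' @param n_species,n_reactions Sizes (both at least 1).
#' @param max_stoich Largest stoichiometric coefficient (default 2).
#' @param p_io Probability that a reaction is a pure inflow or outflow.
#' @param seed Integer seed.
#' @return A \code{mechanism}.
#' @export
random_mechanism <- function(n_species, n_reactions, max_stoich = 2L,
                             p_io = 0.15, seed = 1L) {
  stopifnot(n_species >= 1L, n_reactions >= 1L, max_stoich >= 1L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  draw_side <- function() {
    size <- sample(0:2, 1L)
    if (size == 0L) return(integer(0))
    sp <- sample.int(n_species, min(size, n_species))
    stats::setNames(sample.int(max_stoich, length(sp), replace = TRUE), sp)
  }

  alpha <- matrix(0L, n_reactions, n_species)
  beta <- matrix(0L, n_reactions, n_species)
  for (j in seq_len(n_reactions)) {
    repeat {
      if (stats::runif(1) < p_io) {
        sp <- sample.int(n_species, 1L)
        if (stats::runif(1) < 0.5) {
          lhs <- integer(0)
          rhs <- stats::setNames(1L, sp)
        } else {
          lhs <- stats::setNames(1L, sp)
          rhs <- integer(0)
        }
      } else {
        lhs <- draw_side()
        rhs <- draw_side()
      }
      if (length(lhs) + length(rhs) > 0L) break
    }
    alpha[j, as.integer(names(lhs))] <- as.integer(lhs)
    beta[j, as.integer(names(rhs))] <- as.integer(rhs)
  }
  # attach unused species somewhere so every species appears in a reaction
  unused <- which(colSums(alpha) + colSums(beta) == 0L)
  for (i in unused) {
    j <- sample.int(n_reactions, 1L)
    if (stats::runif(1) < 0.5) alpha[j, i] <- 1L else beta[j, i] <- 1L
  }

  species <- paste0("A", seq_len(n_species))
  labels <- paste0("k", seq_len(n_reactions))
  dimnames(alpha) <- dimnames(beta) <- list(labels, species)
  structure(
    list(species = species, alpha = alpha, beta = beta,
         rate_labels = labels),
    class = "mechanism")
}
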