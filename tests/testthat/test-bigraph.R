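mech2 <- load_fixture("reversible_substrate_inhibition")
graph2 <- build_graph(mech2)

test_that("bipartite digraph arcs follow reactant/product incidence", {
  arcs <- paste(graph2$arcs$from, graph2$arcs$to, sep = "->")
  expect_true(all(c("A1->k3", "A2->k3", "k3->A3") %in% arcs))
  expect_false("A3->k3" %in% arcs)
  # inflow reaction node: one outgoing arc, no incoming arc
  expect_true("k2->A1" %in% arcs)
  expect_false(any(graph2$arcs$to == "k2"))
  # bipartite: species only point at reactions and vice versa
  expect_true(all(graph2$arcs$from %in% c(mech2$species, mech2$rate_labels)))
  expect_false(any(graph2$arcs$from %in% mech2$species &
                     graph2$arcs$to %in% mech2$species))
  g16 <- build_graph(load_fixture("mapk_double"))
  expect_equal(g16$n_species, 12L)
  expect_equal(g16$n_reactions, 18L)
})

test_that("edge weights are the negated squared reactant coefficients", {
  expect_identical(edge_weight(graph2, species = 1L, reaction = 3L), -1L)
  m <- parse_mechanism("2 A1 + A2 -> A3 ; k1")
  g <- build_graph(m)
  expect_identical(edge_weight(g, 1L, 1L), -4L)
  expect_identical(edge_weight(g, 2L, 1L), -1L)
  expect_error(edge_weight(graph2, 3L, 3L), "no edge")
})

test_that("path weights follow the positive/negative path definitions", {
  # positive path A1 -> B3 -> A3
  expect_equal(path_weight(graph2, 1L, 3L, 3L, "positive"), 1)
  # the two orientations of the negative path through B3
  expect_equal(path_weight(graph2, 1L, 3L, 2L, "negative"), -1)
  expect_equal(path_weight(graph2, 2L, 3L, 1L, "negative"), -1)
  # autocatalytic self-loop A1 -> B -> A1 with beta = 2
  g <- build_graph(parse_mechanism("A1 -> 2 A1 ; k1"))
  expect_equal(path_weight(g, 1L, 1L, 1L, "positive"), 2)
  # a species cannot be its own negative-path partner
  expect_error(path_weight(g, 1L, 1L, 1L, "negative"), "must differ")
  expect_error(path_weight(graph2, 1L, 4L, 2L, "positive"), "not a reactant")
})

test_that("mirrors of negative paths exist with equal weight", {
  for (name in c("reversible_substrate_inhibition", "mapk_single")) {
    g <- build_graph(load_fixture(name))
    for (j in seq_len(g$n_reactions)) {
      reac <- which(g$alpha[j, ] > 0L)
      for (a in reac) for (b in setdiff(reac, a)) {
        expect_equal(path_weight(g, a, j, b, "negative"),
                     path_weight(g, b, j, a, "negative"))
      }
    }
  }
})

test_that("cycle weights and signs match the worked fragment", {
  key <- list(species = 1:3, reactions = sort(c(5L, 3L, 4L)))
  cycles <- enumerate_cycles(graph2, key)
  expect_length(cycles, 2)
  ords <- vapply(cycles, `[[`, 0, "order")
  ws <- vapply(cycles, `[[`, 0, "weight")
  # the 2-cycle A2,A3;B3,B4 is positive, the 3-cycle A1,A3,A2;B5,B4,B3
  # is positive as well (two negative paths)
  expect_equal(sort(ords), c(2, 3))
  expect_equal(ws[order(ords)], c(1, 1))
  # sign equals parity of negative paths on every enumerated cycle
  for (name in c("reversible_substrate_inhibition",
                 "glycolysis_gluconeogenesis")) {
    g <- build_graph(load_fixture(name))
    r <- stoich_rank(stoichiometric_matrix(g$mechanism))
    for (k in seq_len(min(3, r))) {
      for (kk in enumerate_fragments(g, k)) {
        for (cyc in enumerate_cycles(g, kk)) {
          n_neg <- sum(vapply(cyc$paths, `[[`, 0, "polarity") < 0)
          expect_equal(sign(cyc$weight), (-1)^n_neg)
          expect_equal(cyc$weight,
                       prod(vapply(cyc$paths, `[[`, 0, "weight")))
        }
      }
    }
  }
})

test_that("negative 2-cycle through one reaction has positive weight", {
  # C = A1,A2;B3,B3 is formed by the two expansions of the negative path
  key <- list(species = 1:2, reactions = c(3L, 3L))
  cycles <- enumerate_cycles(graph2, key)
  expect_length(cycles, 1)
  expect_equal(cycles[[1]]$order, 2)
  expect_equal(cycles[[1]]$weight, 1)  # (-1) * (-1)
  expect_equal(sort(cycles[[1]]$reactions), c(3, 3))
})

test_that("DOT export renders both node shapes and all arcs", {
  dot <- export_dot(graph2)
  expect_match(dot[1], "digraph")
  expect_equal(sum(grepl("shape=circle", dot)), 4)
  expect_equal(sum(grepl("shape=box", dot)), 6)
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), nrow(graph2$arcs))
})
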