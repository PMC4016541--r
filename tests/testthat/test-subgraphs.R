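mech2 <- load_fixture("reversible_substrate_inhibition")
graph2 <- build_graph(mech2)
s3_key <- list(species = 1:3, reactions = sort(c(5L, 3L, 4L)))

test_that("component table lists the constituents of the worked fragment", {
  tab <- component_table(graph2, s3_key)
  expect_named(tab, c("A1", "A2", "A3"))
  a1 <- tab[["A1"]]
  expect_true(any(a1$type == "edge" & a1$reaction == 5))
  # A1 contributes the negative path [A1,B5,A3-] to the 3-cycle
  expect_true(any(a1$type == "negative_path" & a1$reaction == 5 &
                    a1$end == 3))
  a3 <- tab[["A3"]]
  expect_true(any(a3$type == "positive_path" & a3$reaction == 4 &
                    a3$end == 2))
})

test_that("a fragment with an uncoverable species has no subgraphs", {
  # A4's only outgoing edge is B6; reactions {3,4} cannot be consumed by A4
  key <- list(species = c(3L, 4L), reactions = c(3L, 3L))
  expect_length(enumerate_subgraphs(graph2, key), 0)
  wf <- fragment_weight(graph2, key)
  expect_equal(wf$weight, 0)
  expect_false(wf$critical)
})

test_that("the worked fragment has exactly three subgraphs with the
           published weights", {
  sgs <- enumerate_subgraphs(graph2, s3_key)
  expect_length(sgs, 3)
  ws <- sort(vapply(sgs, `[[`, 0, "weight"))
  expect_equal(ws, c(-1, -1, 1))
  # g3 is the edges-only subgraph (empty clique of the cycle graph)
  n_cycles <- vapply(sgs, function(g) length(g$cycles), 0)
  expect_equal(sort(n_cycles), c(0, 1, 1))
  edges_only <- sgs[[which(n_cycles == 0)]]
  expect_equal(sort(edges_only$edges$reaction), c(3, 4, 5))
  expect_equal(subgraph_weight(edges_only), 1)
  # subgraph weights recompute from their components
  for (g in sgs) expect_equal(subgraph_weight(g), g$weight)
  # fragment weight and criticality
  wf <- fragment_weight(graph2, s3_key)
  expect_equal(wf$weight, -1)
  expect_true(wf$critical)
})

test_that("path-graph cycle enumeration matches the stock circuit oracle", {
  expect_length(enumerate_cycles(graph2, s3_key), 2)
  set.seed(99)
  n_checked <- 0
  for (rep in seq_len(60)) {
    g <- build_graph(random_mechanism(sample(2:5, 1), sample(3:7, 1),
                                      seed = 4000L + rep))
    k <- sample.int(g$n_species, 1)
    key <- random_key(g, k)
    if (is.null(key)) next
    n_checked <- n_checked + 1
    got <- vapply(enumerate_cycles(g, key), `[[`, "", "key")
    expect_identical(sort(got), oracle_cycles(g, key))
  }
  expect_gte(n_checked, 50)
})

test_that("subgraph enumeration matches the combinatorial-filter oracle", {
  set.seed(123)
  n_checked <- 0
  for (rep in seq_len(60)) {
    g <- build_graph(random_mechanism(sample(2:5, 1), sample(3:7, 1),
                                      seed = 5000L + rep))
    k <- sample.int(g$n_species, 1)
    key <- random_key(g, k)
    if (is.null(key)) next
    n_checked <- n_checked + 1
    sgs <- enumerate_subgraphs(g, key)
    got <- data.frame(key = vapply(sgs, `[[`, "", "key"),
                      weight = vapply(sgs, `[[`, 0, "weight"))
    want <- oracle_subgraphs(g, key)
    expect_identical(got$key, want$key)
    expect_equal(got$weight, want$weight)
  }
  expect_gte(n_checked, 50)
  # and on every fragment of the worked mechanism
  for (k in 1:4) {
    for (key in enumerate_fragments(graph2, k)) {
      sgs <- enumerate_subgraphs(graph2, key)
      want <- oracle_subgraphs(graph2, key)
      expect_identical(vapply(sgs, `[[`, "", "key"), want$key)
    }
  }
})

test_that("subgraphs conserve the reaction multiset and cover each species
           once", {
  set.seed(5)
  for (rep in seq_len(20)) {
    g <- build_graph(random_mechanism(sample(3:6, 1), sample(3:8, 1),
                                      seed = 6000L + rep))
    key <- random_key(g, sample.int(g$n_species, 1))
    if (is.null(key)) next
    for (sg in enumerate_subgraphs(g, key)) {
      consumed <- c(unlist(lapply(sg$cycles, `[[`, "reactions")),
                    sg$edges$reaction)
      expect_equal(sort(consumed), key$reactions, ignore_attr = TRUE)
      covered <- c(unlist(lapply(sg$cycles, `[[`, "species")),
                   sg$edges$species)
      expect_equal(sort(covered), key$species, ignore_attr = TRUE)
    }
  }
})

test_that("every order-4 fragment of the rank-3 mechanism has weight zero", {
  for (key in enumerate_fragments(graph2, 4)) {
    expect_equal(fragment_weight(graph2, key)$weight, 0)
  }
})

test_that("criticality is invariant under relabeling of species and
           reactions", {
  perm_s <- c(3L, 1L, 4L, 2L)  # new position of each species
  perm_r <- c(2L, 4L, 6L, 1L, 3L, 5L)
  m <- mech2
  inv_s <- order(perm_s)
  inv_r <- order(perm_r)
  shuffled <- structure(
    list(species = m$species[inv_s],
         alpha = m$alpha[inv_r, inv_s],
         beta = m$beta[inv_r, inv_s],
         rate_labels = m$rate_labels[inv_r]),
    class = "mechanism")
  dimnames(shuffled$alpha) <- dimnames(shuffled$beta) <-
    list(shuffled$rate_labels, shuffled$species)
  for (k in 1:4) {
    a <- run_analysis(mech2, order = k)
    b <- run_analysis(shuffled, order = k)
    expect_equal(nrow(a$critical), nrow(b$critical))
    expect_equal(sort(a$critical$weight), sort(b$critical$weight))
    expect_equal(sum(a$n_fragments), sum(b$n_fragments))
  }
})
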