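test_that("closest_proximity matches hand evaluation on the 4-node path", {
  g <- path4()
  # S = {A}, T = {C, D}: distances 2 and 3, average 2.5
  expect_equal(closest_proximity(c("C", "D"), "A", g), 2.5)
  # targets inside the disease set -> 0
  expect_equal(closest_proximity(c("A", "B"), c("A", "B", "C"), g), 0)
})

test_that("unreachable targets yield Inf, or are dropped under that policy", {
  g <- load_interactome(cbind(c("A", "C"), c("B", "D")))  # two components
  expect_equal(closest_proximity(c("C", "D"), "A", g), Inf)
  expect_equal(closest_proximity(c("B", "C"), "A", g), Inf)
  expect_equal(closest_proximity(c("B", "C"), "A", g, unreachable = "drop"), 1)
  # no in-network target is an error, not Inf
  expect_error(closest_proximity("Z", "A", g), "no drug target")
})

test_that("closest_proximity equals the BFS oracle on 100 random graphs", {
  mismatches <- 0
  for (i in 1:100) {
    set.seed(i)
    n <- sample(5:50, 1)
    g <- random_test_graph(n, p = runif(1, 0.05, 0.3), seed = i)
    nodes <- igraph::V(g)$name
    adj <- adj_list(igraph::as_edgelist(g), nodes)
    targets <- sample(nodes, sample(1:4, 1))
    disease <- sample(nodes, sample(1:6, 1))
    got <- closest_proximity(targets, disease, g)
    want <- oracle_closest_proximity(unique(targets), unique(disease), adj)
    if (!identical(got == Inf, want == Inf) ||
        (is.finite(want) && abs(got - want) > 0)) {
      mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("proximity respects monotonicity and disconnected-node invariance", {
  for (i in 1:20) {
    g <- random_test_graph(20, 0.15, seed = 1000 + i)
    nodes <- igraph::V(g)$name
    set.seed(i)
    targets <- sample(nodes, 3)
    disease <- sample(nodes, 4)
    base <- closest_proximity(targets, disease, g)
    # adding a disease gene can never increase proximity
    extra <- sample(setdiff(nodes, disease), 1)
    expect_lte(closest_proximity(targets, c(disease, extra), g), base)
    # adding an isolated node never changes a finite proximity
    g2 <- igraph::add_vertices(g, 1, name = "ISOLATED")
    if (is.finite(base)) {
      expect_equal(closest_proximity(targets, disease, g2), base)
    }
  }
})

test_that("proximity is zero exactly when all in-network targets are disease genes", {
  g <- random_test_graph(15, 0.2, seed = 77)
  nodes <- igraph::V(g)$name
  expect_equal(closest_proximity(nodes[1:3], nodes[1:5], g), 0)
  expect_gt(closest_proximity(nodes[c(1, 6)], nodes[1:5], g), 0)
})

test_that("proximity_screen fills cells like per-drug calls and ranks strictly", {
  gen <- shared_scenario()
  gs2 <- plant_disease_module(gen$net, synthetic_scenario(seed = 17, n_genes = 300,
                                                          n_disease_genes = 10))
  gs2$name <- "module_b"
  pm <- suppressMessages(proximity_screen(gen$dtn, list(gen$disease, gs2), gen$net))
  # spot-check cells against independent closest_proximity calls
  for (d in sample(pm$drugs, 5)) {
    tg <- drug_targets(gen$dtn, d)
    expect_equal(pm$d[d, gen$disease$name],
                 closest_proximity(tg, gen$disease$genes, gen$net))
    expect_equal(pm$d[d, "module_b"],
                 closest_proximity(tg, gs2$genes, gen$net))
  }
  # each rank column is a strict permutation ordered by (d, drug_id)
  for (j in seq_along(pm$gene_sets)) {
    expect_setequal(pm$ranks[, j], seq_along(pm$drugs))
    ord <- order(pm$ranks[, j])
    dcol <- pm$d[ord, j]
    expect_true(all(diff(dcol) >= 0))
  }
})

test_that("drugs sharing targets get identical proximities; drug with a disease-gene target ranks first", {
  g <- path4()
  dtn <- as_drug_target_network(data.frame(
    drug_id = c("d1", "d2", "d3"), gene = c("A", "A", "D"),
    mean_pactivity = 6))
  gs <- gene_set("mod", c("A", "B"))
  pm <- proximity_screen(dtn, list(gs), g)
  expect_equal(pm$d["d1", 1], pm$d["d2", 1])
  expect_equal(pm$d["d1", 1], 0)
  expect_equal(pm$ranks["d1", 1], 1)  # tie with d2 broken lexicographically
  expect_equal(pm$ranks["d2", 1], 2)
  expect_equal(pm$ranks["d3", 1], 3)
})

test_that("drugs without in-network targets are excluded with a message", {
  g <- path4()
  dtn <- as_drug_target_network(data.frame(
    drug_id = c("d1", "d2"), gene = c("A", "ZZZ"), mean_pactivity = 6))
  expect_message(pm <- proximity_screen(dtn, list(gene_set("m", "A")), g),
                 "excluded 1 drug")
  expect_identical(pm$drugs, "d1")
  expect_identical(pm$meta$excluded_drugs, "d2")
})

test_that("rank_correlation matches a direct Spearman computation", {
  gen <- shared_scenario()
  gs2 <- plant_disease_module(gen$net, synthetic_scenario(seed = 18, n_genes = 300,
                                                          n_disease_genes = 12))
  gs2$name <- "module_c"
  pm <- suppressMessages(proximity_screen(gen$dtn, list(gen$disease, gs2), gen$net))
  rc <- rank_correlation(pm)
  expect_equal(diag(rc), c(1, 1), ignore_attr = TRUE)
  expect_equal(rc[1, 2], rc[2, 1])
  ok <- is.finite(pm$d[, 1]) & is.finite(pm$d[, 2])
  # definitional oracle: rank then Pearson
  expect_equal(rc[1, 2],
               cor(rank(pm$d[ok, 1]), rank(pm$d[ok, 2]), method = "pearson"))
  # a column against its negation ranking
  pm2 <- pm
  pm2$d[, 2] <- -pm2$d[, 1]
  expect_equal(rank_correlation(pm2)[1, 2], -1)
})
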