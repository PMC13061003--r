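test_that("MC transition rules follow the pairwise-preference definitions", {
  # unanimous order: A above B in both lists
  P <- mc_transition_matrix(list(c("A", "B"), c("A", "B")), "MC3", teleport = 0)
  expect_equal(P["A", "B"], 0)          # no list prefers B over A
  expect_equal(P["B", "A"], 1 / 2)      # unanimous preference, 1/n mass
  expect_equal(P["B", "B"], 1 / 2)
  expect_equal(rowSums(P), c(A = 1, B = 1))

  # 3 items, 2 lists with one disagreement: hand evaluation of the MC3 rule
  lists <- list(c("A", "B", "C"), c("B", "A", "C"))
  P3 <- mc_transition_matrix(lists, "MC3", teleport = 0)
  n <- 3
  expect_equal(P3["A", "B"], (1 / 2) / n)  # one of two lists ranks B above A
  expect_equal(P3["B", "A"], (1 / 2) / n)
  expect_equal(P3["C", "A"], 1 / n)        # both lists rank A above C
  expect_equal(P3["A", "C"], 0)
  # MC1 moves on any support, MC2 needs a strict majority
  P1 <- mc_transition_matrix(lists, "MC1", teleport = 0)
  expect_equal(P1["A", "B"], 1 / n)
  P2 <- mc_transition_matrix(lists, "MC2", teleport = 0)
  expect_equal(P2["A", "B"], 0)
  expect_equal(P2["C", "A"], 1 / n)
})

test_that("transition matrices are row-stochastic and teleport-mixed", {
  gen_lists <- function(seed) {
    set.seed(seed)
    items <- sprintf("i%02d", 1:8)
    lapply(1:4, function(i) sample(items))
  }
  for (s in 1:5) {
    for (v in c("MC1", "MC2", "MC3")) {
      P <- mc_transition_matrix(gen_lists(s), v, teleport = 0.05)
      expect_true(all(abs(rowSums(P) - 1) < 1e-12))
      expect_true(all(P >= 0.05 / nrow(P) - 1e-15))  # teleport floor
    }
  }
  expect_error(mc_transition_matrix(list(c("A", "B")), "MC3"), "two ranked lists")
  expect_error(mc_transition_matrix(list(c("A", "B"), c("B", "A")), "MC3",
                                    items = c("A", "B", "Z")),
               "zero lists")
})

test_that("stationary_distribution matches the eigenvector oracle", {
  # degenerate and symmetric cases
  expect_equal(stationary_distribution(matrix(1, 1, 1)), 1, ignore_attr = TRUE)
  P2 <- matrix(0.5, 2, 2)
  expect_equal(stationary_distribution(P2), c(0.5, 0.5), ignore_attr = TRUE)
  # random irreducible chains up to 10x10 against eigen decomposition
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:10, 1)
    P <- matrix(rgamma(n * n, 1), n)
    P <- P / rowSums(P)
    got <- stationary_distribution(P)
    want <- oracle_stationary(P)
    expect_lt(max(abs(got - want)), 1e-8)
  }
  expect_error(stationary_distribution(matrix(c(1, 1, 0, 0.5), 2)), "stochastic")
})

test_that("modified_kendall matches brute-force case analysis and its boundary identities", {
  expect_equal(modified_kendall(c("A", "B", "C"), c("A", "B", "C")), 0)
  expect_equal(modified_kendall(c("A", "B", "C", "D"), c("D", "C", "B", "A"),
                                penalty_p = 0.3), 1)
  # partial-overlap toy case against exhaustive pair enumeration
  a <- c("A", "B", "C", "D", "E")
  b <- c("C", "F", "A", "G", "B")
  for (p in c(0, 0.5, 1)) {
    for (k in c(3, 4, 5)) {
      expect_equal(modified_kendall(a, b, penalty_p = p, top_k = k),
                   oracle_kendall(a, b, p, k))
    }
  }
  # randomised cross-check
  for (s in 1:25) {
    set.seed(s)
    items <- sprintf("x%02d", 1:12)
    la <- sample(items, 8); lb <- sample(items, 8)
    p <- runif(1); k <- sample(2:8, 1)
    expect_equal(modified_kendall(la, lb, p, k), oracle_kendall(la, lb, p, k))
    # symmetry in the two list arguments
    expect_equal(modified_kendall(la, lb, p, k), modified_kendall(lb, la, p, k))
  }
  expect_error(modified_kendall(c("A", "B"), c("A", "B"), top_k = 1), "at least 2")
})

test_that("aggregating identical lists returns that list for every algorithm", {
  l <- sprintf("d%02d", 1:6)
  lists <- list(l, l, l)
  for (alg in c("MC1", "MC2", "MC3", "Borda")) {
    expect_identical(aggregate_ranks(lists, alg)$consensus, l)
  }
  res <- select_and_aggregate(lists)
  expect_identical(res$consensus, l)
  expect_equal(res$mean_kendall, 0)
  expect_equal(sum(res$stationary), 1, tolerance = 1e-9)
})

test_that("consensus is equivariant under relabeling of the items", {
  set.seed(9)
  items <- sprintf("a%02d", 1:7)
  lists <- lapply(1:3, function(i) sample(items))
  base <- aggregate_ranks(lists, "MC3")$consensus
  # a relabeling that preserves lexicographic tie-break order
  perm <- setNames(sprintf("b%02d", order(order(items))), items)
  relisted <- lapply(lists, function(l) unname(perm[l]))
  expect_identical(unname(perm[base]), aggregate_ranks(relisted, "MC3")$consensus)
})

test_that("selected consensus attains the exhaustive-search optimum on 3-item instances", {
  items <- c("A", "B", "C")
  perms <- all_permutations(items)
  for (i in seq_along(perms)) {
    for (j in seq_along(perms)) {
      lists <- list(perms[[i]], perms[[j]])
      res <- select_and_aggregate(lists, penalty_p = 0.5)
      scores <- vapply(perms, function(pp) {
        mean(vapply(lists, function(l) modified_kendall(pp, l, 0.5), numeric(1)))
      }, numeric(1))
      expect_equal(res$mean_kendall, min(scores), tolerance = 1e-12)
    }
  }
})

test_that("consensus of noisy copies recovers a planted order better than a typical input", {
  set.seed(31)
  planted <- sprintf("p%02d", 1:15)
  noisy <- lapply(1:6, function(i) {
    l <- planted
    for (r in 1:5) {  # a few random adjacent swaps
      pos <- sample(seq_len(length(l) - 1), 1)
      l[c(pos, pos + 1)] <- l[c(pos + 1, pos)]
    }
    l
  })
  res <- select_and_aggregate(noisy)
  d_consensus <- modified_kendall(res$consensus, planted)
  d_inputs <- vapply(noisy, function(l) modified_kendall(l, planted), numeric(1))
  expect_lte(d_consensus, median(d_inputs))
})
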