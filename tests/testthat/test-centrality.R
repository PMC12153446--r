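three_node <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("A1", "A2", "B1"),
                                       c("A1", "A2", "B1")))
  W["A1", "A2"] <- W["A2", "A1"] <- 0.3
  W["A1", "B1"] <- W["B1", "A1"] <- -0.1
  toy_model(W, c(A1 = "anxiety", A2 = "anxiety", B1 = "depression"))
}

test_that("expected influence sums incident weights, by variant", {
  model <- three_node()
  expect_equal(unname(expected_influence(model, "absolute")["A1"]), 0.4)
  expect_equal(unname(expected_influence(model, "signed")["A1"]), 0.2)
  empty <- toy_model(matrix(0, 3, 3))
  expect_true(all(expected_influence(empty) == 0))
})

test_that("absolute and signed EI coincide on all-positive networks", {
  W <- abs(random_corr(5, 6)); diag(W) <- 0
  model <- toy_model(W)
  expect_equal(expected_influence(model, "absolute"),
               expected_influence(model, "signed"))
  # oracle: row sums of |W|
  expect_equal(unname(expected_influence(model)), unname(rowSums(abs(W))))
})

test_that("bridge expected influence sums cross-community weights only", {
  model <- three_node()
  bei <- bridge_expected_influence(model)
  expect_equal(unname(bei), c(-0.1, 0, -0.1))
  # hand case: cross edges 0.34 and 0.12 -> 0.46
  W <- matrix(0, 3, 3, dimnames = list(c("G1", "C1", "C2"),
                                       c("G1", "C1", "C2")))
  W["G1", "C1"] <- W["C1", "G1"] <- 0.34
  W["G1", "C2"] <- W["C2", "G1"] <- 0.12
  W["C1", "C2"] <- W["C2", "C1"] <- 0.9  # within, ignored
  m2 <- toy_model(W, c(G1 = "anxiety", C1 = "depression",
                       C2 = "depression"))
  expect_equal(unname(bridge_expected_influence(m2)["G1"]), 0.46)
})

test_that("block-diagonal networks have zero BEI; single community warns", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5; W[3, 4] <- W[4, 3] <- 0.4
  comm <- setNames(c("anxiety", "anxiety", "depression", "depression"),
                   paste0("N", 1:4))
  expect_true(all(bridge_expected_influence(toy_model(W, comm)) == 0))
  expect_warning(b <- bridge_expected_influence(toy_model(W)), "single")
  expect_true(all(b == 0))
})

test_that("signed BEI totals twice the cross-community weight sum", {
  set.seed(41)
  truth <- make_ground_truth()
  model <- toy_model(truth$partials, truth$communities)
  ce <- cross_community_edges(model)
  expect_equal(sum(bridge_expected_influence(model)), 2 * sum(ce$weight))
})

test_that("for all-positive networks BEI never exceeds absolute EI", {
  truth <- make_ground_truth()
  model <- toy_model(truth$partials, truth$communities)
  expect_true(all(bridge_expected_influence(model) <=
                    expected_influence(model) + 1e-12))
})

test_that("centralities are equivariant under node relabeling", {
  truth <- make_ground_truth()
  W <- truth$partials
  perm <- c(5, 3, 1, 2, 4, 7, 6, 10, 8, 9, 12, 11, 14, 13, 16, 15, 17)
  Wp <- W[perm, perm]
  mp <- toy_model(Wp, truth$communities[perm])
  m0 <- toy_model(W, truth$communities)
  expect_equal(expected_influence(m0)[perm], expected_influence(mp))
  expect_equal(bridge_expected_influence(m0)[perm],
               bridge_expected_influence(mp))
})

test_that("ranks order descending with lexicographic tie-breaks", {
  W <- matrix(0, 4, 4, dimnames = list(c("B", "A", "D", "C"),
                                       c("B", "A", "D", "C")))
  W["B", "A"] <- W["A", "B"] <- 0.2   # A and B tie on EI
  W["D", "C"] <- W["C", "D"] <- 0.1   # C and D tie lower
  comm <- setNames(c("anxiety", "anxiety", "depression", "depression"),
                   c("B", "A", "D", "C"))
  tab <- centrality_table(toy_model(W, comm))
  expect_equal(tab$ei_rank[tab$node == "A"], 1)  # tie broken by label
  expect_equal(tab$ei_rank[tab$node == "B"], 2)
  expect_equal(tab$ei_rank[tab$node == "C"], 3)
  expect_equal(sort(tab$ei_rank), 1:4)
  expect_equal(sort(tab$bei_rank_within_community[tab$community == "anxiety"]),
               1:2)
})

test_that("a node carrying all bridge weight is BEI rank 1 in its community", {
  truth <- make_ground_truth(bridge_spec = data.frame(
    node_a = "GAD5", node_b = "CESD6", weight = 0.3))
  tab <- centrality_table(toy_model(truth$partials, truth$communities))
  expect_equal(tab$bei_rank_within_community[tab$node == "GAD5"], 1)
  expect_equal(tab$bei_rank_within_community[tab$node == "CESD6"], 1)
})
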