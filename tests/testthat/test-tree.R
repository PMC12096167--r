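test_that("rollback handles leaves and symmetric chance nodes", {
  leaf <- chance_node("root", list(
    tree_branch("only", 1, cost = 5, effect = 2, node = terminal_node("t"))))
  expect_equal(tree_rollback(leaf), c(cost = 5, effect = 2))

  sym <- chance_node("toss", list(
    tree_branch("a", 0.5, cost = 10, effect = 0, node = terminal_node("t")),
    tree_branch("b", 0.5, cost = 0, effect = 10, node = terminal_node("t"))))
  expect_equal(tree_rollback(sym), c(cost = 5, effect = 5))
})

test_that("a decision root reports every strategy instead of optimizing", {
  d <- decision_node("strategy", list(
    tree_branch("cheap", node = terminal_node("t"), cost = 1, effect = 1),
    tree_branch("dear", node = terminal_node("t"), cost = 9, effect = 2)))
  ev <- tree_rollback(d)
  expect_named(ev, c("cheap", "dear"))
  expect_equal(ev$cheap, c(cost = 1, effect = 1))
  expect_equal(ev$dear, c(cost = 9, effect = 2))
})

test_that("invalid chance probabilities are rejected, naming the node", {
  bad <- chance_node("lopsided", list(
    tree_branch("a", 0.6, node = terminal_node("t")),
    tree_branch("b", 0.6, node = terminal_node("t"))))
  expect_error(tree_rollback(bad), "lopsided.*sum")
  neg <- chance_node("neg", list(
    tree_branch("a", -0.2, node = terminal_node("t")),
    tree_branch("b", 1.2, node = terminal_node("t"))))
  expect_error(tree_rollback(neg), "neg.*out of \\[0, 1\\]")
})

test_that("path enumeration is exhaustive and conserves probability", {
  two <- chance_node("root", list(
    tree_branch("a", 0.3, cost = 1, node = terminal_node("t")),
    tree_branch("b", 0.7, cost = 2, node = terminal_node("t"))))
  df <- tree_paths(two)
  expect_identical(nrow(df), 2L)
  expect_equal(sum(df$prob), 1)

  degenerate <- chance_node("root", list(
    tree_branch("sure", 1, cost = 4, effect = 1, node = terminal_node("t"))))
  df1 <- tree_paths(degenerate)
  expect_identical(nrow(df1), 1L)
  expect_equal(df1$cost, 4)
})

test_that("rollback equals brute-force enumeration on 1000 random trees", {
  set.seed(20240312)
  for (i in 1:1000) {
    tr <- random_tree(depth = sample(1:4, 1))
    df <- tree_paths(tr)
    expect_equal(sum(df$prob), 1, tolerance = 1e-12)
    expect_equal(tree_rollback(tr), paths_expectation(tr), tolerance = 1e-9)
  }
})

test_that("expected cost is linear in a global cost scaling", {
  scale_costs <- function(node, k) {
    node$branches <- lapply(node$branches, function(b) {
      b$payoff["cost"] <- b$payoff["cost"] * k
      b$node <- scale_costs(b$node, k)
      b
    })
    node
  }
  set.seed(99)
  for (i in 1:25) {
    tr <- random_tree(3)
    k <- stats::runif(1, 0.1, 10)
    ev <- tree_rollback(tr)
    ev_k <- tree_rollback(scale_costs(tr, k))
    expect_equal(unname(ev_k["cost"]), unname(k * ev["cost"]), tolerance = 1e-9)
    expect_equal(unname(ev_k["effect"]), unname(ev["effect"]), tolerance = 1e-12)
  }
})

test_that("trees serialize to plain JSON-compatible lists", {
  tr <- chance_node("root", list(
    tree_branch("a", 1, cost = 2, node = terminal_node("t"))))
  plain <- tree_unclass(tr)
  expect_type(plain, "list")
  expect_silent(jsonlite::toJSON(plain, auto_unbox = TRUE, null = "null"))
})
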