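# random chance trees for the rollback-vs-enumeration oracle checks
random_tree <- function(depth = 3, max_branches = 3) {
  if (depth == 0 || stats::runif(1) < 0.25) {
    return(terminal_node("leaf"))
  }
  k <- sample(2:max_branches, 1)
  p <- stats::runif(k)
  p <- p / sum(p)
  branches <- lapply(seq_len(k), function(i) {
    tree_branch(paste0("b", i), prob = p[i],
                cost = stats::runif(1, 0, 100),
                effect = stats::runif(1, 0, 10),
                node = random_tree(depth - 1, max_branches))
  })
  chance_node("node", branches)
}

# expected payoff by explicit path enumeration, independent of tree_rollback
paths_expectation <- function(tree) {
  df <- tree_paths(tree)
  c(cost = sum(df$prob * df$cost), effect = sum(df$prob * df$effect))
}

# recursive conservation check: at every chance node the branch
# probabilities (child shares of the parent count) sum to 1
check_conservation <- function(node, count) {
  if (node$kind != "chance" || length(node$branches) == 0) return(TRUE)
  shares <- vapply(node$branches, function(b) b$prob, numeric(1)) * count
  ok <- abs(sum(shares) - count) < 1e-9 * max(1, count) && all(shares >= 0)
  ok && all(vapply(seq_along(node$branches), function(i) {
    check_conservation(node$branches[[i]]$node, shares[i])
  }, logical(1)))
}
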