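#' Decision-tree nodes and branches
#'
#' Minimal deterministic decision-tree machinery: chance, decision and
#' terminal nodes, with payoffs attached to branches as *incremental*
#' (cost, effect) pairs that accumulate along a root-to-leaf path. A
#' terminal node carries no payoff of its own — final increments sit on the
#' branch leading into it.
#'
#' `tree_branch()` links a parent to a child node with a probability (ignored
#' under a decision node, where branches are alternative strategies) and an
#' incremental payoff. The optional `info` list travels with the branch into
#' the audit trace of [evaluate_arm()] (e.g. child counts, durations, unit
#' prices).
#'
#' @param label branch or node label used in traces and error messages.
#' @param branches list of `tree_branch` objects.
#' @param prob branch probability in \[0, 1\] (chance nodes).
#' @param cost,effect incremental payoff accumulated when the branch is
#'   traversed.
#' @param node the child node.
#' @param info optional named list of audit metadata.
#' @return Node constructors return a `tree_node`; `tree_branch()` a
#'   `tree_branch`.
#' @examples
#' t <- chance_node("toss",
#'   list(tree_branch("heads", 0.5, cost = 10, node = terminal_node("H")),
#'        tree_branch("tails", 0.5, effect = 10, node = terminal_node("T"))))
#' tree_rollback(t)
#' @name tree_node
NULL

#' @rdname tree_node
#' @export
chance_node <- function(label, branches) {
  structure(list(kind = "chance", label = label, branches = branches),
            class = "tree_node")
}

#' @rdname tree_node
#' @export
decision_node <- function(label, branches) {
  structure(list(kind = "decision", label = label, branches = branches),
            class = "tree_node")
}

#' @rdname tree_node
#' @export
terminal_node <- function(label) {
  structure(list(kind = "terminal", label = label, branches = list()),
            class = "tree_node")
}

#' @rdname tree_node
#' @export
tree_branch <- function(label, prob = NA_real_, cost = 0, effect = 0, node,
                        info = NULL) {
  structure(list(label = label, prob = prob,
                 payoff = c(cost = cost, effect = effect),
                 node = node, info = info),
            class = "tree_branch")
}

#' Validate tree invariants
#'
#' Checks that every chance node's branch probabilities lie in \[0, 1\] and
#' sum to 1 within `tol`, recursively; fails with a message naming the first
#' offending node.
#'
#' @param node a `tree_node`.
#' @param tol tolerance on the probability sum (default 1e-9).
#' @return `node`, invisibly.
#' @export
validate_tree <- function(node, tol = 1e-9) {
  stopifnot(inherits(node, "tree_node"))
  if (node$kind == "chance") {
    p <- vapply(node$branches, function(b) b$prob, numeric(1))
    if (anyNA(p) || any(p < -tol) || any(p > 1 + tol))
      fail("chance node '", node$label, "': branch probability out of [0, 1]")
    if (abs(sum(p) - 1) > tol)
      fail("chance node '", node$label, "': probabilities sum to ",
           format(sum(p), digits = 12), ", not 1")
  }
  for (b in node$branches) validate_tree(b$node, tol)
  invisible(node)
}

#' Expected-value rollback of a tree
#'
#' Computes the expected accumulated (cost, effect) payoff bottom-up. At a
#' chance node the branch payoff plus the child's expectation is weighted by
#' the branch probability; at a terminal node the expectation is zero. A
#' *decision* node at the root is not optimized over: the rollback returns a
#' named list with one expected payoff per strategy branch, since the
#' analysis compares both arms rather than picking one.
#'
#' @param node a `tree_node` (validated first).
#' @return For chance/terminal roots, a named numeric vector
#'   `c(cost =, effect =)`; for a decision root, a named list of such
#'   vectors, one per strategy.
#' @seealso [tree_paths()] for the brute-force path-enumeration oracle.
#' @export
tree_rollback <- function(node) {
  validate_tree(node)
  roll(node)
}

roll <- function(node) {
  if (node$kind == "terminal") return(c(cost = 0, effect = 0))
  if (node$kind == "decision") {
    out <- lapply(node$branches, function(b) b$payoff + roll(b$node))
    names(out) <- vapply(node$branches, function(b) b$label, character(1))
    return(out)
  }
  ev <- c(cost = 0, effect = 0)
  for (b in node$branches) ev <- ev + b$prob * (b$payoff + roll(b$node))
  ev
}

#' Exhaustive path enumeration (rollback oracle)
#'
#' Enumerates every root-to-leaf path of a chance tree, with its probability
#' and the payoff accumulated along it. The probability-weighted sum of path
#' payoffs equals [tree_rollback()] exactly; the two routes are kept
#' independent so each can check the other. Path probabilities sum to 1.
#'
#' For a decision root, paths are enumerated per strategy and tagged with a
#' `strategy` column; probabilities sum to 1 within each strategy.
#'
#' @param node a `tree_node` (validated first).
#' @return A data.frame with columns `strategy` (if the root is a decision
#'   node), `path` (slash-separated branch labels), `prob`, `cost`, `effect`,
#'   and a list-column `info` of per-path audit metadata (the last non-NULL
#'   branch `info` entries merged along the path).
#' @export
tree_paths <- function(node) {
  validate_tree(node)
  if (node$kind == "decision") {
    out <- lapply(node$branches, function(b) {
      df <- walk_paths(b$node, b$label, b$prob * 0 + 1, b$payoff,
                       merge_info(list(), b$info))
      df$strategy <- b$label
      df
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    return(df[c("strategy", "path", "prob", "cost", "effect", "info")])
  }
  df <- walk_paths(node, character(0), 1, c(cost = 0, effect = 0), list())
  rownames(df) <- NULL
  df
}

merge_info <- function(acc, info) {
  if (is.null(info)) acc else utils::modifyList(acc, info)
}

walk_paths <- function(node, labels, prob, payoff, info) {
  if (node$kind == "terminal" || length(node$branches) == 0L) {
    df <- data.frame(path = paste(c(labels, node$label), collapse = "/"),
                     prob = prob, cost = unname(payoff["cost"]),
                     effect = unname(payoff["effect"]),
                     stringsAsFactors = FALSE)
    df$info <- list(info)
    return(df)
  }
  if (node$kind == "decision")
    fail("decision node '", node$label, "' below the root is not supported")
  out <- lapply(node$branches, function(b) {
    walk_paths(b$node, c(labels, b$label), prob * b$prob,
               payoff + b$payoff, merge_info(info, b$info))
  })
  do.call(rbind, out)
}

#' Serialize a tree to plain nested lists
#'
#' Strips classes so a tree can be dumped with [jsonlite::toJSON()] for
#' debugging.
#'
#' @param node a `tree_node`.
#' @return A nested plain list.
#' @export
tree_unclass <- function(node) {
  out <- list(kind = node$kind, label = node$label)
  out$branches <- lapply(node$branches, function(b) {
    list(label = b$label, prob = b$prob,
         cost = unname(b$payoff["cost"]), effect = unname(b$payoff["effect"]),
         info = b$info, node = tree_unclass(b$node))
  })
  out
}
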