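# Shared fixtures and independent oracles, built in code.

# Two-strategy toy tree: A = sure thing, B = 60/40 gamble.
toy_tree <- function() {
  decision_tree(list(
    A = terminal_node("sure", cost = 10, effect = 1),
    B = chance_node("gamble",
                    children = list(terminal_node("win", cost = 5, effect = 1),
                                    terminal_node("lose", cost = 20, effect = 0)),
                    probs = list(0.6, 0.4))))
}

# Multiply every node/terminal cost in a tree by k (numeric costs only).
scale_costs <- function(tree, k) {
  walk <- function(node) {
    if (is.numeric(node$cost)) node$cost <- node$cost * k
    if (!is.null(node$children)) node$children <- lapply(node$children, walk)
    node
  }
  tree$strategies <- lapply(tree$strategies, walk)
  tree
}

# O(n^2)-style brute-force dominance oracle: absolute dominance by pairwise
# comparison; extended dominance if any segment between two other surviving
# strategies passes strictly below the point at its effectiveness.
oracle_dominance <- function(d) {
  n <- nrow(d)
  status <- rep("undominated", n)
  for (i in seq_len(n)) {
    dominated <- any(d$cost <= d$cost[i] & d$effect >= d$effect[i] &
                       (d$cost < d$cost[i] | d$effect > d$effect[i]))
    if (dominated) status[i] <- "absolutely_dominated"
  }
  surv <- which(status == "undominated")
  for (i in surv) {
    for (a in surv) {
      for (b in surv) {
        if (d$effect[a] < d$effect[i] && d$effect[i] < d$effect[b]) {
          w <- (d$effect[i] - d$effect[a]) / (d$effect[b] - d$effect[a])
          interp <- (1 - w) * d$cost[a] + w * d$cost[b]
          if (interp < d$cost[i] - 1e-12) status[i] <- "extendedly_dominated"
        }
      }
    }
  }
  status
}

random_strategy_set <- function(n) {
  data.frame(strategy = paste0("s", seq_len(n)),
             cost = runif(n, 0, 500),
             effect = runif(n),
             stringsAsFactors = FALSE)
}

# Aggregate an enumerate_paths() table into per-strategy expected values.
aggregate_paths <- function(paths) {
  agg <- function(v) tapply(v, paths$strategy, sum)
  data.frame(strategy = names(agg(paths$probability)),
             prob_sum = as.numeric(agg(paths$probability)),
             expected_cost = as.numeric(agg(paths$probability * paths$cost)),
             expected_effect = as.numeric(agg(paths$probability * paths$effect)),
             stringsAsFactors = FALSE)
}
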