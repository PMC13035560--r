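#' Monte Carlo probabilistic sensitivity analysis
#'
#' Samples all registry parameters jointly (independently across parameters)
#' from their fitted distributions, resolves the decision tree on every draw,
#' and rolls back expected cost and effectiveness per strategy and iteration.
#' Deterministic given the seed: the same seed and registry give bitwise
#' identical matrices.
#'
#' @param tree a `decision_tree` whose probabilities/costs reference registry
#'   parameter names.
#' @param registry a fitted `param_registry`.
#' @param n_iterations number of Monte Carlo iterations (published analyses
#'   conventionally use 10,000).
#' @param seed integer seed.
#' @return object of class `psa_result`: list with `cost` and `effect`
#'   (n x strategy matrices), `draws` (the parameter table), `n_iterations`,
#'   `seed`.
#' @export
run_psa <- function(tree, registry, n_iterations = 10000, seed) {
  stopifnot(inherits(tree, "decision_tree"), n_iterations >= 1)
  draws <- sample_parameters(registry, n_iterations, seed)
  v <- eval_tree(tree, as.list(draws), n = n_iterations)
  structure(list(cost = v$cost, effect = v$effect, draws = draws,
                 n_iterations = n_iterations, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA:", x$n_iterations, "iterations, seed", x$seed, "\n")
  cat("Mean cost:  ", paste(sprintf("%s %.2f", colnames(x$cost),
                                    colMeans(x$cost)), collapse = ", "), "\n")
  cat("Mean effect:", paste(sprintf("%s %.3f", colnames(x$effect),
                                    colMeans(x$effect)), collapse = ", "), "\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curves and frontier
#'
#' For each willingness-to-pay value, the probability that each strategy has
#' the maximal net monetary benefit across the PSA iterations. Exact NMB ties
#' within an iteration split the probability equally (a measure-zero event for
#' continuous draws, needed for degenerate registries). The acceptability
#' *frontier* marks, at each willingness-to-pay, the strategy with the highest
#' mean NMB.
#'
#' @param psa a `psa_result`.
#' @param wtp_grid willingness-to-pay grid in USD per unit of effectiveness
#'   (default 0 to 3500 in steps of 50).
#' @return data.frame of class `ceac_curve`: wtp, strategy, probability,
#'   on_frontier. Probabilities sum to 1 at every wtp.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 3500, by = 50)) {
  stopifnot(inherits(psa, "psa_result"), length(wtp_grid) >= 1,
            all(wtp_grid >= 0))
  S <- ncol(psa$cost)
  strategies <- colnames(psa$cost)
  n <- nrow(psa$cost)
  out <- vector("list", length(wtp_grid))
  for (i in seq_along(wtp_grid)) {
    lambda <- wtp_grid[i]
    nmb <- lambda * psa$effect - psa$cost
    best <- nmb == matrixStats_rowMax(nmb)
    w <- best / rowSums(best)       # split ties equally
    prob <- colSums(w) / n
    mean_nmb <- colMeans(nmb)
    out[[i]] <- data.frame(wtp = lambda, strategy = strategies,
                           probability = as.numeric(prob),
                           on_frontier = seq_len(S) == which.max(mean_nmb),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ceac_curve", "data.frame")
  res
}

## rowMaxs without a matrixStats dependency
matrixStats_rowMax <- function(m) {
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' CE-plane cloud from a PSA
#'
#' Long-format per-iteration (cost, effect) pairs for scatter plotting.
#'
#' @param psa a `psa_result`.
#' @return data.frame: iteration, strategy, cost, effect.
#' @export
ce_plane_cloud <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  strategies <- colnames(psa$cost)
  do.call(rbind, lapply(seq_along(strategies), function(j) {
    data.frame(iteration = seq_len(nrow(psa$cost)), strategy = strategies[j],
               cost = psa$cost[, j], effect = psa$effect[, j],
               stringsAsFactors = FALSE)
  }))
}
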