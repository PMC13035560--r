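#' Random decision trees with known structure
#'
#' Generates a valid random decision tree for oracle and property testing:
#' chance-node probabilities are drawn uniformly then normalized to sum to 1,
#' terminal payoffs are drawn in the given ranges (effectiveness anywhere in
#' \[0, 1\], deliberately wider than the binary episode outcome of the
#' sedation model), and interior nodes can carry accrued costs. Reproducible
#' from the seed.
#'
#' @param seed integer seed (mandatory).
#' @param n_strategies number of strategy arms.
#' @param max_depth maximum chance-node depth below each arm root (depth 1
#'   makes every arm a bare terminal).
#' @param branching integer range of children per chance node.
#' @param cost_range range of terminal/node costs (USD).
#' @param effect_range range of terminal effectiveness values within \[0, 1\].
#' @param p_terminal probability that a node below the root stops early.
#' @return a `decision_tree` that passes [validate_tree()].
#' @export
random_tree <- function(seed, n_strategies = 3, max_depth = 4,
                        branching = c(2, 4), cost_range = c(0, 100),
                        effect_range = c(0, 1), p_terminal = 0.3) {
  stopifnot(max_depth >= 1, branching[1] >= 1, branching[2] >= branching[1],
            effect_range[1] >= 0, effect_range[2] <= 1,
            diff(cost_range) >= 0)
  set.seed(seed)
  counter <- 0L
  next_id <- function() { counter <<- counter + 1L; counter }
  rcost <- function() stats::runif(1, cost_range[1], cost_range[2])
  grow <- function(depth) {
    if (depth >= max_depth || (depth > 1 && stats::runif(1) < p_terminal))
      return(terminal_node(paste0("t", next_id()), cost = rcost(),
                           effect = stats::runif(1, effect_range[1],
                                                 effect_range[2])))
    k <- sample(seq(branching[1], branching[2]), 1)
    p <- stats::runif(k)
    p <- p / sum(p)
    chance_node(paste0("c", next_id()), cost = rcost(),
                children = lapply(seq_len(k), function(i) grow(depth + 1)),
                probs = as.list(p))
  }
  arms <- lapply(seq_len(n_strategies), function(i) grow(1))
  names(arms) <- paste0("strategy_", seq_len(n_strategies))
  decision_tree(arms, label = paste0("synthetic_", seed))
}

#' Random parameter registries with recorded ground truth
#'
#' Builds a registry of beta/gamma/normal/fixed parameters with known true
#' moments, for sampler and fit-recovery tests. The truth (family, mean, sd)
#' is attached as attribute `truth`.
#'
#' @param seed integer seed.
#' @param n_params number of parameters.
#' @param families families to draw from.
#' @return a fitted `param_registry` with attribute `truth` (data.frame:
#'   name, family, mean, sd).
#' @export
random_registry <- function(seed, n_params = 8,
                            families = c("beta", "gamma", "normal", "fixed")) {
  set.seed(seed)
  specs <- vector("list", n_params)
  truth <- vector("list", n_params)
  for (i in seq_len(n_params)) {
    fam <- sample(families, 1)
    name <- sprintf("param_%02d_%s", i, fam)
    d <- switch(fam,
      beta = dist_beta(stats::runif(1, 2, 80), stats::runif(1, 2, 80)),
      gamma = dist_gamma(stats::runif(1, 4, 60), stats::runif(1, 0.5, 5)),
      normal = dist_normal(stats::runif(1, 20, 100), stats::runif(1, 1, 10),
                           floor = 0),
      fixed = dist_fixed(stats::runif(1, 1, 50)))
    role <- switch(fam, beta = "probability", gamma = "other",
                   normal = "other", fixed = "other")
    specs[[i]] <- param_spec(name, base_value = dist_mean(d), unit = "",
                             distribution = d, role = role)
    truth[[i]] <- data.frame(name = name, family = fam, mean = dist_mean(d),
                             sd = dist_sd(d), stringsAsFactors = FALSE)
  }
  reg <- param_registry(specs)
  attr(reg, "truth") <- do.call(rbind, truth)
  reg
}
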