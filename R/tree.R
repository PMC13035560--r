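#' Decision-tree node constructors
#'
#' A decision tree is built from three node kinds. `terminal_node()` carries the
#' episode payoff: a cost (USD) and an effectiveness value (for the sedation
#' model, 1 if first-line sedation succeeded, 0 otherwise; the generic engine
#' permits any value in \[0, 1\]). `chance_node()` splits on a clinical event,
#' with one probability expression per child; probabilities must resolve to
#' values summing to 1. A `decision_node()` may appear only at the root, where
#' its children are the strategies under comparison.
#'
#' Costs may be attached to any node (`cost`); they accumulate additively along
#' the root-to-terminal path, which is how stage costs (drug, procedure fee,
#' opportunity cost on an aborted scan) are accrued. Effectiveness is a
#' terminal-only payoff and never accumulates.
#'
#' Probabilities, costs and effects may be numeric constants or character
#' strings naming arithmetic expressions over registry parameters (e.g.
#' `"1 - p_triclofos"`); expressions are resolved at evaluation time so one
#' tree serves the base case, deterministic sweeps and probabilistic draws.
#'
#' @param label short node label used in path listings and validation messages.
#' @param cost cost accrued on reaching this node: a number or an expression
#'   string over parameter names.
#' @param effect terminal effectiveness payoff in \[0, 1\]: number or
#'   expression string.
#' @param children list of child nodes.
#' @param probs list (parallel to `children`) of edge probabilities: numbers or
#'   expression strings.
#' @return an object of class `ctree_node`.
#' @examples
#' arm <- chance_node("sedation", cost = 5,
#'   children = list(terminal_node("success", effect = 1),
#'                   terminal_node("failure", cost = 20, effect = 0)),
#'   probs = list(0.9, 0.1))
#' rollback(decision_tree(list(toy = arm)))
#' @export
terminal_node <- function(label, cost = 0, effect) {
  structure(list(kind = "terminal", label = label, cost = cost, effect = effect),
            class = "ctree_node")
}

#' @rdname terminal_node
#' @export
chance_node <- function(label, children, probs, cost = 0) {
  stopifnot(is.list(children), length(children) >= 1L)
  if (length(probs) != length(children))
    stop("chance_node '", label, "': need one probability per child")
  structure(list(kind = "chance", label = label, cost = cost,
                 children = children, probs = probs),
            class = "ctree_node")
}

#' @rdname terminal_node
#' @export
decision_node <- function(label, children) {
  structure(list(kind = "decision", label = label, cost = 0, children = children),
            class = "ctree_node")
}

#' Assemble a decision tree from named strategy arms
#'
#' @param strategies named list of `ctree_node` subtrees, one per strategy;
#'   names must be unique.
#' @param label root label.
#' @return object of class `decision_tree`: a root decision node whose children
#'   are the strategy arms.
#' @export
decision_tree <- function(strategies, label = "strategy") {
  nm <- names(strategies)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("strategies must be a uniquely named list")
  structure(list(label = label, strategies = strategies), class = "decision_tree")
}

#' @export
print.decision_tree <- function(x, ...) {
  cat("Decision tree <", x$label, "> with ", length(x$strategies),
      " strategies: ", paste(names(x$strategies), collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Resolve a numeric-or-expression field against a parameter environment.
## Values are recycled to a common draw length so the same tree evaluates the
## base case (scalars) and a whole PSA (length-n columns) in one pass.
resolve_expr <- function(x, env, n, what = "value") {
  if (is.null(x)) return(rep_len(0, n))
  if (is.numeric(x)) return(rep_len(x, n))
  if (!is.character(x) || length(x) != 1L)
    stop("cannot resolve ", what, ": expected number or expression string")
  expr <- tryCatch(parse(text = x)[[1]], error = function(e)
    stop("cannot parse ", what, " expression '", x, "': ", conditionMessage(e)))
  vars <- all.vars(expr)
  missing <- setdiff(vars, names(env))
  if (length(missing) > 0L)
    stop("unresolved parameter(s) in ", what, " '", x, "': ",
         paste(missing, collapse = ", "))
  val <- eval(expr, envir = env, enclos = baseenv())
  if (!is.numeric(val)) stop(what, " expression '", x, "' is not numeric")
  rep_len(val, n)
}

param_env_length <- function(params) {
  if (length(params) == 0L) return(1L)
  max(vapply(params, length, 1L))
}

#' Validate a decision tree
#'
#' Structural checks (terminals childless, non-terminals with at least one
#' child, interior decision nodes flagged, probability lists matching child
#' lists) plus, when parameter values are supplied, numeric checks: every
#' chance node's outgoing probabilities in \[0, 1\] and summing to 1 within
#' `tol`, and every expression resolvable.
#'
#' @param tree a `decision_tree`.
#' @param params named list/vector of parameter values used to resolve
#'   expressions; omit for structure-only validation.
#' @param tol tolerance on probability sums (default 1e-9).
#' @return character vector of violations; `character(0)` iff valid.
#' @export
validate_tree <- function(tree, params = NULL, tol = 1e-9) {
  stopifnot(inherits(tree, "decision_tree"))
  env <- if (is.null(params)) NULL else list2env(as.list(params), parent = baseenv())
  n <- if (is.null(params)) 1L else param_env_length(params)
  out <- character(0)
  note <- function(...) out <<- c(out, paste0(...))

  walk <- function(node, path) {
    if (!inherits(node, "ctree_node")) {
      note(path, ": not a ctree_node")
      return(invisible())
    }
    here <- paste0(path, "/", node$label)
    if (node$kind == "terminal") {
      if (!is.null(node$children) && length(node$children) > 0L)
        note(here, ": terminal node has children")
      if (is.null(node$effect))
        note(here, ": terminal node missing effectiveness payoff")
      else if (!is.null(env)) {
        e <- tryCatch(resolve_expr(node$effect, env, n, "effect"),
                      error = function(err) {note(here, ": ", conditionMessage(err)); NULL})
        if (!is.null(e) && any(e < -tol | e > 1 + tol))
          note(here, ": effectiveness outside [0, 1]")
      }
    } else if (node$kind == "chance") {
      if (length(node$children) < 1L) note(here, ": chance node has no children")
      if (length(node$probs) != length(node$children))
        note(here, ": probability count does not match child count")
      else if (!is.null(env)) {
        p <- tryCatch(
          vapply(node$probs, resolve_expr, numeric(n), env = env, n = n,
                 what = "probability"),
          error = function(err) {note(here, ": ", conditionMessage(err)); NULL})
        if (!is.null(p)) {
          p <- matrix(p, nrow = n)
          if (any(p < -tol | p > 1 + tol))
            note(here, ": edge probability outside [0, 1]")
          s <- rowSums(p)
          if (any(abs(s - 1) > tol))
            note(here, sprintf(": probabilities sum to %.6g", s[which.max(abs(s - 1))]))
        }
      }
      for (ch in node$children) walk(ch, here)
    } else if (node$kind == "decision") {
      note(here, ": decision nodes are only supported at the tree root")
    } else note(here, ": unknown node kind '", node$kind, "'")
    if (!is.null(env) && !is.null(node$cost)) {
      cst <- tryCatch(resolve_expr(node$cost, env, n, "cost"),
                      error = function(err) {note(here, ": ", conditionMessage(err)); NULL})
      if (!is.null(cst) && any(cst < 0)) note(here, ": negative cost")
    }
  }
  for (nm in names(tree$strategies)) walk(tree$strategies[[nm]], nm)
  out
}

## Core evaluator: returns list(cost, effect), each an n x n_strategies matrix.
eval_tree <- function(tree, params = NULL, n = NULL) {
  stopifnot(inherits(tree, "decision_tree"))
  params <- if (is.null(params)) list() else as.list(params)
  if (is.null(n)) n <- param_env_length(params)
  env <- list2env(params, parent = baseenv())

  node_value <- function(node) {
    cost <- resolve_expr(node$cost, env, n, "cost")
    if (any(cost < 0)) stop("negative cost at node '", node$label, "'")
    if (node$kind == "terminal") {
      eff <- resolve_expr(node$effect, env, n, "effect")
      return(list(cost = cost, effect = eff))
    }
    if (node$kind != "chance")
      stop("rollback: unsupported interior node kind '", node$kind, "'")
    ec <- numeric(n); ee <- numeric(n); psum <- numeric(n)
    for (i in seq_along(node$children)) {
      p <- resolve_expr(node$probs[[i]], env, n, "probability")
      if (any(p < -1e-12 | p > 1 + 1e-12))
        stop("probability outside [0, 1] at node '", node$label, "'")
      child <- node_value(node$children[[i]])
      ec <- ec + p * child$cost
      ee <- ee + p * child$effect
      psum <- psum + p
    }
    if (any(abs(psum - 1) > 1e-9))
      stop("probabilities at node '", node$label, "' sum to ",
           format(psum[which.max(abs(psum - 1))], digits = 10))
    list(cost = cost + ec, effect = ee)
  }

  S <- length(tree$strategies)
  cost <- matrix(NA_real_, n, S, dimnames = list(NULL, names(tree$strategies)))
  effect <- cost
  for (j in seq_len(S)) {
    v <- node_value(tree$strategies[[j]])
    cost[, j] <- v$cost
    effect[, j] <- v$effect
  }
  list(cost = cost, effect = effect)
}

#' Expected-value rollback
#'
#' Computes each strategy's expected cost and expected effectiveness bottom-up:
#' terminals return their payoff, chance nodes the probability-weighted sum of
#' their children, and node costs accrue additively along paths.
#'
#' @inheritParams validate_tree
#' @param params named list of resolved parameter values (scalars).
#' @return data.frame with columns `strategy`, `expected_cost`,
#'   `expected_effect`, one row per strategy in tree order.
#' @seealso [enumerate_paths()] for the exhaustive path-by-path oracle.
#' @export
rollback <- function(tree, params = NULL) {
  v <- eval_tree(tree, params, n = 1L)
  data.frame(strategy = colnames(v$cost),
             expected_cost = as.numeric(v$cost[1, ]),
             expected_effect = as.numeric(v$effect[1, ]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exhaustive root-to-terminal path enumeration
#'
#' Independent of [rollback()]: walks every root-to-terminal path, multiplying
#' edge probabilities and summing node costs. Per strategy the path
#' probabilities sum to 1 and the probability-weighted cost/effect totals equal
#' the rollback output (used as a test oracle).
#'
#' @inheritParams rollback
#' @return data.frame with columns `strategy`, `path` (slash-separated labels),
#'   `probability`, `cost`, `effect`.
#' @export
enumerate_paths <- function(tree, params = NULL) {
  stopifnot(inherits(tree, "decision_tree"))
  params <- if (is.null(params)) list() else as.list(params)
  if (param_env_length(params) != 1L)
    stop("enumerate_paths expects scalar parameter values")
  env <- list2env(params, parent = baseenv())
  res <- list()
  walk <- function(node, strategy, prob, cost, path) {
    cost <- cost + resolve_expr(node$cost, env, 1L, "cost")
    path <- paste0(path, "/", node$label)
    if (node$kind == "terminal") {
      eff <- resolve_expr(node$effect, env, 1L, "effect")
      res[[length(res) + 1L]] <<- data.frame(
        strategy = strategy, path = path, probability = prob,
        cost = cost, effect = eff, stringsAsFactors = FALSE)
      return(invisible())
    }
    for (i in seq_along(node$children)) {
      p <- resolve_expr(node$probs[[i]], env, 1L, "probability")
      walk(node$children[[i]], strategy, prob * p, cost, path)
    }
  }
  for (nm in names(tree$strategies)) walk(tree$strategies[[nm]], nm, 1, 0, nm)
  do.call(rbind, res)
}

node_to_list <- function(node) {
  out <- list(kind = node$kind, label = node$label)
  if (!is.null(node$cost)) out$cost <- node$cost
  if (node$kind == "terminal") {
    out$effect <- node$effect
  } else {
    out$children <- lapply(node$children, node_to_list)
    if (node$kind == "chance") out$probs <- node$probs
  }
  out
}

node_from_list <- function(x) {
  switch(x$kind,
    terminal = terminal_node(x$label, cost = if (is.null(x$cost)) 0 else x$cost,
                             effect = x$effect),
    chance = chance_node(x$label, children = lapply(x$children, node_from_list),
                         probs = as.list(x$probs),
                         cost = if (is.null(x$cost)) 0 else x$cost),
    stop("unknown node kind '", x$kind, "' in serialized tree"))
}

#' Read and write decision trees as YAML
#'
#' Trees serialize to a structured config (node kind, label, cost/probability
#' expressions) and round-trip losslessly.
#'
#' @param tree a `decision_tree`.
#' @param path file path.
#' @return `write_tree()` returns `path` invisibly; `read_tree()` returns the
#'   reconstructed `decision_tree`.
#' @export
write_tree <- function(tree, path) {
  obj <- list(label = tree$label,
              strategies = lapply(tree$strategies, node_to_list))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- yaml::read_yaml(path)
  decision_tree(lapply(obj$strategies, node_from_list), label = obj$label)
}
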