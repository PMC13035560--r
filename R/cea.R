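#' Incremental cost-effectiveness table
#'
#' For every strategy, the incremental cost and incremental effectiveness
#' versus a common reference and their ratio (ICER, USD per unit of
#' effectiveness). ICERs are reported with their sign for dominated strategies
#' too, matching the convention of publishing negative ICERs alongside a
#' dominance label; a ratio with |incremental effect| below `eps` is reported
#' as `NA` (undefined), never as infinity. Dominance status and the efficiency
#' frontier come from [dominance_classification()].
#'
#' @param results data.frame with columns `strategy`, `expected_cost`,
#'   `expected_effect` (as returned by [rollback()]), or `cost`/`effect`.
#' @param reference name of the reference strategy.
#' @param eps threshold below which an effectiveness difference counts as zero.
#' @return data.frame of class `cea_table`: strategy, cost, effect, incr_cost,
#'   incr_effect, icer (all vs reference), status, on_frontier, frontier_icer.
#' @export
icer_table <- function(results, reference, eps = 1e-12) {
  r <- normalize_results(results)
  if (anyDuplicated(r$strategy))
    stop("duplicate strategy names: ",
         paste(unique(r$strategy[duplicated(r$strategy)]), collapse = ", "))
  if (!reference %in% r$strategy)
    stop("reference strategy '", reference, "' not found")
  ref <- r[r$strategy == reference, ]
  dc <- r$cost - ref$cost
  de <- r$effect - ref$effect
  icer <- ifelse(abs(de) < eps, NA_real_, dc / de)
  is_ref <- r$strategy == reference
  dc[is_ref] <- NA_real_; de[is_ref] <- NA_real_; icer[is_ref] <- NA_real_
  dom <- dominance_classification(r)
  out <- data.frame(strategy = r$strategy, cost = r$cost, effect = r$effect,
                    incr_cost = dc, incr_effect = de, icer = icer,
                    status = dom$status, on_frontier = dom$on_frontier,
                    frontier_icer = dom$frontier_icer,
                    tie = dom$tie, stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  class(out) <- c("cea_table", "data.frame")
  out
}

normalize_results <- function(results) {
  d <- as.data.frame(results)
  if (all(c("expected_cost", "expected_effect") %in% names(d))) {
    d$cost <- d$expected_cost
    d$effect <- d$expected_effect
  }
  if (!all(c("strategy", "cost", "effect") %in% names(d)))
    stop("results need columns strategy and cost/effect")
  d[, c("strategy", "cost", "effect")]
}

#' Dominance classification and efficiency frontier
#'
#' A strategy is *absolutely dominated* if some other strategy costs no more
#' and is at least as effective, with at least one strict inequality (ties on
#' both axes dominate neither; they are kept and flagged). Among the
#' survivors, sorted by increasing effectiveness, *extended dominance* removes
#' any strategy whose ICER versus the previous frontier member exceeds the
#' ICER of the next (the standard lower-convex-hull sweep). The remaining
#' strategies form the efficiency frontier; their pairwise ICERs are strictly
#' increasing in effectiveness.
#'
#' @inheritParams icer_table
#' @return list with `status` (per input strategy: undominated,
#'   absolutely_dominated, extendedly_dominated), `on_frontier`,
#'   `frontier_icer` (ICER vs the previous frontier strategy; NA for the
#'   cheapest), `tie` (exact cost+effect duplicate), and `frontier` (names in
#'   order of increasing effectiveness).
#' @export
dominance_classification <- function(results) {
  r <- normalize_results(results)
  n <- nrow(r)
  stopifnot(n >= 1)
  status <- rep("undominated", n)
  tie <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (r$cost[j] == r$cost[i] && r$effect[j] == r$effect[i]) {
        tie[i] <- TRUE
      } else if (r$cost[j] <= r$cost[i] && r$effect[j] >= r$effect[i]) {
        status[i] <- "absolutely_dominated"
      }
    }
  }
  ## Extended dominance: convex-hull sweep over survivors ordered by effect.
  surv <- which(status == "undominated")
  ord <- surv[order(r$effect[surv], r$cost[surv])]
  repeat {
    if (length(ord) < 3L) break
    removed <- FALSE
    for (k in seq(2L, length(ord) - 1L)) {
      prev <- ord[k - 1L]; cur <- ord[k]; nxt <- ord[k + 1L]
      icer_prev <- (r$cost[cur] - r$cost[prev]) / (r$effect[cur] - r$effect[prev])
      icer_next <- (r$cost[nxt] - r$cost[cur]) / (r$effect[nxt] - r$effect[cur])
      if (icer_prev > icer_next) {
        status[cur] <- "extendedly_dominated"
        ord <- ord[-k]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  on_frontier <- status == "undominated"
  frontier_icer <- rep(NA_real_, n)
  if (length(ord) > 1L)
    for (k in seq(2L, length(ord))) {
      cur <- ord[k]; prev <- ord[k - 1L]
      frontier_icer[cur] <- (r$cost[cur] - r$cost[prev]) /
        (r$effect[cur] - r$effect[prev])
    }
  list(status = status, on_frontier = on_frontier,
       frontier_icer = frontier_icer, tie = tie,
       frontier = r$strategy[ord])
}

#' Net monetary benefit
#'
#' NMB = lambda x effect - cost at willingness-to-pay lambda (USD per unit of
#' effectiveness). Maximizing NMB is equivalent to ICER-threshold decision
#' making; two strategies have equal NMB exactly at their pairwise ICER.
#'
#' @inheritParams icer_table
#' @param wtp willingness-to-pay lambda (scalar or vector, >= 0).
#' @return data.frame: strategy, wtp, nmb (one row per strategy x wtp).
#' @export
nmb <- function(results, wtp) {
  stopifnot(all(wtp >= 0))
  r <- normalize_results(results)
  out <- expand.grid(strategy = r$strategy, wtp = wtp,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(out$strategy, r$strategy)
  out$nmb <- out$wtp * r$effect[idx] - r$cost[idx]
  out
}

#' Presentation rounding for cost-effectiveness tables
#'
#' Costs and ICERs to 2 decimals, effectiveness to 3; internal arithmetic is
#' never rounded.
#'
#' @param x a `cea_table`.
#' @return data.frame rounded for display.
#' @export
format_cea <- function(x) {
  stopifnot(inherits(x, "cea_table"))
  out <- as.data.frame(x)
  for (col in c("cost", "incr_cost", "icer", "frontier_icer"))
    out[[col]] <- round(out[[col]], 2)
  for (col in c("effect", "incr_effect"))
    out[[col]] <- round(out[[col]], 3)
  out
}

#' @export
print.cea_table <- function(x, ...) {
  cat("Cost-effectiveness table (reference: ", attr(x, "reference"), ")\n", sep = "")
  print(format_cea(x))
  invisible(x)
}
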