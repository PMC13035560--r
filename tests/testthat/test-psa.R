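# Small fully-specified two-strategy model for PSA mechanics: terminal costs
# are sampled parameters, effects fixed.
psa_toy <- function() {
  tree <- decision_tree(list(
    cheap = terminal_node("cheap", cost = "c_a", effect = 0.5),
    effective = terminal_node("effective", cost = "c_b", effect = 0.6)))
  reg <- param_registry(list(
    param_spec("c_a", 50, distribution = dist_gamma((50 / 10)^2, 10^2 / 50),
               role = "other"),
    param_spec("c_b", 60, distribution = dist_gamma((60 / 10)^2, 10^2 / 60),
               role = "other")))
  list(tree = tree, reg = reg)
}

test_that("a degenerate PSA (all distributions fixed) reproduces the base case", {
  reg <- table1_registry()
  for (nm in names(reg$specs))
    reg$specs[[nm]]$distribution <- dist_fixed(reg$specs[[nm]]$base_value)
  tree <- build_sedation_model(reg)
  psa <- run_psa(tree, reg, n_iterations = 25, seed = 1)
  rb <- rollback(tree, base_values(reg))
  for (i in seq_len(25)) {
    expect_equal(as.numeric(psa$cost[i, ]), rb$expected_cost)
    expect_equal(as.numeric(psa$effect[i, ]), rb$expected_effect)
  }
})

test_that("the same seed gives bitwise-identical PSA results", {
  reg <- table1_registry()
  tree <- build_sedation_model(reg)
  a <- run_psa(tree, reg, n_iterations = 300, seed = 123)
  b <- run_psa(tree, reg, n_iterations = 300, seed = 123)
  expect_identical(a$cost, b$cost)
  expect_identical(a$effect, b$effect)
  c <- run_psa(tree, reg, n_iterations = 300, seed = 124)
  expect_false(identical(a$cost, c$cost))
})

test_that("PSA means recover the base case under proportional billing", {
  # with proportional vial billing the tree is multilinear in independent
  # parameters, so iteration means converge on the base-case expected values
  reg <- table1_registry()
  tree <- build_sedation_model(reg, sedation_config(billing = "proportional"))
  n <- 4000
  psa <- run_psa(tree, reg, n_iterations = n, seed = 99)
  rb <- rollback(tree, base_values(reg))
  for (j in seq_len(ncol(psa$cost))) {
    se_c <- sd(psa$cost[, j]) / sqrt(n)
    expect_lt(abs(mean(psa$cost[, j]) - rb$expected_cost[j]), 4 * se_c,
              label = paste("cost mean,", colnames(psa$cost)[j]))
    se_e <- sd(psa$effect[, j]) / sqrt(n)
    if (se_e == 0) {  # GA effectiveness is certain by construction
      expect_equal(mean(psa$effect[, j]), rb$expected_effect[j])
    } else {
      expect_lt(abs(mean(psa$effect[, j]) - rb$expected_effect[j]), 4 * se_e,
                label = paste("effect mean,", colnames(psa$effect)[j]))
    }
  }
})

test_that("CEAC probabilities partition at every willingness-to-pay", {
  toy <- psa_toy()
  psa <- run_psa(toy$tree, toy$reg, n_iterations = 2000, seed = 8)
  cc <- ceac(psa, wtp_grid = seq(0, 500, by = 25))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # exactly one frontier strategy per wtp
  expect_equal(as.numeric(tapply(cc$on_frontier, cc$wtp, sum)),
               rep(1, length(sums)))
})

test_that("the strategy that is cheapest by construction wins at wtp 0", {
  tree <- decision_tree(list(
    low = terminal_node("low", cost = "c_lo", effect = 0.3),
    high = terminal_node("high", cost = "c_lo + bump", effect = 0.9)))
  reg <- param_registry(list(
    param_spec("c_lo", 20, distribution = dist_gamma(16, 20 / 16), role = "other"),
    param_spec("bump", 10, distribution = dist_gamma(25, 10 / 25), role = "other")))
  psa <- run_psa(tree, reg, n_iterations = 500, seed = 3)
  cc <- ceac(psa, wtp_grid = 0)
  expect_equal(cc$probability[cc$strategy == "low"], 1)
})

test_that("exact NMB ties split probability equally", {
  tree <- decision_tree(list(
    a = terminal_node("a", cost = 10, effect = 0.5),
    b = terminal_node("b", cost = 10, effect = 0.5),
    c = terminal_node("c", cost = 50, effect = 0.5)))
  reg <- param_registry(list(param_spec("unused", 1,
                                        distribution = dist_fixed(1),
                                        role = "other")))
  psa <- run_psa(tree, reg, n_iterations = 10, seed = 1)
  cc <- ceac(psa, wtp_grid = c(0, 100))
  expect_equal(cc$probability[cc$strategy %in% c("a", "b")], rep(0.5, 4))
  expect_equal(cc$probability[cc$strategy == "c"], rep(0, 2))
})

test_that("the acceptability frontier never exceeds the maximum CEAC", {
  toy <- psa_toy()
  psa <- run_psa(toy$tree, toy$reg, n_iterations = 1000, seed = 21)
  cc <- ceac(psa, wtp_grid = seq(0, 400, by = 50))
  for (w in unique(cc$wtp)) {
    at <- cc[cc$wtp == w, ]
    expect_lte(at$probability[at$on_frontier], max(at$probability))
  }
})

test_that("CEAC Monte-Carlo error scales roughly as 1/sqrt(n)", {
  toy <- psa_toy()
  # lambda = 100: NMB difference is centred near zero, maximizing variance
  p_at <- function(n, seed) {
    psa <- run_psa(toy$tree, toy$reg, n_iterations = n, seed = seed)
    cc <- ceac(psa, wtp_grid = 100)
    cc$probability[cc$strategy == "cheap"]
  }
  seeds <- 1:30
  sd_small <- sd(vapply(seeds, function(s) p_at(400, s), numeric(1)))
  sd_large <- sd(vapply(seeds + 500, function(s) p_at(1600, s), numeric(1)))
  expect_gt(sd_small / sd_large, 1.3)   # ideal ratio 2 for a 4x larger n
  expect_lt(sd_small / sd_large, 3.1)
})
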