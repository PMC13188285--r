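test_that("average ratio reproduces forced arithmetic and identity cases", {
  st <- study_table(paste0("s", 1:6),
                    c("A", "A", "A", "A", "B", "B"),
                    c("dried", "dried", "frozen", "frozen", "dried", "frozen"),
                    metrics = data.frame(yield = c(2, 2, 4, 4, 1, 4)))
  r <- average_ratio(st, "yield", "dried", "frozen")
  expect_equal(r$per_material_ratios, c(A = 0.5, B = 0.25))
  expect_equal(r$average_ratio, 0.375)

  same <- make_design(3, 2, values = rep(7, 12))
  rs <- average_ratio(same, "m", "dried", "frozen")
  expect_equal(unname(rs$per_material_ratios), rep(1, 3))
  expect_equal(rs$average_ratio, 1)

  # geometric averaging
  rg <- average_ratio(st, "yield", "dried", "frozen",
                      mean_type = "geometric")
  expect_equal(rg$average_ratio, sqrt(0.5 * 0.25))
})

test_that("average ratio validates its inputs", {
  st <- study_table(paste0("s", 1:4), rep("A", 4),
                    c("dried", "dried", "frozen", "frozen"),
                    metrics = data.frame(m = c(1, 2, 0, 0)))
  expect_error(average_ratio(st, "m", "dried", "frozen"),
               "zero denominator mean in material 'A'")
  expect_error(average_ratio(st, "nope", "dried", "frozen"), "available")

  lopsided <- study_table(paste0("s", 1:4),
                          c("A", "A", "B", "B"),
                          c("dried", "frozen", "dried", "dried"),
                          metrics = data.frame(m = 1:4))
  expect_error(average_ratio(lopsided, "m", "dried", "frozen"), "material 'B'")
})

test_that("samples with missing metric values are dropped, with a count", {
  st <- study_table(paste0("s", 1:6), rep("A", 6),
                    rep(c("dried", "frozen"), each = 3),
                    metrics = data.frame(m = c(2, 2, NA, 1, 1, NA)))
  r <- average_ratio(st, "m", "dried", "frozen")
  expect_equal(r$average_ratio, 2)
  expect_equal(r$n_dropped, 2)
})

test_that("stratified assignment counts follow the product of binomials", {
  st <- make_design(1, 2)
  expect_equal(count_stratified_assignments(st, "m", "dried", "frozen"),
               choose(4, 2))
  big <- make_design(6, 5)
  expect_equal(count_stratified_assignments(big, "m", "dried", "frozen"),
               choose(10, 5)^6)
  empty <- study_table(character(0), character(0), character(0))
  expect_equal(count_stratified_assignments(empty, "m", "dried", "frozen"), 1)
})

test_that("ratio statistic is equivariant and per-material swap-reciprocal", {
  set.seed(21)
  for (rep in 1:5) {
    st <- simulate_metric_table(n_materials = 3, n_replicates = 3,
                                delta = runif(1, 0.3, 3),
                                sigma = 0.4, seed = 100 + rep)
    base <- average_ratio(st, "metric", "dried", "frozen")
    c0 <- 2.5
    scaled <- st
    scaled$metric <- ifelse(scaled$treatment == "dried",
                            scaled$metric * c0, scaled$metric)
    scaled <- study_table(scaled$sample_id, scaled$material,
                          scaled$treatment,
                          data.frame(metric = scaled$metric))
    expect_equal(average_ratio(scaled, "metric", "dried", "frozen")$average_ratio,
                 c0 * base$average_ratio, tolerance = 1e-12)

    swapped <- average_ratio(st, "metric", "frozen", "dried")
    expect_equal(swapped$per_material_ratios,
                 1 / base$per_material_ratios, tolerance = 1e-12)
  }
})

test_that("exhaustive mode equals an independent brute-force enumeration", {
  # the canonical strong-effect design: 2 materials, dried {10,10}, frozen {1,1}
  st <- study_table(paste0("s", 1:8), rep(c("A", "B"), each = 4),
                    rep(c("dried", "dried", "frozen", "frozen"), 2),
                    metrics = data.frame(m = rep(c(10, 10, 1, 1), 2)))
  res <- ratio_permutation_test(st, "m", "dried", "frozen")
  expect_equal(res$mode, "exhaustive")
  expect_equal(res$n_permutations, 36)
  p_oracle <- oracle_ratio_p(list(c(10, 10, 1, 1), c(10, 10, 1, 1)),
                             list(2, 2), res$average_ratio)
  expect_equal(res$p_value, p_oracle)
  expect_equal(p_oracle, 2 / 36)  # only the two all-or-nothing assignments

  # randomized small designs, observed not at the extreme
  for (s in 1:4) {
    set.seed(300 + s)
    vals <- rlnorm(12, sd = 0.8)
    st2 <- study_table(paste0("s", 1:12), rep(c("A", "B", "C"), each = 4),
                       rep(c("dried", "dried", "frozen", "frozen"), 3),
                       metrics = data.frame(m = vals))
    res2 <- ratio_permutation_test(st2, "m", "dried", "frozen")
    # subset enumeration is order-free, so material order within vbm is moot
    vbm <- split(vals, rep(c("A", "B", "C"), each = 4))
    expect_equal(res2$p_value,
                 oracle_ratio_p(vbm, list(2, 2, 2), res2$average_ratio))
  }
})

test_that("degenerate all-identical data gives average ratio 1 and p = 1", {
  st <- make_design(2, 3, values = rep(4.2, 12))
  res <- ratio_permutation_test(st, "m", "dried", "frozen")
  expect_equal(res$average_ratio, 1)
  expect_equal(res$p_value, 1)
})

test_that("Monte-Carlo p agrees with the exhaustive p within binomial error", {
  st <- study_table(paste0("s", 1:8), rep(c("A", "B"), each = 4),
                    rep(c("dried", "dried", "frozen", "frozen"), 2),
                    metrics = data.frame(m = c(3, 5, 2, 4, 10, 7, 6, 12)))
  exact <- ratio_permutation_test(st, "m", "dried", "frozen")
  expect_equal(exact$mode, "exhaustive")
  n_mc <- 20000
  mc <- ratio_permutation_test(st, "m", "dried", "frozen", n_perm = n_mc,
                               seed = 99, exhaustive_limit = 0)
  expect_equal(mc$mode, "monte_carlo")
  se <- sqrt(exact$p_value * (1 - exact$p_value) / n_mc)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 2 / n_mc)
})

test_that("one-sided alternatives target the corresponding tails", {
  st <- study_table(paste0("s", 1:8), rep(c("A", "B"), each = 4),
                    rep(c("dried", "dried", "frozen", "frozen"), 2),
                    metrics = data.frame(m = rep(c(1, 1, 10, 10), 2)))
  less <- ratio_permutation_test(st, "m", "dried", "frozen",
                                 sidedness = "less")
  greater <- ratio_permutation_test(st, "m", "dried", "frozen",
                                    sidedness = "greater")
  expect_lt(less$p_value, 0.1)   # observed ratio 0.1 is the low extreme
  expect_equal(greater$p_value, 1)
})
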