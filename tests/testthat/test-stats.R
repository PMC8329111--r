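test_that("Spearman rho and exact permutation p match full enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 3, 1, 4, 5)     # sum d^2 = 6 -> rho = 1 - 36/120 = 0.7
  res <- spearman(x, y)
  orc <- oracle_spearman(x, y)
  expect_equal(res$statistic, 0.7)
  expect_equal(orc$rho, 0.7)
  expect_equal(res$p_value, orc$p)
  # cross-check against the independent exact implementation in stats::
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(res$p_value, unname(ct$p.value), tolerance = 1e-12)

  y2 <- c(2, 1, 4, 3, 5)    # sum d^2 = 4 -> rho = 0.8
  res2 <- spearman(x, y2)
  expect_equal(res2$statistic, 0.8)
  expect_equal(res2$p_value, oracle_spearman(x, y2)$p)

  expect_equal(spearman(1:8, 1:8)$statistic, 1)
  expect_equal(spearman(1:8, 8:1)$statistic, -1)
  expect_error(spearman(rep(1, 5), 1:5), class = "segsim_degenerate_error")
  expect_error(spearman(1:2, 1:2), class = "segsim_precondition_error")
})

test_that("Spearman is symmetric and invariant under strictly monotone transforms", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(c(6, 15, 40), 1)
    x <- rnorm(n); y <- rnorm(n)
    a <- spearman(x, y); b <- spearman(y, x)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p_value, b$p_value)
    tr <- spearman(exp(x), y)
    expect_equal(a$statistic, tr$statistic, tolerance = 1e-12)
    expect_equal(a$p_value, tr$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U: exact p from labeling enumeration on a worked example", {
  # U = 0; enumerate all C(6,3) = 20 group labelings of the pooled values:
  # only the observed split and its mirror are as extreme -> p = 2/20 = 0.1
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  res <- mann_whitney_u(g1, g2)
  expect_equal(res$statistic, 0)
  pooled <- c(g1, g2)
  labelings <- combn(6, 3)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - 3 * 4 / 2
  }
  u_obs <- min(u_of(1:3), 9 - u_of(1:3))
  u_all <- apply(labelings, 2, function(idx) min(u_of(idx), 9 - u_of(idx)))
  expect_equal(res$p_value, mean(u_all <= u_obs))
  expect_equal(res$p_value, 0.1)

  expect_equal(mann_whitney_u(c(1.3, 2.7, 3.1), c(1.3, 2.7, 3.1))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:5), class = "segsim_precondition_error")
  expect_error(mann_whitney_u(1, 1:2), class = "segsim_precondition_error")
})

test_that("Mann-Whitney U is invariant under common strictly monotone transforms", {
  set.seed(72)
  g1 <- rnorm(12); g2 <- rnorm(15, 0.8)
  a <- mann_whitney_u(g1, g2)
  b <- mann_whitney_u(exp(g1), exp(g2))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("Kruskal-Wallis H matches the rank formula and gates the post-hoc tests", {
  # tie-free groups (1,2), (3,4), (5,6): H = 12/(n(n+1)) * sum n_i rbar_i^2 - 3(n+1)
  groups <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  rbar <- c(1.5, 3.5, 5.5)
  H <- 12 / (6 * 7) * sum(2 * rbar^2) - 3 * 7
  res <- kruskal_wallis_with_posthoc(groups, alpha = 0.05)
  expect_equal(res$statistic[1], H)
  expect_equal(res$statistic[1], unname(kruskal.test(groups)$statistic))

  # three identical groups: omnibus p ~ 1, no post-hoc rows
  same <- list(g1 = c(1.1, 2.2, 3.3), g2 = c(1.1, 2.2, 3.3), g3 = c(1.1, 2.2, 3.3))
  res2 <- kruskal_wallis_with_posthoc(same)
  expect_equal(nrow(res2), 1L)
  expect_gt(res2$p_value[1], 0.9)

  # one group shifted far: omnibus significant, 3 pairwise rows with
  # Bonferroni-adjusted p = min(1, 3p)
  set.seed(73)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 5))
  res3 <- kruskal_wallis_with_posthoc(g)
  expect_equal(nrow(res3), 4L)
  expect_lt(res3$p_value[1], 0.001)
  ph <- res3[-1, ]
  expect_equal(ph$adjusted_p, pmin(1, ph$p_value * 3))
  expect_true(all(ph$adjusted_p >= ph$p_value))
  expect_true(all(ph$adjusted_p <= 1))

  expect_error(kruskal_wallis_with_posthoc(list(1:3, 4:6)),
               class = "segsim_routing_error")
  expect_error(kruskal_wallis_with_posthoc(list(1:3, 4:6, 7)),
               class = "segsim_precondition_error")
})

test_that("Kruskal-Wallis with 2 groups agrees with the Mann-Whitney decision", {
  set.seed(74)
  for (rep in 1:10) {
    g1 <- rnorm(8); g2 <- rnorm(9, 0.5)
    kw <- kruskal.test(list(g1, g2))$p.value
    mw <- mann_whitney_u(g1, g2)$p_value  # approx path would differ slightly;
    # compare decisions at alpha = 0.05 on tie-free data
    expect_equal(kw < 0.05, mw < 0.05)
  }
})

test_that("Shapiro-Wilk gate rejects heavy lognormal data and validates input", {
  set.seed(75)
  x <- exp(rnorm(50, sd = 1.5))
  res <- suppressMessages(shapiro_wilk(x, "lognormal"))
  expect_lt(res$p_value, 0.001)
  expect_message(shapiro_wilk(x), "nonparametric")
  expect_error(suppressMessages(shapiro_wilk(c(1, 2))),
               class = "segsim_precondition_error")
  expect_error(suppressMessages(shapiro_wilk(rep(2, 10))),
               class = "segsim_degenerate_error")
  # calibration: rejection rate near nominal alpha for normal samples
  set.seed(76)
  rej <- mean(replicate(400, shapiro.test(rnorm(50))$p.value < 0.05))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("metric_time_correlation_table ranks by |rho|, preserves signs, drops constants", {
  set.seed(77)
  n <- 60
  err <- rexp(n, 1 / 50)                 # latent error burden
  panel <- data.frame(
    case_id = sprintf("c%02d", 1:n),
    apl_px = err * 10 + rnorm(n, sd = 20),       # strong error metric
    volumetric_dsc = 1 - err / max(err) * 0.2 + rnorm(n, sd = 0.15), # weak similarity
    flat = rep(3.3, n))
  cases <- data.frame(case_id = panel$case_id,
                      correction_time = 5 + 0.3 * err * 10 * exp(rnorm(n, sd = 0.1)))
  tab <- metric_time_correlation_table(panel, cases)
  expect_equal(attr(tab, "excluded"), "flat")
  expect_equal(tab$metric[1], "apl_px")
  expect_gt(tab$rho[tab$metric == "apl_px"], 0)
  expect_lt(tab$rho[tab$metric == "volumetric_dsc"], 0)
  expect_true(all(diff(abs(tab$rho)) <= 1e-15))

  # permutation of case order changes nothing
  perm <- sample(n)
  tab2 <- metric_time_correlation_table(panel[perm, ], cases)
  expect_equal(tab$rho, tab2$rho)
  expect_equal(tab$p_value, tab2$p_value)

  expect_error(metric_time_correlation_table(panel[1:2, ], cases[1:2, ]),
               class = "segsim_insufficient_data_error")
})
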