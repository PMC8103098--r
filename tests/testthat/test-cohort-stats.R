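test_that("Kaplan-Meier matches hand-computed product-limit values", {
  km <- km_fit(c(5, 8, 12), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  km2 <- km_fit(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 2], 2 / 3)
  expect_equal(km2$surv[km2$time == 6], 0)
  # all censored: S stays 1
  km3 <- km_fit(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  # no censoring: KM equals the empirical survival function
  set.seed(1)
  t <- rexp(40); e <- rep(1, 40)
  km4 <- km_fit(t, e)
  ecdf_surv <- vapply(km4$time, function(u) mean(t > u), 0)
  expect_equal(km4$surv, ecdf_surv, tolerance = 1e-12)
  expect_true(all(diff(km4$surv) <= 0))
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test matches the hand oracle and its invariances", {
  # worked example: A = (1,2) both events, B = (3,4) both events
  t <- c(1, 2, 3, 4); e <- rep(1, 4); g <- c("A", "A", "B", "B")
  lr <- logrank_test(t, e, g)
  expect_equal(lr$statistic, logrank_by_hand(t, e, g), tolerance = 1e-10)
  expect_equal(lr$statistic, 2.88, tolerance = 0.01)
  expect_equal(lr$df, 1)
  # two identical groups: statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # k duplicated groups: statistic 0
  lrk <- logrank_test(rep(c(1, 2, 3), 3), rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(lrk$statistic, 0, tolerance = 1e-12)
  # relabeling invariance
  set.seed(5)
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.8); g2 <- rep(c("x", "y"), 15)
  expect_equal(logrank_test(t2, e2, g2)$statistic,
               logrank_test(t2, e2, ifelse(g2 == "x", "y", "x"))$statistic,
               tolerance = 1e-12)
  expect_error(logrank_test(t2, e2, factor(g2, levels = c("x", "y", "z"))),
               "empty group")
})

test_that("Cox fits agree with symmetry, a grid-search oracle, and log-rank", {
  # exchangeable groups: beta 0, HR 1
  d_sym <- data.frame(time = rep(c(1, 2, 3), 2), event = 1,
                      grp = rep(c(0, 1), each = 3))
  f_sym <- cox_fit(d_sym, "time", "event", "grp", ties = "breslow")
  expect_equal(f_sym$table$beta, 0, tolerance = 1e-8)
  expect_equal(f_sym$table$hr, 1, tolerance = 1e-8)
  # brute-force partial-likelihood maximizer, binary covariate
  d <- data.frame(time = c(1, 3, 2, 4), event = 1, x = c(1, 1, 0, 0))
  f <- cox_fit(d, "time", "event", "x", ties = "breslow")
  oracle <- cox_grid_oracle(d$time, d$event, d$x)
  expect_equal(f$table$beta, oracle, tolerance = 1e-3)
  # two-group score test equals the log-rank statistic on untied data
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(10:30, 1)
    dd <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.8),
                     x = rbinom(n, 1, 0.5))
    if (sum(dd$event) == 0 || length(unique(dd$x)) < 2) next
    if (min(table(dd$x[dd$event == 1])) == 0) next
    sc <- cox_fit(dd, "time", "event", "x")$score_test
    lr <- logrank_test(dd$time, dd$event, dd$x)$statistic
    expect_equal(sc, lr, tolerance = 1e-6)
  }
  # constant covariate named in the error
  d_const <- data.frame(time = 1:4, event = 1, x = 1)
  expect_error(cox_fit(d_const, "time", "event", "x"), "'x'")
})

test_that("Cox fit reports reference levels, CIs and missingness", {
  set.seed(21)
  n <- 120
  d <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.8),
                  stage = sample(c("I", "II", "III"), n, replace = TRUE),
                  age = rnorm(n, 60, 8))
  d$age[1:5] <- NA
  f <- cox_fit(d, "time", "event", c("stage", "age"))
  expect_equal(f$n_used, n - 5)
  expect_equal(f$n_missing, 5)
  tab <- f$table
  expect_true(tab$ref[tab$term == "stage" & tab$level == "I"])
  non_ref <- tab[!tab$ref, ]
  expect_true(all(non_ref$hr > 0))
  expect_true(all(non_ref$ci_lower <= non_ref$hr &
                    non_ref$hr <= non_ref$ci_upper))
  # Wald CI reproduces exp(beta +/- 1.96 se)
  se <- sqrt(diag(f$fit$var))
  expect_equal(non_ref$ci_lower,
               exp(non_ref$beta - qnorm(0.975) * se), tolerance = 1e-6)
})

test_that("progression tables count events by horizon and test independence", {
  # closed-form chi-square on the worked 2x2 table
  strata <- rep(c("lo", "hi"), c(50, 50))
  times <- c(rep(5, 20), rep(30, 30), rep(5, 30), rep(30, 20))
  events <- rep(1, 100)
  pt <- progression_table(strata, times, events, horizon = 12)
  expect_equal(unname(pt$test$statistic), 4.0, tolerance = 1e-12)
  expect_equal(pt$test$p_value, 0.0455, tolerance = 1e-3)
  # identical rows: statistic 0
  pt0 <- progression_table(rep(c("a", "b"), each = 4),
                           rep(c(5, 5, 30, 30), 2), rep(1, 8), horizon = 12)
  expect_equal(unname(pt0$test$statistic), 0)
  # horizon beyond all times, no censoring: everyone progressed
  pt1 <- progression_table(rep(c("a", "b"), each = 3), rep(1:3, 2),
                           rep(1, 6), horizon = 99)
  expect_equal(unname(pt1$table["progressed", ]), c(3, 3))
  # early censored subjects are excluded by default, included on request
  strata2 <- c("a", "a", "b", "b")
  t2 <- c(5, 5, 20, 20); e2 <- c(0, 1, 1, 0)
  pt2 <- progression_table(strata2, t2, e2, horizon = 12)
  expect_equal(pt2$excluded, 1)
  expect_equal(sum(pt2$table), 3)
  pt3 <- progression_table(strata2, t2, e2, horizon = 12,
                           censored_as_nonprogressed = TRUE)
  expect_equal(sum(pt3$table), 4)
  # row/column permutation invariance
  tab_a <- progression_table(strata, times, events, 12)$test$statistic
  tab_b <- progression_table(rev(strata), rev(times), rev(events),
                             12)$test$statistic
  expect_equal(tab_a, tab_b, tolerance = 1e-12)
})

test_that("Mann-Whitney p-values match exact enumeration for small groups", {
  rt <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(rt$statistic), 0)
  expect_equal(rt$p_value, 0.1)
  # identical groups: p 1 under the exact convention
  expect_equal(rank_test(c(1, 3, 5), c(2, 4, 6))$p_value,
               mw_enumerate(c(1, 3, 5), c(2, 4, 6)))
  # full enumeration for all group sizes up to 6
  set.seed(31)
  for (na in 2:6) for (nb in 2:6) {
    x <- sample(seq_len(100), na + nb)  # distinct values, no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(rank_test(a, b)$p_value, mw_enumerate(a, b),
                 tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
  # large-sample shift alternative is reliably detected
  set.seed(32)
  hits <- vapply(1:40, function(i) {
    a <- rnorm(50); b <- rnorm(50) + 2
    rank_test(a, b)$p_value < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_error(rank_test(numeric(0), 1), "non-empty")
})

test_that("association measures recover exact coefficients", {
  x <- c(1, 2, 3, 4, 5)
  lr <- suppressWarnings(association(x, 2 * x + 1, method = "linear_regression"))
  expect_equal(lr$coefficient, 2)
  expect_equal(lr$intercept, 1)
  expect_equal(lr$r_squared, 1)
  expect_equal(association(x, 2 * x + 1, method = "pearson")$coefficient, 1)
  # hand rank computation: x = (1,2,3), y = (1,3,2)
  expect_equal(association(c(1, 2, 3), c(1, 3, 2),
                           method = "spearman")$coefficient, 0.5)
  # independence: |r| small for most seeds
  set.seed(41)
  rs <- vapply(1:40, function(i)
    abs(association(rnorm(1000), rnorm(1000))$coefficient), 0)
  expect_gte(mean(rs < 0.1), 0.95)
  expect_error(association(rep(1, 5), 1:5), "variance")
  expect_error(association(1:2, 1:2), "length")
})

test_that("differential immune-gene testing applies Welch t with Bonferroni", {
  # identical groups: t 0, p 1
  expr <- matrix(rep(c(1, 2, 1, 2), 3), 3, byrow = TRUE,
                 dimnames = list(paste0("g", 1:3), NULL))
  strata <- factor(rep(c("Q4", "Q1"), each = 2), levels = c("Q1", "IQR", "Q4"))
  res0 <- diff_immune_genes(expr, strata)
  expect_true(all(res0$p_value > 0.99))
  # Bonferroni arithmetic: m * p, capped at 1; never below raw p
  set.seed(51)
  sim <- simulate_expression(100, 10, 10, n_effect = 0, seed = 52)
  res <- diff_immune_genes(sim$expr, sim$strata)
  expect_equal(res$adjusted_p, pmin(1, 100 * res$p_value))
  expect_true(all(res$adjusted_p >= res$p_value))
  # zero-variance gene flagged with p 1
  expr_z <- rbind(gA = rep(1, 8), gB = rnorm(8))
  strata_z <- factor(rep(c("Q4", "Q1"), each = 4), levels = c("Q1", "IQR", "Q4"))
  res_z <- diff_immune_genes(expr_z, strata_z)
  expect_true(res_z$degenerate[1])
  expect_equal(res_z$p_value[1], 1)
  expect_error(diff_immune_genes(expr, factor(c("Q4", "Q1", "Q1", "Q1"),
                                              levels = c("Q1", "Q4"))),
               "at least two")
})

test_that("significance count is non-increasing in the multiplicity burden", {
  sim <- simulate_expression(200, 30, 30, n_effect = 5, effect_size = 1.2,
                             seed = 61)
  res_all <- diff_immune_genes(sim$expr, sim$strata)
  res_sub <- diff_immune_genes(sim$expr[1:50, ], sim$strata)
  n_all <- sum(res_all$significant[1:50])
  n_sub <- sum(res_sub$significant)
  expect_lte(n_all, n_sub)
})

test_that("HRD subgrouping uses the >= 42 boundary and retains strata", {
  set.seed(71)
  n <- 60
  pat <- data.frame(hrd_score = c(42, 41.9, runif(n - 2, 0, 100)),
                    stratum = factor(rep(c("Q1", "Q4", "IQR"), length.out = n),
                                     levels = c("Q1", "IQR", "Q4")),
                    time = rexp(n, 0.05), event = rbinom(n, 1, 0.8))
  hs <- hrd_subgroup(pat, "time", "event")
  n_pos_q <- sum(pat$hrd_score >= 42 & pat$stratum %in% c("Q1", "Q4"))
  n_neg_q <- sum(pat$hrd_score < 42 & pat$stratum %in% c("Q1", "Q4"))
  expect_equal(hs$positive$n, n_pos_q)   # score exactly 42 counts positive
  expect_equal(hs$negative$n, n_neg_q)
  # a subgroup without events is skipped with a reason
  pat0 <- pat; pat0$event[pat0$hrd_score >= 42] <- 0
  hs0 <- hrd_subgroup(pat0, "time", "event")
  expect_true(hs0$positive$skipped)
  expect_false(hs0$negative$skipped)
})
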