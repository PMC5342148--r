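test_that("product-limit estimate has its closed forms without censoring", {
  km <- km_estimate(1:4, rep(TRUE, 4))
  expect_equal(tidy(km)$survival, c(0.75, 0.5, 0.25, 0))

  cens <- km_estimate(c(2, 5, 9), rep(FALSE, 3))
  expect_true(all(tidy(cens)$survival == 1))
  expect_equal(tidy(cens)$n_risk, c(3L, 2L, 1L))

  # hand product-limit: event at 1 (S = 2/3), censor at 2, event at 3 (S = 0)
  mix <- tidy(km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
  expect_equal(mix$survival, c(2 / 3, 2 / 3, 0))

  expect_error(km_estimate(numeric(0), logical(0)))
  expect_error(km_estimate(c(0, 2), c(TRUE, TRUE)),
               class = "ragc_validation_error")
})

test_that("without censoring the curve equals one minus the empirical CDF", {
  withr::with_seed(31, {
    times <- sample(rexp(50, 0.1))
  })
  km <- tidy(km_estimate(times, rep(TRUE, 50)))
  expect_equal(km$survival,
               vapply(km$time, function(t) mean(times > t), numeric(1)),
               tolerance = 1e-12)
})

test_that("KM and log-rank match the survival package on random instances", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      times <- round(rexp(n, 0.1), 1) + 0.1  # induces ties
      events <- runif(n) < 0.7
      km <- tidy(km_estimate(times, events))
      sf <- summary(survival::survfit(survival::Surv(times, events) ~ 1),
                    times = km$time)
      expect_equal(km$survival, sf$surv, tolerance = 1e-9)
      expect_equal(km$n_risk, sf$n.risk, tolerance = 1e-9)

      groups <- sample(c("a", "b", "c"), n, replace = TRUE)
      if (length(unique(groups)) >= 2 && sum(events) > 0) {
        lr <- log_rank(times, events, groups)
        sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
        expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
        expect_equal(lr$df, length(unique(groups)) - 1L)
      }
    }
  })
})

test_that("log-rank has its hand-computed value on a six-subject example", {
  times <- c(1, 3, 5, 2, 4, 6)
  events <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  groups <- rep(c("a", "b"), each = 3)
  lr <- log_rank(times, events, groups)
  # hand O/E table: O_a = 2, E_a = 0.5 + 0.4 + 0.5 = 1.4, V = 0.74
  expect_equal(lr$statistic, 0.36 / 0.74, tolerance = 1e-9)
  o_a <- tidy(lr)$observed[tidy(lr)$group == "a"]
  expect_equal(o_a, 2)
  expect_equal(tidy(lr)$expected[tidy(lr)$group == "a"], 1.4, tolerance = 1e-9)
})

test_that("log-rank degenerate and structural properties hold", {
  # two identical groups: observed equals expected exactly
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  events <- rep(c(TRUE, TRUE, FALSE, TRUE), 2)
  groups <- rep(c("a", "b"), each = 4)
  lr <- log_rank(times, events, groups)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  withr::with_seed(23, {
    times <- rexp(60, 0.1); events <- runif(60) < 0.6
    groups <- sample(letters[1:4], 60, replace = TRUE)
  })
  lr4 <- log_rank(times, events, groups)
  expect_equal(lr4$df, 3L)
  # conservation: expected events sum to observed events
  expect_equal(sum(tidy(lr4)$expected), sum(tidy(lr4)$observed),
               tolerance = 1e-9)
  # invariance under a common monotone transformation of time
  lr_sqrt <- log_rank(sqrt(times), events, groups)
  expect_equal(lr_sqrt$statistic, lr4$statistic, tolerance = 1e-9)
})

test_that("pairwise log-rank restricts to the named groups and validates labels", {
  withr::with_seed(5, {
    times <- rexp(90, 0.05); events <- runif(90) < 0.7
    groups <- sample(c("pGS", "pCIN", "EBV_positive"), 90, replace = TRUE)
  })
  pw <- pairwise_log_rank(times, events, groups, c("pGS", "pCIN"))
  keep <- groups %in% c("pGS", "pCIN")
  direct <- log_rank(times[keep], events[keep], groups[keep])
  expect_equal(pw$statistic, direct$statistic)
  expect_error(pairwise_log_rank(times, events, groups, c("pGS", "pGS")))
  expect_error(pairwise_log_rank(times, events, groups, c("pGS", "D_pGS")),
               "not present")
})

test_that("pairwise log-rank holds its size under the null and its power under HR 2", {
  rejections_null <- 0L
  for (seed in 1:150) {
    withr::with_seed(1000 + seed, {
      t1 <- rexp(60, 0.02); t2 <- rexp(60, 0.02)
      c1 <- runif(60, 12, 60); c2 <- runif(60, 12, 60)
      times <- c(pmin(t1, c1), pmin(t2, c2))
      events <- c(t1 <= c1, t2 <= c2)
    })
    groups <- rep(c("g1", "g2"), each = 60)
    p <- pairwise_log_rank(times, events, groups, c("g1", "g2"))$p_value
    if (p < 0.05) rejections_null <- rejections_null + 1L
  }
  expect_lte(rejections_null / 150, 0.11)  # 5% nominal + 3 SE

  rejections_alt <- 0L
  for (seed in 1:200) {
    withr::with_seed(2000 + seed, {
      t1 <- rexp(150, 0.02); t2 <- rexp(150, 0.04)  # hazard ratio 2
      c1 <- runif(150, 12, 60); c2 <- runif(150, 12, 60)
    })
    times <- c(pmin(t1, c1), pmin(t2, c2))
    events <- c(t1 <= c1, t2 <= c2)
    groups <- rep(c("D_pGS", "I_pCIN"), each = 150)
    p <- pairwise_log_rank(times, events, groups, c("D_pGS", "I_pCIN"))$p_value
    if (p < 0.05) rejections_alt <- rejections_alt + 1L
  }
  expect_gte(rejections_alt / 200, 0.80)
})

test_that("compare_survival assembles curves, the test, and exclusions", {
  sim <- simulate_cohort(simulation_params(n_cases = 250, seed = 13))
  ann <- annotate_cohort(sim$cohort, sim$sish)
  dat <- dplyr::left_join(
    ann, sim$cohort[, c("case_id", "rfs_months", "rfs_event")], by = "case_id")
  dat$rfs_months[1:5] <- NA
  cs <- compare_survival(dat, "rfs_months", "rfs_event", "subgroup_histologic")
  expect_identical(cs$n_excluded, 5L)
  expect_true(all(c("group", "time", "survival") %in% names(tidy(cs))))
  expect_identical(names(glance(cs)), c("statistic", "df", "p_value"))
  ref <- survival::survdiff(
    survival::Surv(rfs_months, rfs_event == "event") ~ subgroup_histologic,
    data = dat[!is.na(dat$rfs_months), ])
  expect_equal(glance(cs)$statistic, ref$chisq, tolerance = 1e-9)
  expect_s3_class(ggplot2::autoplot(cs), "ggplot")
})

test_that("the Cox adapter delegates to the survival package", {
  sim <- simulate_cohort(simulation_params(n_cases = 300, seed = 29))
  ann <- annotate_cohort(sim$cohort, sim$sish)
  dat <- dplyr::left_join(
    ann, sim$cohort[, c("case_id", "age", "os_months", "os_event")],
    by = "case_id")
  fit <- fit_cox(dat, "os_months", "os_event",
                 c("age", "subgroup_histologic"))
  expect_s3_class(fit, "coxph")
  expect_true("age" %in% rownames(summary(fit)$coefficients))
})
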