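test_that("Welch t from summaries matches stats::t.test on raw data", {
  withr::with_seed(10, {
    x <- rnorm(25, 22, 2)
    y <- rnorm(25, 21, 3)
  })
  ours <- welch_t(mean(x), sd(x), 25, mean(y), sd(y), 25)
  ref <- t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  dat <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), each = 25))
  expect_equal(welch_t_data(dat, "v", "g"), ours)
})

test_that("Welch t edge behaviour: identical groups, equal variances, zero variance", {
  same <- welch_t(5, 1, 10, 5, 1, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # equal variances and equal n give the pooled df exactly
  eq <- welch_t(6, 2, 12, 5, 2, 12)
  expect_equal(eq$df, 22)
  expect_error(welch_t(1, 0, 5, 2, 0, 5), "zero")
})

# independent split-plot oracle: explicit sums-of-squares identities on cell
# means, written without aov
split_plot_ss <- function(d) {
  g <- mean(d$y)
  n_sub <- length(unique(d$subject))
  n_w <- length(unique(d$w1))
  sub_m <- tapply(d$y, d$subject, mean)
  grp_of <- tapply(as.character(d$group), d$subject, `[`, 1)
  grp_m <- tapply(d$y, d$group, mean)
  w_m <- tapply(d$y, d$w1, mean)
  cell_gw <- tapply(d$y, list(d$group, d$w1), mean)
  n_per_g <- table(grp_of)
  ss_between <- n_w * sum(n_per_g * (grp_m - g)^2)
  ss_sub <- n_w * sum((sub_m - grp_m[grp_of])^2)
  ss_w <- n_sub * sum((w_m - g)^2)
  ss_gw <- sum(outer(n_per_g, rep(1, n_w)) * (cell_gw -
    outer(grp_m - g, w_m - g, `+`) - g)^2)
  ss_tot <- sum((d$y - g)^2)
  ss_res <- ss_tot - ss_between - ss_sub - ss_w - ss_gw
  list(
    between = ss_between, subj = ss_sub, within = ss_w, inter = ss_gw,
    resid = ss_res, total = ss_tot
  )
}

test_that("split-plot ANOVA matches the sums-of-squares identities on a toy table", {
  # 4 subjects x 2 groups(between) x 2 positions(within); small integers
  d <- tibble::tibble(
    subject = rep(c("a", "b", "c", "d"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    w1 = rep(c("p1", "p2"), times = 4),
    y = c(3, 5, 4, 7, 6, 6, 8, 9)
  )
  out <- mixed_anova(d, "y", "subject", "group", "w1")
  ss <- split_plot_ss(d)
  get <- function(term) out$sumsq[out$term == term]
  expect_equal(get("group"), ss$between, tolerance = 1e-10)
  expect_equal(get("w1"), ss$within, tolerance = 1e-10)
  expect_equal(get("group:w1"), ss$inter, tolerance = 1e-10)
  res <- out$sumsq[out$term == "Residuals"]
  expect_equal(sort(res), sort(c(ss$subj, ss$resid)), tolerance = 1e-10)
  # F ratios against the correct strata
  expect_equal(
    out$statistic[out$term == "group"],
    (ss$between / 1) / (ss$subj / 2),
    tolerance = 1e-10
  )
  expect_equal(
    out$statistic[out$term == "w1"],
    (ss$within / 1) / (ss$resid / 2),
    tolerance = 1e-10
  )
})

test_that("ANOVA decomposition: SS identity, location invariance, balance check", {
  make_tbl <- function(seed, shift = 0) {
    withr::with_seed(seed, {
      tidyr::expand_grid(
        subject = sprintf("s%02d", 1:10), w1 = c("p1", "p2", "p3"),
        w2 = c("i1", "i2")
      ) |>
        dplyr::mutate(
          group = ifelse(subject <= "s05", "g1", "g2"),
          y = rnorm(dplyr::n()) + shift
        )
    })
  }
  d <- make_tbl(5)
  out <- mixed_anova(d, "y", "subject", "group", "w1", "w2")
  total <- sum((d$y - mean(d$y))^2)
  expect_equal(sum(out$sumsq), total, tolerance = 1e-8)
  shifted <- mixed_anova(
    dplyr::mutate(d, y = y + 100), "y", "subject", "group", "w1", "w2"
  )
  expect_equal(shifted$statistic, out$statistic, tolerance = 1e-8)
  expect_error(
    mixed_anova(d[-3, ], "y", "subject", "group", "w1", "w2"),
    "design error"
  )
})

test_that("pearson_r matches closed forms and symmetry", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  withr::with_seed(2, {
    a <- rnorm(50)
    b <- rnorm(50)
  })
  expect_equal(pearson_r(a, b)$estimate, pearson_r(b, a)$estimate)
  expect_equal(pearson_r(a, b)$estimate, cor(a, b))
  big <- withr::with_seed(3, list(x = rnorm(1e4), y = rnorm(1e4)))
  expect_lt(abs(pearson_r(big$x, big$y)$estimate), 0.05)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("behavioural summary computes per-target error rates and times", {
  scores <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:25), image_id = "img1"
  ) |>
    dplyr::mutate(
      group = "expert",
      T1 = subject_id != "s01", # 1 of 25 misses target 1
      T2 = TRUE,
      T3 = subject_id <= "s20",
      targets_found = T1 + T2 + T3
    )
  times <- dplyr::distinct(scores, subject_id, image_id) |>
    dplyr::mutate(time_s = 40 + seq_len(25))
  out <- behavioral_summary(scores, times)
  expect_equal(nrow(out), 3) # 1 group x 1 image x 3 targets
  expect_equal(out$error_rate[out$target == "T1"], 0.04)
  expect_equal(out$error_rate[out$target == "T2"], 0)
  expect_equal(out$error_rate[out$target == "T3"], 0.2)
  expect_equal(unique(out$mean_time_s), mean(times$time_s))
})
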