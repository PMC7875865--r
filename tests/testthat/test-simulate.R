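test_that("the default scene is the canonical 7-state arrangement", {
  sc <- make_search_scene(seed = 3)
  expect_equal(sc$model$n_states, 7)
  expect_setequal(
    sc$model$state_roles,
    c("P1", "P2", "P3", "T1", "T2", "T3", "orientation")
  )
  expect_equal(nrow(sc$aois$regions), 6)
  # determinism
  sc2 <- make_search_scene(seed = 3)
  expect_identical(sc$aois$regions$polygon, sc2$aois$regions$polygon)
  expect_identical(sc$model, sc2$model)
  # AOI state means sit at the AOI centres
  for (i in 1:6) {
    expect_equal(sc$model$means[i, ], unname(sc$aois$regions$center[[i]]))
  }
  # distractors extend the state space
  sc3 <- make_search_scene(scene_config(n_distractors = 2), seed = 3)
  expect_equal(sc3$model$n_states, 9)
})

test_that("group presets tighten/broaden emissions and keep models valid", {
  sc <- fixture_scene()
  em <- expert_hmm(sc)
  nm <- novice_hmm(sc)
  aoi_idx <- which(sc$model$state_roles %in% c("P1", "P2", "P3", "T1", "T2", "T3"))
  for (j in aoi_idx) {
    expect_lt(em$covs[1, 1, j], nm$covs[1, 1, j])
    expect_lt(em$covs[2, 2, j], nm$covs[2, 2, j])
  }
  expect_gte(em$n_states, nm$n_states)
  expect_equal(rowSums(em$A), rep(1, em$n_states), tolerance = 1e-9)
  expect_equal(rowSums(nm$A), rep(1, nm$n_states), tolerance = 1e-9)
  expect_equal(sum(em$pi), 1, tolerance = 1e-9)
  expect_equal(sum(nm$pi), 1, tolerance = 1e-9)
})

test_that("scanpath simulation is seeded, absorbing-consistent and clipped", {
  m <- gaze_hmm(
    pi = c(1, 0), A = rbind(c(1, 0), c(0.5, 0.5)),
    means = rbind(c(300, 300), c(1500, 900)), variances = matrix(400, 2, 2)
  )
  a <- simulate_scanpath(m, 200, seed = 5, return_states = TRUE)
  b <- simulate_scanpath(m, 200, seed = 5, return_states = TRUE)
  expect_identical(a, b)
  # pi = delta_1 and absorbing state 1: every draw comes from state 1
  expect_true(all(a$true_state == 1))
  expect_true(all(abs(a$x_px - 300) < 5 * 20))
  expect_true(all(a$x_px >= 0 & a$x_px <= 1920 & a$y_px >= 0 & a$y_px <= 1200))
  expect_true(all(a$duration_ms > 0))
  expect_equal(a$fixation_index, 1:200)
})

test_that("long-run transition frequencies approach the transition matrix", {
  A <- rbind(c(0.85, 0.15), c(0.3, 0.7))
  m <- gaze_hmm(
    pi = c(0.5, 0.5), A = A,
    means = rbind(c(300, 300), c(1500, 900)), variances = matrix(400, 2, 2)
  )
  p <- simulate_scanpath(m, 10000, seed = 11, return_states = TRUE)
  emp <- prop.table(table(head(p$true_state, -1), p$true_state[-1]), margin = 1)
  expect_true(all(abs(emp - A) < 0.02))
})

test_that("cohort simulation is seeded, valid and touch-consistent", {
  sc <- fixture_scene()
  cfg <- cohort_config(
    n_per_group = 3, len_meanlog = log(60),
    len_range = c(30, 120)
  )
  ch1 <- simulate_cohort(sc, config = cfg, seed = 9)
  ch2 <- simulate_cohort(sc, config = cfg, seed = 9)
  expect_identical(ch1$fixations, ch2$fixations)
  expect_identical(ch1$touches, ch2$touches)
  expect_equal(dplyr::n_distinct(ch1$fixations$subject_id), 6)
  expect_setequal(unique(ch1$fixations$group), c("expert", "novice"))
  rep <- validate_gaze_data(ch1$fixations, sc$aois)
  expect_equal(nrow(rep$issues), 0)
  # perfect accuracy, zero scatter: every target identified
  perfect <- simulate_cohort(sc,
    config = cohort_config(
      n_per_group = 2, len_meanlog = log(40), len_range = c(30, 60),
      hit_prob = c(expert = 1, novice = 1), touch_sd = 0
    ), seed = 4
  )
  scores <- score_touches(perfect$touches, sc$aois)
  expect_true(all(scores$targets_found == 3))
  expect_true("group" %in% names(perfect$task_times))
})

test_that("a configured 1.2-target accuracy gap yields the implied Welch t on average", {
  p_e <- 0.9
  p_n <- 0.5 # 3 targets/image: mean gap = 3 * 0.4 = 1.2 targets
  n_sub <- 12
  cfg <- cohort_config(
    n_per_group = n_sub, len_meanlog = log(25), len_range = c(20, 30),
    hit_prob = c(expert = p_e, novice = p_n), touch_sd = 0
  )
  sc <- fixture_scene()
  tstats <- vapply(1:200, function(rep) {
    ch <- simulate_cohort(sc, config = cfg, seed = 1000 + rep)
    found <- score_touches(ch$touches, sc$aois) |>
      dplyr::mutate(group = substr(subject_id, 1, 1))
    welch_t_data(found, "targets_found", "group")$statistic
  }, numeric(1))
  # per-subject targets are Binomial(3, p_g); the implied t follows from the
  # binomial moments, with the small-sample mean correction of Student's t
  k <- 3
  v_e <- k * p_e * (1 - p_e)
  v_n <- k * p_n * (1 - p_n)
  t_implied <- k * (p_e - p_n) / sqrt((v_e + v_n) / n_sub)
  df_w <- ((v_e + v_n) / n_sub)^2 /
    ((v_e / n_sub)^2 / (n_sub - 1) + (v_n / n_sub)^2 / (n_sub - 1))
  correction <- sqrt(df_w / 2) * gamma((df_w - 1) / 2) / gamma(df_w / 2)
  expect_lt(abs(mean(tstats) - t_implied * correction), 0.3)
})
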