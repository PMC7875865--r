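# deterministic assignment fixture: explicit states and coordinates
manual_assignment <- function(states, xs, ys, subject = "s1", group = "g",
                              image = "img1") {
  tibble::tibble(
    subject_id = subject, group = group, image_id = image,
    fixation_index = seq_along(states), duration_ms = 280,
    x_px = xs, y_px = ys, state = states
  )
}

test_that("classification is exhaustive, disjunctive and separation-consistent", {
  m <- gaze_hmm(
    pi = c(0.5, 0.5), A = matrix(c(0.9, 0.1, 0.1, 0.9), 2),
    means = rbind(c(200, 200), c(900, 200)), variances = matrix(100, 2, 2)
  )
  fx <- dplyr::bind_rows(
    simulate_scanpath(m, 60, seed = 1, subject_id = "a"),
    simulate_scanpath(m, 60, seed = 2, subject_id = "b")
  )
  for (mode in c("posterior", "viterbi")) {
    asg <- classify_fixations(fx, m, mode = mode)
    expect_equal(nrow(asg), nrow(fx))
    expect_true(all(asg$state %in% 1:2))
    near1 <- asg$x_px < 500
    expect_true(mean(asg$state[near1] == 1) > 0.99)
  }
  m1 <- gaze_hmm(1, matrix(1), cbind(500, 500), cbind(100, 100))
  expect_true(all(classify_fixations(fx, m1)$state == 1))
})

test_that("overlap matrix equals direct per-fixation counting", {
  scene <- fixture_scene()
  a <- scene$aois
  cents <- do.call(rbind, a$regions$center)
  # 12 fixations across 3 states and labels T1, T2, WS
  asg <- manual_assignment(
    states = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 3, 3),
    xs = c(rep(cents[4, 1], 4), rep(cents[5, 1], 3), rep(30, 5)),
    ys = c(rep(cents[4, 2], 4), rep(cents[5, 2], 3), rep(30, 5))
  )
  om <- overlap_matrix(asg, a, n_states = 3)
  expect_equal(sum(om), 12)
  expect_equal(om[1, "T1"], 4L)
  expect_equal(om[2, "T2"], 3L)
  expect_equal(om[3, "WS"], 5L)
  expect_equal(sum(om[, c("P1", "P2", "P3", "T3")]), 0L)
  expect_equal(unname(rowSums(om)), c(4L, 3L, 5L))
  # single-state, single-AOI case
  asg2 <- manual_assignment(rep(2, 10), rep(cents[1, 1], 10), rep(cents[1, 2], 10))
  om2 <- overlap_matrix(asg2, a, n_states = 2)
  expect_equal(om2[2, "P1"], 10L)
  expect_equal(sum(om2), 10)
})

test_that("state linkage is argmax with ties low, many-to-one allowed, zero flagged", {
  labs <- c("P1", "P2", "P3", "T1", "T2", "T3", "WS")
  m <- matrix(0L, 3, 7, dimnames = list(state = 1:3, label = labs))
  m[, "T3"] <- c(2L, 9L, 0L)
  m[, "T1"] <- c(5L, 5L, 0L) # tie between states 1 and 2
  m[1, c("P1", "P2", "P3")] <- c(8L, 7L, 3L) # one state dominates all primes
  m[, "T2"] <- c(0L, 0L, 4L)
  class(m) <- c("overlap_matrix", "matrix")
  lk <- link_states(m)
  expect_equal(lk$state[lk$aoi_label == "T3"], 2L)
  expect_equal(lk$state[lk$aoi_label == "T1"], 1L) # tie -> lower index
  expect_equal(lk$state[lk$aoi_label %in% c("P1", "P2", "P3")], rep(1L, 3))
  expect_equal(lk$state[lk$aoi_label == "T2"], 3L)
  # an AOI with no fixations anywhere: undefined, flagged
  m2 <- m
  m2[, "T2"] <- 0L
  lk2 <- link_states(m2)
  expect_true(is.na(lk2$state[lk2$aoi_label == "T2"]))
  expect_true(lk2$flagged[lk2$aoi_label == "T2"])
})

test_that("precision equals direct counting, bounded, consistent across modes", {
  scene <- fixture_scene()
  a <- scene$aois
  cents <- do.call(rbind, a$regions$center)
  # state 1 linked to T1: 7 of its 10 fixations inside T1; subject split 6/4
  asg <- manual_assignment(
    states = rep(1, 10),
    xs = c(rep(cents[4, 1], 7), 30, 40, 50),
    ys = c(rep(cents[4, 2], 7), 30, 40, 50),
    subject = c(rep("s1", 6), rep("s2", 4))
  )
  lk <- tibble::tibble(aoi_label = "T1", state = 1L, n_fixations = 7L, flagged = FALSE)
  ps <- precision_scores(asg, lk, a)
  expect_equal(ps$precision_percent, 70)
  expect_equal(ps$n_state_fixations, 10)
  expect_equal(ps$n_in_aoi, 7)
  # per-subject: s1 has 6 state-1 fixations, all inside; s2 has 4, 1 inside
  pps <- precision_scores(asg, lk, a, per_subject = TRUE)
  expect_equal(pps$precision_percent[pps$subject_id == "s1"], 100)
  expect_equal(pps$precision_percent[pps$subject_id == "s2"], 25)
  # group percentage equals pooled subject numerators/denominators
  expect_equal(
    100 * sum(pps$n_in_aoi) / sum(pps$n_state_fixations),
    ps$precision_percent
  )
  # subject absent from the linked state: 0 and flagged
  asg2 <- dplyr::bind_rows(asg, manual_assignment(2, 100, 100, subject = "s3"))
  pps2 <- precision_scores(asg2, lk, a, per_subject = TRUE)
  expect_equal(pps2$precision_percent[pps2$subject_id == "s3"], 0)
  expect_true(pps2$flagged[pps2$subject_id == "s3"])
})

test_that("precision beats a shuffled-assignment null on AOI-centred data", {
  scene <- fixture_scene()
  a <- scene$aois
  truth <- scene$model
  fx <- dplyr::bind_rows(lapply(1:6, function(i) {
    simulate_scanpath(truth, 150,
      seed = derive_seed(77, i),
      subject_id = sprintf("s%d", i), image_id = a$image_id
    )
  }))
  fit <- fit_hmm(fx, truth$n_states, seed = 2)
  asg <- classify_fixations(fx, fit)
  om <- overlap_matrix(asg, a, n_states = fit$model$n_states)
  lk <- link_states(om)
  real <- precision_scores(asg, lk, a)
  for (seed in 1:5) {
    null_asg <- asg
    null_asg$state <- withr::with_seed(seed, sample(asg$state))
    null_om <- overlap_matrix(null_asg, a, n_states = fit$model$n_states)
    null <- precision_scores(null_asg, link_states(null_om), a)
    expect_gt(mean(real$precision_percent), mean(null$precision_percent))
  }
})

test_that("touch scoring applies the inclusive 50-pixel rule per target", {
  scene <- fixture_scene()
  a <- scene$aois
  cents <- do.call(rbind, a$regions$center)[4:6, ]
  touches <- tibble::tibble(
    subject_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    image_id = a$image_id,
    x_px = c(cents[1, 1], cents[2, 1] + 50, cents[3, 1], cents[1, 1] + 50.1, 30, cents[2, 1]),
    y_px = c(cents[1, 2], cents[2, 2], cents[3, 2], cents[1, 2], 30, cents[2, 2])
  )
  sc <- score_touches(touches, a, radius = 50)
  s1 <- sc[sc$subject_id == "s1", ]
  expect_equal(s1$targets_found, 3) # exact centre, distance 50.0, centre
  s2 <- sc[sc$subject_id == "s2", ]
  expect_equal(s2$targets_found, 0) # 50.1 px misses; far touch misses
  s3 <- sc[sc$subject_id == "s3", ]
  expect_true(s3$T2 && !s3$T1 && !s3$T3)
})
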