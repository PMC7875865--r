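test_that("model constructor enforces stochasticity and positive definiteness", {
  expect_error(gaze_hmm(c(0.6, 0.5), diag(2), matrix(0, 2, 2), matrix(1, 2, 2)), "sum to 1")
  expect_error(
    gaze_hmm(c(0.5, 0.5), matrix(c(0.9, 0.2, 0.2, 0.9), 2), matrix(0, 2, 2), matrix(1, 2, 2)),
    "sum to 1"
  )
  expect_error(
    gaze_hmm(1, matrix(1), matrix(0, 1, 2), matrix(c(1, -1), 1, 2)),
    "positive definite"
  )
})

test_that("single-state log-likelihood equals the closed-form Gaussian sum", {
  obs <- withr::with_seed(2, cbind(rnorm(40, 500, 30), rnorm(40, 400, 20)))
  m <- gaze_hmm(1, matrix(1), cbind(510, 390), cbind(900, 500))
  expected <- sum(dnorm(obs[, 1], 510, 30, log = TRUE) +
    dnorm(obs[, 2], 390, sqrt(500), log = TRUE))
  expect_equal(hmm_loglik(obs_tibble(obs), m), expected, tolerance = 1e-12)
})

test_that("forward likelihood matches exhaustive path enumeration", {
  inst <- random_instance(42, T_max = 4, N_max = 2)
  got <- hmm_loglik(obs_tibble(inst$obs), as_ghmm(inst))
  expect_equal(got, brute_loglik(inst$obs, inst$pi, inst$A, inst$means, inst$vars),
    tolerance = 1e-9
  )
})

test_that("likelihood is invariant to state relabelling and sequence order", {
  inst <- random_instance(7, T_max = 6, N_max = 3)
  m <- as_ghmm(inst)
  fx <- obs_tibble(inst$obs)
  ll <- hmm_loglik(fx, m)
  if (inst$n > 1) {
    p <- c(inst$n, seq_len(inst$n - 1)) # cyclic permutation
    mp <- gaze_hmm(
      pi = inst$pi[p], A = inst$A[p, p, drop = FALSE],
      means = inst$means[p, , drop = FALSE], variances = inst$vars[p, , drop = FALSE]
    )
    expect_equal(hmm_loglik(fx, mp), ll, tolerance = 1e-9)
  }
  # two sequences, either order
  inst2 <- random_instance(43, T_max = 5, N_max = 3)
  fx2 <- dplyr::bind_rows(
    obs_tibble(inst$obs, subject = "a"),
    obs_tibble(inst$obs[1:3, , drop = FALSE], subject = "b")
  )
  fx2r <- dplyr::bind_rows(
    obs_tibble(inst$obs[1:3, , drop = FALSE], subject = "b"),
    obs_tibble(inst$obs, subject = "a")
  )
  expect_equal(hmm_loglik(fx2, m), hmm_loglik(fx2r, m))
})

test_that("posteriors match enumeration, rows sum to one, N=1 is degenerate", {
  inst <- random_instance(11, T_max = 3, N_max = 2)
  post <- posterior_state_probs(obs_tibble(inst$obs), as_ghmm(inst))
  pm <- as.matrix(post[, grep("^p_state_", names(post))])
  expect_equal(unname(pm),
    brute_posterior(inst$obs, inst$pi, inst$A, inst$means, inst$vars),
    tolerance = 1e-9
  )
  expect_equal(rowSums(pm), rep(1, nrow(pm)), tolerance = 1e-9)

  m1 <- gaze_hmm(1, matrix(1), cbind(0, 0), cbind(100, 100))
  p1 <- posterior_state_probs(obs_tibble(cbind(1:3, 1:3)), m1)
  expect_equal(p1$p_state_1, rep(1, 3))
})

test_that("far-separated states give near-certain posteriors", {
  m <- gaze_hmm(
    pi = c(0.5, 0.5), A = matrix(c(0.9, 0.1, 0.1, 0.9), 2),
    means = rbind(c(200, 200), c(700, 200)), variances = matrix(100, 2, 2)
  )
  obs <- withr::with_seed(5, cbind(rnorm(30, 200, 10), rnorm(30, 200, 10)))
  post <- posterior_state_probs(obs_tibble(obs), m)
  expect_true(all(post$p_state_1 > 0.999))
})

test_that("Viterbi equals brute-force argmax and respects structure", {
  for (seed in c(3, 14, 15, 92)) {
    inst <- random_instance(seed, T_max = 5, N_max = 3)
    vp <- viterbi_path(obs_tibble(inst$obs), as_ghmm(inst))$state
    expect_equal(vp, unname(brute_viterbi(inst$obs, inst$pi, inst$A, inst$means, inst$vars)))
  }
  # N=1: constant path
  m1 <- gaze_hmm(1, matrix(1), cbind(0, 0), cbind(100, 100))
  expect_equal(viterbi_path(obs_tibble(cbind(1:4, 1:4)), m1)$state, rep(1L, 4))
  # deterministic cyclic transition matrix with a point-mass start forces the
  # path irrespective of the observations
  mcyc <- gaze_hmm(
    pi = c(1, 0, 0),
    A = rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
    means = rbind(c(0, 0), c(500, 0), c(0, 500)),
    variances = matrix(200, 3, 2)
  )
  obs <- withr::with_seed(1, cbind(runif(6, 0, 500), runif(6, 0, 500)))
  expect_equal(viterbi_path(obs_tibble(obs), mcyc)$state, c(1L, 2L, 3L, 1L, 2L, 3L))
})

test_that("path log-probability never exceeds the sequence log-likelihood", {
  inst <- random_instance(21, T_max = 6, N_max = 3)
  fx <- obs_tibble(inst$obs)
  m <- as_ghmm(inst)
  vp <- viterbi_path(fx, m)$state
  lp <- path_logprob(vp, inst$obs, inst$pi, inst$A, inst$means, inst$vars)
  expect_lte(lp, hmm_loglik(fx, m) + 1e-12)
})

test_that("parameter count and BIC follow their closed forms", {
  expect_equal(n_free_parameters(1, "diagonal"), 4L)
  expect_equal(n_free_parameters(2, "diagonal"), 11L)
  expect_equal(n_free_parameters(7, "full"), 83L)
  ns <- 1:14
  expect_equal(n_free_parameters(ns, "diagonal"), as.integer(ns^2 + 4 * ns - 1))
  fake <- structure(
    list(
      model = gaze_hmm(c(.5, .5), matrix(.5, 2, 2), matrix(0, 2, 2), matrix(1, 2, 2)),
      log_likelihood = -500, n_observations = 100
    ),
    class = "gaze_hmm_fit"
  )
  expect_equal(hmm_bic(fake), 1000 + 11 * log(100), tolerance = 1e-12)
  fake$n_observations <- 1000
  expect_gt(hmm_bic(fake), 1000 + 11 * log(100)) # BIC increases with n
})

test_that("initialization is deterministic, stochastic and cluster-aware", {
  truth <- separated_hmm(3, sd = 20, seed = 2)
  fx <- simulate_pool(truth, 6, 60, seed = 5)
  a <- init_hmm(fx, 4, seed = 9, strategy = "random")
  b <- init_hmm(fx, 4, seed = 9, strategy = "random")
  expect_identical(a, b)
  expect_equal(rowSums(a$A), rep(1, 4), tolerance = 1e-9)
  expect_equal(sum(a$pi), 1, tolerance = 1e-9)
  km <- init_hmm(fx, 3, seed = 1, strategy = "kmeans")
  d <- as.matrix(dist(rbind(km$means, truth$means)))[1:3, 4:6]
  expect_true(all(apply(d, 2, min) < 3 * 20))
  expect_error(init_hmm(fx[1:2, ], 3, seed = 1), "cannot initialize")
})

test_that("model JSON round trip is bit-exact", {
  truth <- separated_hmm(5, seed = 3)
  fx <- simulate_pool(truth, 4, 50, seed = 8)
  fit <- fit_hmm(fx, 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm(fit$model, path)
  back <- read_hmm(path)
  expect_identical(back$pi, fit$model$pi)
  expect_identical(back$A, fit$model$A)
  expect_identical(back$means, fit$model$means)
  expect_identical(back$covs, fit$model$covs)
})
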