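# Independent brute-force oracles: likelihood, posteriors and decoding by
# exhaustive enumeration over all N^T state paths. Deliberately naive and
# written without reference to the package's forward-backward code.

diag_dens <- function(x, y, mean, var) {
  dnorm(x, mean[1], sqrt(var[1])) * dnorm(y, mean[2], sqrt(var[2]))
}

log_diag_dens <- function(x, y, mean, var) {
  dnorm(x, mean[1], sqrt(var[1]), log = TRUE) +
    dnorm(y, mean[2], sqrt(var[2]), log = TRUE)
}

all_paths <- function(n_states, T) {
  as.matrix(expand.grid(rep(list(seq_len(n_states)), T)))[, T:1, drop = FALSE]
}

# log path probability: raw products underflow at pixel scale, so the
# oracle enumerates fully in log space and uses log-sum-exp
path_logprob <- function(path, obs, pi, A, means, vars) {
  lp <- log(pi[path[1]]) +
    log_diag_dens(obs[1, 1], obs[1, 2], means[path[1], ], vars[path[1], ])
  for (t in seq_along(path)[-1]) {
    lp <- lp + log(A[path[t - 1], path[t]]) +
      log_diag_dens(obs[t, 1], obs[t, 2], means[path[t], ], vars[path[t], ])
  }
  lp
}

brute_loglik <- function(obs, pi, A, means, vars) {
  paths <- all_paths(length(pi), nrow(obs))
  lps <- apply(paths, 1, path_logprob, obs, pi, A, means, vars)
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

brute_posterior <- function(obs, pi, A, means, vars) {
  paths <- all_paths(length(pi), nrow(obs))
  lps <- apply(paths, 1, path_logprob, obs, pi, A, means, vars)
  probs <- exp(lps - max(lps))
  T <- nrow(obs)
  n <- length(pi)
  gam <- matrix(0, T, n)
  for (t in seq_len(T)) {
    for (j in seq_len(n)) gam[t, j] <- sum(probs[paths[, t] == j])
  }
  gam / rowSums(gam)
}

brute_viterbi <- function(obs, pi, A, means, vars) {
  paths <- all_paths(length(pi), nrow(obs))
  lps <- apply(paths, 1, path_logprob, obs, pi, A, means, vars)
  paths[which.max(lps), ]
}

# random valid diagonal-covariance model + observations for property tests
random_instance <- function(seed, T_max = 6, N_max = 3) {
  withr::with_seed(seed, {
    n <- sample.int(N_max, 1)
    T <- sample.int(T_max, 1)
    pi <- runif(n) + 0.05
    pi <- pi / sum(pi)
    A <- matrix(runif(n * n) + 0.05, n, n)
    A <- A / rowSums(A)
    means <- cbind(runif(n, 0, 1000), runif(n, 0, 800))
    vars <- cbind(runif(n, 100, 2000), runif(n, 100, 2000))
    obs <- cbind(runif(T, 0, 1000), runif(T, 0, 800))
    list(n = n, T = T, pi = pi, A = A, means = means, vars = vars, obs = obs)
  })
}

as_ghmm <- function(inst) {
  gaze_hmm(pi = inst$pi, A = inst$A, means = inst$means, variances = inst$vars)
}

# wrap a bare coordinate matrix as a one-subject fixation tibble
obs_tibble <- function(obs, subject = "s1", image = "img1", group = "g") {
  tibble::tibble(
    subject_id = subject, group = group, image_id = image,
    fixation_index = seq_len(nrow(obs)),
    onset_ms = (seq_len(nrow(obs)) - 1) * 300,
    duration_ms = 280, x_px = obs[, 1], y_px = obs[, 2]
  )
}

# well-separated ground truth: K states on a jittered grid, mutual mean
# separation at least 8 SD, persistent transitions
separated_hmm <- function(n_states, sd = 25, self = 0.9, seed = 1) {
  grid <- as.matrix(expand.grid(
    x = seq(240, 1680, length.out = 4),
    y = seq(200, 1000, length.out = 3)
  ))
  stopifnot(n_states <= nrow(grid), min(dist(grid)) >= 8 * sd)
  withr::with_seed(seed, {
    means <- grid[sample.int(nrow(grid), n_states), , drop = FALSE]
  })
  A <- matrix((1 - self) / max(n_states - 1, 1), n_states, n_states)
  diag(A) <- if (n_states == 1) 1 else self
  gaze_hmm(
    pi = rep(1 / n_states, n_states), A = A, means = means,
    variances = matrix(sd^2, n_states, 2)
  )
}

simulate_pool <- function(model, n_seq, len, seed) {
  dplyr::bind_rows(lapply(seq_len(n_seq), function(i) {
    simulate_scanpath(model, len,
      seed = derive_seed(seed, i),
      subject_id = sprintf("s%02d", i), image_id = "img1", group = "sim"
    )
  }))
}

# greedy-free optimal state matching: permutation of fitted states that
# minimises total mean distance to the true states
best_permutation <- function(true_means, fit_means) {
  n <- nrow(true_means)
  perms <- all_paths(n, n)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), , drop = FALSE]
  cost <- apply(perms, 1, function(p) {
    sum(sqrt(rowSums((true_means - fit_means[p, , drop = FALSE])^2)))
  })
  perms[which.min(cost), ]
}

pylist <- function(x) sprintf("[%s]", paste(format(x, digits = 17), collapse = ","))

# small square-AOI scene fixture with deterministic target placement
fixture_scene <- function(image_id = "img1") {
  make_search_scene(
    scene_config(target_positions = rbind(c(400, 300), c(900, 600), c(500, 950))),
    seed = 1, image_id = image_id
  )
}
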