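#' Construct a Gaussian-emission hidden Markov model
#'
#' The model `lambda = (A, B, pi)` of a scanpath: `pi` is the initial state
#' distribution, `A` the row-stochastic transition matrix, and the emission
#' distribution `B` of each hidden state is a 2D Gaussian over pixel
#' coordinates, parameterised by a mean (the state's attraction centre) and
#' either per-axis variances (diagonal covariance, the default) or a full
#' 2x2 covariance.
#'
#' @param pi Length-N initial state probability vector.
#' @param A N x N row-stochastic transition matrix.
#' @param means N x 2 matrix of emission means (x, y in pixels).
#' @param variances N x 2 matrix of per-axis emission variances (pixels^2),
#'   or a 2 x 2 x N array of full covariance matrices.
#' @param covariance_kind `"diagonal"` or `"full"`.
#' @param state_roles Optional character vector of length N naming what each
#'   state emulates in a synthetic scene (e.g. `"P1"`, `"orientation"`);
#'   purely descriptive.
#' @return An object of class `gaze_hmm`.
#' @examples
#' m <- gaze_hmm(
#'   pi = c(0.5, 0.5), A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
#'   means = rbind(c(100, 100), c(900, 600)), variances = rbind(c(400, 400), c(900, 900))
#' )
#' tidy(m)
#' @export
gaze_hmm <- function(pi, A, means, variances,
                     covariance_kind = c("diagonal", "full"),
                     state_roles = NULL) {
  covariance_kind <- match.arg(covariance_kind)
  pi <- as.numeric(pi)
  n <- length(pi)
  A <- matrix(as.numeric(A), n, n)
  means <- matrix(as.numeric(means), n, 2)
  covs <- array(0, dim = c(2, 2, n))
  if (length(dim(variances)) == 3) {
    covs <- variances
  } else {
    v <- matrix(as.numeric(variances), n, 2)
    for (j in seq_len(n)) covs[, , j] <- diag(v[j, ], 2)
  }
  m <- structure(
    list(
      n_states = n, pi = pi, A = A, means = means, covs = covs,
      covariance_kind = covariance_kind, state_roles = state_roles
    ),
    class = "gaze_hmm"
  )
  validate_gaze_hmm(m)
  m
}

validate_gaze_hmm <- function(m, tol = 1e-9) {
  n <- m$n_states
  if (n < 1) abort("a gaze_hmm needs at least one state")
  if (abs(sum(m$pi) - 1) > tol) abort("initial distribution pi must sum to 1")
  if (any(m$pi < -tol)) abort("pi must be non-negative")
  rs <- rowSums(m$A)
  if (any(abs(rs - 1) > tol)) abort("every row of the transition matrix A must sum to 1")
  if (any(m$A < -tol)) abort("A must be non-negative")
  if (any(!is.finite(m$means))) abort("emission means must be finite")
  for (j in seq_len(n)) {
    S <- m$covs[, , j]
    if (S[1, 1] <= 0 || S[2, 2] <= 0 || (S[1, 1] * S[2, 2] - S[1, 2]^2) <= 0) {
      abort(paste0("emission covariance of state ", j, " is not positive definite"))
    }
  }
  if (!is.null(m$state_roles) && length(m$state_roles) != n) {
    abort("state_roles must have one entry per state")
  }
  invisible(m)
}

#' @export
print.gaze_hmm <- function(x, ...) {
  cat("<gaze_hmm> ", x$n_states, " state(s), ", x$covariance_kind,
    " covariance\n",
    sep = ""
  )
  print(tidy(x), ...)
  invisible(x)
}

#' Per-state parameter table of a fitted or constructed HMM
#'
#' @param x A `gaze_hmm`.
#' @param ... Unused.
#' @return A tibble with one row per hidden state: initial probability,
#'   self-transition, emission mean and (co)variances, and the descriptive
#'   role when present.
#' @export
tidy.gaze_hmm <- function(x, ...) {
  n <- x$n_states
  out <- tibble::tibble(
    state = seq_len(n),
    pi = x$pi,
    self_transition = diag(x$A),
    mean_x = x$means[, 1],
    mean_y = x$means[, 2],
    var_x = vapply(seq_len(n), function(j) x$covs[1, 1, j], numeric(1)),
    var_y = vapply(seq_len(n), function(j) x$covs[2, 2, j], numeric(1)),
    cov_xy = vapply(seq_len(n), function(j) x$covs[1, 2, j], numeric(1))
  )
  if (!is.null(x$state_roles)) out$role <- x$state_roles
  out
}

# Split a fixation table into one T_i x 2 coordinate matrix per
# (subject, image) scanpath, rows ordered by fixation_index. Order of input
# rows is irrelevant; the split is sorted so results are reproducible.
fix_split <- function(fixations) {
  req <- c("subject_id", "image_id", "fixation_index", "x_px", "y_px")
  miss <- setdiff(req, names(fixations))
  if (length(miss) > 0) {
    abort(paste0("fixation table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(fixations) == 0) abort("fixation table is empty")
  fx <- dplyr::arrange(fixations, .data$subject_id, .data$image_id, .data$fixation_index)
  key <- paste(fx$subject_id, fx$image_id, sep = "\r")
  idx <- split(seq_len(nrow(fx)), factor(key, levels = unique(key)))
  lapply(idx, function(i) cbind(fx$x_px[i], fx$y_px[i]))
}

#' Pooled log-likelihood of fixation sequences under an HMM
#'
#' Runs the scaled forward algorithm on every (subject, image) scanpath in
#' the table and returns the sum of the per-sequence log-likelihoods. Each
#' sequence starts from the model's initial distribution `pi`.
#'
#' @param fixations Fixation tibble with at least `subject_id`, `image_id`,
#'   `fixation_index`, `x_px`, `y_px`.
#' @param model A `gaze_hmm`.
#' @return A single finite number.
#' @export
hmm_loglik <- function(fixations, model) {
  validate_gaze_hmm(model)
  obs <- fix_split(fixations)
  ghmm_loglik_cpp(obs, model$pi, model$A, model$means, model$covs)
}

#' Smoothed per-fixation state probabilities
#'
#' Forward-backward posterior probability of each hidden state for every
#' fixation, given its full scanpath. Rows sum to one.
#'
#' @inheritParams hmm_loglik
#' @return The fixation tibble's identifying columns plus one
#'   `p_state_<j>` column per hidden state.
#' @export
posterior_state_probs <- function(fixations, model) {
  validate_gaze_hmm(model)
  fx <- dplyr::arrange(
    fixations, .data$subject_id, .data$image_id,
    .data$fixation_index
  )
  obs <- fix_split(fx)
  gam <- do.call(rbind, lapply(obs, function(o) {
    ghmm_posterior_cpp(o, model$pi, model$A, model$means, model$covs)
  }))
  colnames(gam) <- paste0("p_state_", seq_len(model$n_states))
  dplyr::bind_cols(
    dplyr::select(fx, dplyr::any_of(c(
      "subject_id", "group", "image_id",
      "fixation_index"
    ))),
    tibble::as_tibble(gam)
  )
}

#' Most probable hidden-state path (Viterbi decoding)
#'
#' @inheritParams hmm_loglik
#' @return The fixation tibble's identifying columns plus a 1-based `state`
#'   column holding the jointly most probable path per scanpath. Ties are
#'   broken toward the lower state index.
#' @export
viterbi_path <- function(fixations, model) {
  validate_gaze_hmm(model)
  fx <- dplyr::arrange(
    fixations, .data$subject_id, .data$image_id,
    .data$fixation_index
  )
  obs <- fix_split(fx)
  st <- unlist(lapply(obs, function(o) {
    ghmm_viterbi_cpp(o, model$pi, model$A, model$means, model$covs) + 1L
  }), use.names = FALSE)
  out <- dplyr::select(fx, dplyr::any_of(c(
    "subject_id", "group", "image_id",
    "fixation_index"
  )))
  out$state <- st
  out
}

#' Seeded starting values for Baum-Welch
#'
#' Builds a valid starting model. With `strategy = "kmeans"` the emission
#' means are the k-means centres of the pooled coordinates (stable default);
#' with `"random"` they are fixations sampled at random, which is what the
#' restart machinery uses to escape local optima. Either way the transition
#' matrix starts with self-transition mass `delta` (fixation sequences are
#' strongly persistent) and uniform off-diagonal mass, and `pi` is uniform.
#'
#' @inheritParams hmm_loglik
#' @param n_states Number of hidden states, at least 1.
#' @param seed Integer seed; the result is a pure function of
#'   (data, n_states, seed, strategy).
#' @param strategy `"kmeans"` or `"random"`.
#' @param delta Initial self-transition probability.
#' @param covariance_kind Passed through to the model.
#' @return A `gaze_hmm`.
#' @export
init_hmm <- function(fixations, n_states, seed = 1L,
                     strategy = c("kmeans", "random"), delta = 0.8,
                     covariance_kind = c("diagonal", "full")) {
  strategy <- match.arg(strategy)
  covariance_kind <- match.arg(covariance_kind)
  obs <- fix_split(fixations)
  xy <- do.call(rbind, obs)
  n_obs <- nrow(xy)
  if (n_states > n_obs) {
    abort(paste0(
      "cannot initialize ", n_states, " states from ", n_obs,
      " fixations"
    ))
  }
  start <- withr::with_seed(seed, {
    if (strategy == "kmeans" && n_states > 1) {
      km <- suppressWarnings(
        kmeans(xy, centers = n_states, nstart = 10, iter.max = 100)
      )
      ord <- order(km$centers[, 1], km$centers[, 2])
      # within-cluster per-axis variances: starting at data scale instead
      # lets one broad state swallow several clusters and strands EM in a
      # poor optimum even when the centres start exactly right
      v <- t(vapply(ord, function(j) {
        pts <- xy[km$cluster == j, , drop = FALSE]
        if (nrow(pts) < 2) c(1, 1) else pmax(apply(pts, 2, stats::var), 1)
      }, numeric(2)))
      list(centers = km$centers[ord, , drop = FALSE], variances = v)
    } else if (n_states == 1) {
      list(centers = matrix(colMeans(xy), 1, 2), variances = NULL)
    } else {
      list(centers = xy[sample.int(n_obs, n_states), , drop = FALSE], variances = NULL)
    }
  })
  centers <- start$centers
  variances <- start$variances
  if (is.null(variances)) {
    v0 <- pmax(apply(xy, 2, stats::var) / n_states, 1)
    variances <- matrix(rep(v0, each = n_states), n_states, 2)
  }
  A <- matrix((1 - delta) / max(n_states - 1, 1), n_states, n_states)
  diag(A) <- if (n_states == 1) 1 else delta
  gaze_hmm(
    pi = rep(1 / n_states, n_states), A = A, means = centers,
    variances = variances, covariance_kind = covariance_kind
  )
}

#' Fit a Gaussian-emission HMM by Baum-Welch EM
#'
#' Unconstrained EM on the 2D fixation coordinates of all scanpaths in the
#' table (one observer group on one image, in the intended workflow). Every
#' sequence starts independently from `pi`; expected-count statistics
#' accumulate across sequences. Iterations stop when the relative
#' log-likelihood improvement falls below `tol` or after `max_iter`
#' iterations. Per-axis emission variances are floored at `var_floor` each
#' M-step to prevent state collapse.
#'
#' @inheritParams init_hmm
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param var_floor Minimum per-axis emission variance (pixels^2).
#' @param min_obs_per_state Minimum fixations required per requested state;
#'   guards over-parameterised fits.
#' @param init_model Optional explicit starting `gaze_hmm` (must have
#'   `n_states` states); overrides `strategy` and `seed`-based
#'   initialisation. Used by the state-count scan's warm starts.
#' @return A `gaze_hmm_fit`: the fitted `model` plus `log_likelihood`,
#'   `loglik_trace` (non-decreasing), `n_iterations`, `converged`, `seed`
#'   and `n_observations`.
#' @examples
#' fx <- simulate_scanpath(
#'   gaze_hmm(1, matrix(1), cbind(500, 400), cbind(100, 100)),
#'   n_fixations = 50, seed = 1
#' )
#' fit <- fit_hmm(fx, n_states = 1, seed = 1)
#' glance(fit)
#' @export
fit_hmm <- function(fixations, n_states, seed = 1L, max_iter = 500,
                    tol = 1e-6, strategy = c("kmeans", "random"),
                    covariance_kind = c("diagonal", "full"), var_floor = 1,
                    min_obs_per_state = 5, init_model = NULL) {
  strategy <- match.arg(strategy)
  covariance_kind <- match.arg(covariance_kind)
  obs <- fix_split(fixations)
  n_obs <- sum(vapply(obs, nrow, integer(1)))
  if (n_obs < min_obs_per_state * n_states) {
    abort(paste0(
      "too few fixations (", n_obs, ") for ", n_states,
      " states: need at least ", min_obs_per_state, " per state"
    ))
  }
  if (!is.null(init_model)) {
    validate_gaze_hmm(init_model)
    if (init_model$n_states != n_states) {
      abort("init_model has the wrong number of states")
    }
    covariance_kind <- init_model$covariance_kind
    m0 <- init_model
  } else {
    m0 <- init_hmm(fixations, n_states,
      seed = seed, strategy = strategy,
      covariance_kind = covariance_kind
    )
  }
  res <- ghmm_em_cpp(
    obs, m0$pi, m0$A, m0$means, m0$covs,
    max_iter = max_iter, tol = tol, var_floor = var_floor,
    diagonal = covariance_kind == "diagonal"
  )
  model <- structure(
    list(
      n_states = n_states, pi = as.numeric(res$pi), A = res$A,
      means = res$means, covs = res$covs,
      covariance_kind = covariance_kind, state_roles = NULL
    ),
    class = "gaze_hmm"
  )
  validate_gaze_hmm(model, tol = 1e-6)
  # renormalise away accumulated floating-point drift
  model$pi <- model$pi / sum(model$pi)
  model$A <- model$A / rowSums(model$A)
  structure(
    list(
      model = model, log_likelihood = res$log_likelihood,
      loglik_trace = as.numeric(res$loglik_trace),
      n_iterations = res$n_iterations, converged = res$converged,
      seed = seed, n_observations = res$n_observations
    ),
    class = "gaze_hmm_fit"
  )
}

#' @export
print.gaze_hmm_fit <- function(x, ...) {
  cat("<gaze_hmm_fit> ", x$model$n_states, " states, logL = ",
    format(x$log_likelihood), ", ", x$n_iterations, " iterations (",
    if (x$converged) "converged" else "not converged", "), n = ",
    x$n_observations, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.gaze_hmm_fit <- function(x, ...) tidy(x$model, ...)

#' One-row fit summary
#'
#' @param x A `gaze_hmm_fit`.
#' @param ... Unused.
#' @return A tibble with `n_states`, `log_likelihood`, `bic`, `n_parameters`,
#'   `n_iterations`, `converged`, `n_observations`, `seed`.
#' @export
glance.gaze_hmm_fit <- function(x, ...) {
  tibble::tibble(
    n_states = x$model$n_states,
    log_likelihood = x$log_likelihood,
    bic = hmm_bic(x),
    n_parameters = n_free_parameters(x$model$n_states, x$model$covariance_kind),
    n_iterations = x$n_iterations,
    converged = x$converged,
    n_observations = x$n_observations,
    seed = x$seed
  )
}

#' @export
logLik.gaze_hmm_fit <- function(object, ...) {
  structure(object$log_likelihood,
    df = n_free_parameters(object$model$n_states, object$model$covariance_kind),
    nobs = object$n_observations, class = "logLik"
  )
}

#' Number of free parameters of a Gaussian-emission HMM
#'
#' Counts the independently estimable parameters entering the BIC penalty:
#' `N - 1` for `pi`, `N (N - 1)` for the transition matrix, `2 N` for the
#' emission means and `2 N` (diagonal) or `3 N` (full) for the covariances,
#' i.e. `N^2 + 4N - 1` and `N^2 + 5N - 1` respectively.
#'
#' @param n_states Number of hidden states.
#' @param covariance_kind `"diagonal"` or `"full"`.
#' @return An integer.
#' @export
n_free_parameters <- function(n_states, covariance_kind = c("diagonal", "full")) {
  covariance_kind <- match.arg(covariance_kind)
  stopifnot(n_states >= 1)
  cov_pars <- if (covariance_kind == "diagonal") 2L else 3L
  as.integer((n_states - 1) + n_states * (n_states - 1) +
    2L * n_states + cov_pars * n_states)
}

#' Bayesian Information Criterion of a fitted HMM
#'
#' `BIC = -2 logL + k ln(n)` with `k` free parameters and `n` the total
#' number of fixations pooled over the fitted sequences.
#'
#' @param fit A `gaze_hmm_fit`.
#' @return A single number; smaller is better.
#' @export
hmm_bic <- function(fit) {
  stopifnot(inherits(fit, "gaze_hmm_fit"))
  k <- n_free_parameters(fit$model$n_states, fit$model$covariance_kind)
  -2 * fit$log_likelihood + k * log(fit$n_observations)
}

#' Write / read a model as JSON
#'
#' Serialises all model matrices at 17 significant digits so a round trip is
#' bit-exact.
#'
#' @param model A `gaze_hmm`.
#' @param path File path.
#' @return `write_hmm` returns `path` invisibly; `read_hmm` returns the
#'   `gaze_hmm`.
#' @export
write_hmm <- function(model, path) {
  validate_gaze_hmm(model)
  n <- model$n_states
  obj <- list(
    n_states = n,
    covariance_kind = model$covariance_kind,
    pi = model$pi,
    A = lapply(seq_len(n), function(i) model$A[i, ]),
    means = lapply(seq_len(n), function(j) model$means[j, ]),
    covariances = lapply(seq_len(n), function(j) {
      list(
        var_x = model$covs[1, 1, j], var_y = model$covs[2, 2, j],
        cov_xy = model$covs[1, 2, j]
      )
    }),
    state_roles = model$state_roles
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- obj$n_states
  covs <- array(0, dim = c(2, 2, n))
  cv <- obj$covariances
  for (j in seq_len(n)) {
    covs[1, 1, j] <- cv$var_x[j]
    covs[2, 2, j] <- cv$var_y[j]
    covs[1, 2, j] <- covs[2, 1, j] <- cv$cov_xy[j]
  }
  as_row_matrix <- function(x, ncol) {
    if (is.list(x)) do.call(rbind, lapply(x, as.numeric)) else matrix(as.numeric(x), ncol = ncol)
  }
  gaze_hmm(
    pi = obj$pi,
    A = as_row_matrix(obj$A, n),
    means = as_row_matrix(obj$means, 2),
    variances = covs,
    covariance_kind = obj$covariance_kind,
    state_roles = obj$state_roles
  )
}
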