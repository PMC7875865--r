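#' Fit HMMs across a range of state counts
#'
#' Fits the model for every state count in `[n_min, n_max]` (the standard
#' scan is 2 to 14 per observer group and image), keeping for each count the
#' best of `restarts` seeded attempts. The first attempt uses the stable
#' k-means initialisation; further attempts use randomly sampled starting
#' means. Attempt seeds derive deterministically from `base_seed`, the state
#' count and the attempt index, so the whole scan is reproducible and every
#' recorded attempt can be replayed.
#'
#' @inheritParams fit_hmm
#' @param n_min,n_max Scanned range of state counts.
#' @param restarts Seeded attempts per state count.
#' @param base_seed Integer seed governing all attempts.
#' @param ... Passed on to [fit_hmm()] (`tol`, `max_iter`,
#'   `covariance_kind`, ...).
#' @return A `state_scan`: list with `entries` (a tibble with one row per
#'   state count: `n_states`, `log_likelihood`, `bic`, `converged`,
#'   `best_seed`, `n_attempts`, `seeds_tried` list-column,
#'   `repair_exhausted`), `fits` (the best `gaze_hmm_fit` per count),
#'   `selected_n`, and the `group` / `image_id` the data came from when
#'   those columns are present.
#' @export
scan_states <- function(fixations, n_min = 2, n_max = 14, restarts = 3,
                        base_seed = 1L, ...) {
  stopifnot(n_min >= 1, n_max >= n_min, restarts >= 1)
  ns <- seq.int(n_min, n_max)
  fits <- vector("list", length(ns))
  rows <- vector("list", length(ns))
  for (k in seq_along(ns)) {
    n <- ns[k]
    att <- run_attempts(fixations, n, seq_len(restarts), base_seed,
      warm_from = if (k > 1) fits[[k - 1]], ...
    )
    fits[[k]] <- att$best
    rows[[k]] <- tibble::tibble(
      n_states = n,
      log_likelihood = att$best$log_likelihood,
      bic = hmm_bic(att$best),
      converged = att$best$converged,
      best_seed = att$best$seed,
      warm_won = att$warm_won,
      n_attempts = length(att$seeds),
      seeds_tried = list(att$seeds),
      repair_exhausted = FALSE
    )
  }
  entries <- dplyr::bind_rows(rows)
  scan <- structure(
    list(
      entries = entries, fits = fits,
      n_min = n_min, n_max = n_max, base_seed = base_seed,
      group = single_or_na(fixations$group),
      image_id = single_or_na(fixations$image_id),
      fixations = fixations
    ),
    class = "state_scan"
  )
  scan_update_selection(scan)
}

single_or_na <- function(x) {
  if (is.null(x)) {
    return(NA_character_)
  }
  u <- unique(x)
  if (length(u) == 1) as.character(u) else NA_character_
}

# Run fit attempts for one state count: the seeded attempts (attempt 1 is
# the k-means initialisation, later ones random restarts) plus, when a fit
# at N-1 states is supplied, a warm start that splits that model's widest
# state — a larger model nests the smaller one, so the warm start anchors
# the log-likelihood profile from below and rescues counts where k-means
# mis-clusters. Degenerate attempts are recorded and skipped; at least one
# must succeed.
run_attempts <- function(fixations, n_states, attempt_idx, base_seed,
                         warm_from = NULL, ...) {
  best <- NULL
  seeds <- integer(0)
  failures <- character(0)
  warm_won <- FALSE
  for (a in attempt_idx) {
    seed <- derive_seed(base_seed, n_states, a)
    seeds <- c(seeds, seed)
    strategy <- if (a == 1) "kmeans" else "random"
    fit <- tryCatch(
      fit_hmm(fixations, n_states, seed = seed, strategy = strategy, ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  if (!is.null(warm_from) && warm_from$model$n_states == n_states - 1L) {
    warm <- tryCatch(
      fit_hmm(fixations, n_states,
        seed = warm_from$seed,
        init_model = split_widest_state(warm_from$model), ...
      ),
      error = function(e) e
    )
    if (!inherits(warm, "error") &&
      (is.null(best) || warm$log_likelihood > best$log_likelihood)) {
      best <- warm
      warm_won <- TRUE
    }
  }
  if (is.null(best)) {
    abort(paste0(
      "scan error: all ", length(attempt_idx), " attempt(s) at ",
      n_states, " states degenerated (", failures[1], ")"
    ))
  }
  list(best = best, seeds = seeds, warm_won = warm_won)
}

# Add one state by splitting the state with the largest total emission
# variance into two copies offset along its wider axis; transition and
# initial mass entering the old state is shared evenly, so the result is a
# valid model whose likelihood EM can only improve.
split_widest_state <- function(m) {
  n <- m$n_states
  tot_var <- vapply(seq_len(n), function(j) m$covs[1, 1, j] + m$covs[2, 2, j], numeric(1))
  j <- which.max(tot_var)
  axis <- if (m$covs[1, 1, j] >= m$covs[2, 2, j]) 1L else 2L
  off <- sqrt(m$covs[axis, axis, j]) / 2
  mean_new <- mean_old <- m$means[j, ]
  mean_old[axis] <- mean_old[axis] - off
  mean_new[axis] <- mean_new[axis] + off
  A <- rbind(cbind(m$A, 0), c(m$A[j, ], 0))
  A[n + 1, n + 1] <- m$A[j, j]
  A[, n + 1] <- A[, j] / 2
  A[, j] <- A[, j] / 2
  covs <- array(0, dim = c(2, 2, n + 1))
  covs[, , seq_len(n)] <- m$covs
  covs[, , n + 1] <- m$covs[, , j]
  means <- rbind(m$means, mean_new)
  means[j, ] <- mean_old
  # pi: halve the split state's mass and give the other half to the clone
  pi <- c(m$pi, m$pi[j] / 2)
  pi[j] <- m$pi[j] / 2
  out <- structure(
    list(
      n_states = n + 1L, pi = pi / sum(pi), A = A, means = means,
      covs = covs, covariance_kind = m$covariance_kind, state_roles = NULL
    ),
    class = "gaze_hmm"
  )
  validate_gaze_hmm(out)
  out
}

scan_update_selection <- function(scan) {
  e <- scan$entries
  # ties broken toward fewer states: which.min returns the first minimum and
  # entries are ordered by n_states
  scan$selected_n <- e$n_states[which.min(e$bic)]
  scan
}

#' Repair log-likelihood discontinuities in a scan
#'
#' A model with more states nests the smaller model, so the best attainable
#' log-likelihood is non-decreasing in the state count; a drop
#' (`logL(N) < logL(N-1)`) marks a local optimum. For every such count this
#' runs up to `extra_restarts` additional randomly-initialised attempts
#' (seeds continue the recorded attempt sequence) and keeps the best fit,
#' sweeping until no discontinuity remains or each count has exhausted its
#' extra attempts. A better fit is never discarded; counts still
#' discontinuous after exhaustion are flagged `repair_exhausted`, which also
#' makes the operation idempotent.
#'
#' @param scan A `state_scan`.
#' @param extra_restarts Extra attempts allowed per state count.
#' @param ... Passed on to [fit_hmm()].
#' @return The repaired `state_scan`.
#' @export
repair_scan <- function(scan, extra_restarts = 5, ...) {
  stopifnot(inherits(scan, "state_scan"))
  repeat {
    e <- scan$entries
    drop_idx <- which(diff(e$log_likelihood) < 0) + 1L
    drop_idx <- drop_idx[!e$repair_exhausted[drop_idx]]
    if (length(drop_idx) == 0) break
    for (k in drop_idx) {
      n <- e$n_states[k]
      used <- e$n_attempts[k]
      att <- run_attempts(
        scan$fixations, n, used + seq_len(extra_restarts),
        scan$base_seed, warm_from = scan$fits[[k - 1L]], ...
      )
      seeds <- c(e$seeds_tried[[k]], att$seeds)
      if (att$best$log_likelihood > e$log_likelihood[k]) {
        scan$fits[[k]] <- att$best
        scan$entries$log_likelihood[k] <- att$best$log_likelihood
        scan$entries$bic[k] <- hmm_bic(att$best)
        scan$entries$converged[k] <- att$best$converged
        scan$entries$best_seed[k] <- att$best$seed
        scan$entries$warm_won[k] <- att$warm_won
      }
      scan$entries$n_attempts[k] <- used + extra_restarts
      scan$entries$seeds_tried[[k]] <- seeds
      scan$entries$repair_exhausted[k] <-
        scan$entries$log_likelihood[k] < scan$entries$log_likelihood[k - 1L]
    }
  }
  scan_update_selection(scan)
}

#' Pick the scan's model by minimum BIC
#'
#' @param scan A `state_scan`.
#' @return The `gaze_hmm_fit` with the smallest BIC; exact ties go to the
#'   smaller state count.
#' @export
select_model <- function(scan) {
  stopifnot(inherits(scan, "state_scan"))
  scan$fits[[which.min(scan$entries$bic)]]
}

#' @export
print.state_scan <- function(x, ...) {
  cat("<state_scan> N in [", x$n_min, ", ", x$n_max, "], selected N = ",
    x$selected_n,
    if (!is.na(x$group)) paste0(" (group ", x$group, ")"),
    if (!is.na(x$image_id)) paste0(" image '", x$image_id, "'"), "\n",
    sep = ""
  )
  print(tidy(x), ...)
  invisible(x)
}

#' Scan entries as a tibble
#'
#' @param x A `state_scan`.
#' @param ... Unused.
#' @return One row per scanned state count with log-likelihood, BIC and a
#'   `selected` flag — the scan-report table.
#' @export
tidy.state_scan <- function(x, ...) {
  e <- dplyr::select(x$entries, -"seeds_tried")
  e$selected <- as.integer(e$n_states == x$selected_n)
  e$group <- x$group
  e$image_id <- x$image_id
  dplyr::relocate(e, "group", "image_id")
}

#' @export
glance.state_scan <- function(x, ...) {
  sel <- x$fits[[which.min(x$entries$bic)]]
  tibble::tibble(
    group = x$group, image_id = x$image_id, selected_n = x$selected_n,
    log_likelihood = sel$log_likelihood, bic = hmm_bic(sel),
    n_observations = sel$n_observations
  )
}

#' BIC and log-likelihood profile of a scan
#'
#' @param object A `state_scan`.
#' @param ... Unused.
#' @return A ggplot: BIC (and log-likelihood) against the number of states,
#'   the selected count marked.
#' @export
autoplot.state_scan <- function(object, ...) {
  e <- tidy(object)
  long <- tidyr::pivot_longer(
    e[, c("n_states", "log_likelihood", "bic")],
    c("log_likelihood", "bic"),
    names_to = "criterion", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$n_states, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_n, linetype = 2) +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(
      x = "number of hidden states", y = NULL,
      title = paste0("State-count scan (selected N = ", object$selected_n, ")")
    )
}

#' Run one scan per observer group and image
#'
#' Convenience wrapper fitting one independent scan (plus repair) for every
#' (group, image) cell of a fixation table, mirroring the one-model-per-
#' group-per-image design of the analysis.
#'
#' @inheritParams scan_states
#' @param repair Run [repair_scan()] on each scan.
#' @param extra_restarts Extra attempts per count during repair.
#' @return A tibble with columns `group`, `image_id` and a `scan`
#'   list-column of `state_scan` objects.
#' @export
fit_group_scans <- function(fixations, n_min = 2, n_max = 14, restarts = 3,
                            base_seed = 1L, repair = TRUE,
                            extra_restarts = 5, ...) {
  cells <- dplyr::distinct(fixations, .data$group, .data$image_id) |>
    dplyr::arrange(.data$group, .data$image_id)
  cells$scan <- purrr::map2(cells$group, cells$image_id, function(g, img) {
    fx <- dplyr::filter(fixations, .data$group == g, .data$image_id == img)
    sc <- scan_states(fx,
      n_min = n_min, n_max = n_max, restarts = restarts,
      base_seed = derive_seed(base_seed, match(g, unique(cells$group)),
        match(img, unique(cells$image_id))), ...
    )
    if (repair) sc <- repair_scan(sc, extra_restarts = extra_restarts, ...)
    sc
  })
  cells
}
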