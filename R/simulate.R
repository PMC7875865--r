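#' Scene geometry configuration
#'
#' Geometry of a synthetic visual-search stimulus: a tablet-class canvas
#' (default 1920 x 1200), three prime AOIs stacked in a right-hand band,
#' three target AOIs placed in the image field, and optionally extra
#' distractor attraction regions. AOIs are axis-aligned squares of side
#' `aoi_size` centred on their state means.
#'
#' @param canvas_width,canvas_height Canvas size in pixels.
#' @param aoi_size AOI square side length in pixels.
#' @param prime_column_x x-centre of the prime band.
#' @param target_positions Optional 3 x 2 matrix of target centres; when
#'   `NULL` they are placed at seeded random with mutual separation.
#' @param n_distractors Number of extra distractor states (no AOI polygon).
#' @return A `scene_config` list.
#' @export
scene_config <- function(canvas_width = 1920, canvas_height = 1200,
                         aoi_size = 150, prime_column_x = 1700,
                         target_positions = NULL, n_distractors = 0) {
  structure(
    list(
      canvas_width = canvas_width, canvas_height = canvas_height,
      aoi_size = aoi_size, prime_column_x = prime_column_x,
      target_positions = target_positions, n_distractors = n_distractors
    ),
    class = "scene_config"
  )
}

square_at <- function(cx, cy, side) {
  h <- side / 2
  rbind(
    c(cx - h, cy - h), c(cx + h, cy - h),
    c(cx + h, cy + h), c(cx - h, cy + h)
  )
}

#' Generate a search scene with known ground truth
#'
#' Builds one synthetic stimulus: the six predefined AOIs plus a
#' ground-truth HMM in the canonical 7-state arrangement — one Gaussian
#' attraction state centred on each prime and target plus one broad
#' "orientation" state spanning the canvas (plus one state per requested
#' distractor). The transition matrix has dominant self-transitions
#' (fixation sequences are persistent) and elevated prime-to-matched-target
#' transitions; the initial distribution favours orientation and the prime
#' band, where a search starts.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; the scene is a pure function of
#'   `(config, seed)`.
#' @param image_id Image identifier for the generated [aoi_set()].
#' @return A `search_scene`: list with `aois` (the [aoi_set()]), `model`
#'   (ground-truth [gaze_hmm()] with descriptive `state_roles`) and
#'   `config`.
#' @export
make_search_scene <- function(config = scene_config(), seed = 1L,
                              image_id = "img1") {
  w <- config$canvas_width
  h <- config$canvas_height
  s <- config$aoi_size
  primes <- cbind(rep(config$prime_column_x, 3), h * c(0.25, 0.5, 0.75))
  targets <- config$target_positions
  lo <- s
  hi_x <- config$prime_column_x - 2 * s
  if (is.null(targets)) {
    targets <- withr::with_seed(seed, {
      sep <- 2.5 * s
      for (try in 1:500) {
        cand <- cbind(runif(3, lo, hi_x), runif(3, lo, h - s))
        d <- as.matrix(stats::dist(rbind(cand, primes)))[1:3, ]
        diag(d) <- Inf # target-target and target-prime separation only
        if (min(d) >= sep) break
        cand <- NULL
      }
      if (is.null(cand)) {
        abort("placement error: cannot place disjoint targets at this AOI size")
      }
      cand
    })
  } else {
    targets <- matrix(as.numeric(targets), 3, 2)
  }
  centers <- rbind(primes, targets)
  labels <- aoi_labels()
  regions <- tibble::tibble(
    label = labels,
    polygon = lapply(seq_len(6), function(i) square_at(centers[i, 1], centers[i, 2], s)),
    center = lapply(seq_len(6), function(i) centers[i, ])
  )
  aois <- aoi_set(image_id, w, h, regions)

  nd <- config$n_distractors
  dcent <- if (nd > 0) {
    withr::with_seed(seed + 1L, cbind(runif(nd, lo, hi_x), runif(nd, lo, h - s)))
  } else {
    matrix(numeric(0), 0, 2)
  }
  roles <- c(labels, "orientation", if (nd > 0) paste0("distractor", seq_len(nd)))
  n <- length(roles)
  means <- rbind(centers, c(w / 2, h / 2), dcent)
  sd_aoi <- s / 4
  sds <- rbind(
    matrix(sd_aoi, 6, 2),
    c(w / 5, h / 5),
    matrix(s / 3, nd, 2)
  )
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    self <- if (roles[i] == "orientation") 0.6 else 0.8
    A[i, i] <- self
    rest <- 1 - self
    elevated <- integer(0)
    if (grepl("^P", roles[i])) elevated <- 3L + as.integer(sub("P", "", roles[i]))
    if (grepl("^T", roles[i])) {
      k <- as.integer(sub("T", "", roles[i]))
      elevated <- (k %% 3L) + 1L # next prime in the (arbitrary) pairing order
    }
    if (length(elevated) > 0) {
      A[i, elevated] <- rest * 0.5
      rest <- rest * 0.5
    }
    others <- setdiff(seq_len(n), c(i, elevated))
    A[i, others] <- rest / length(others)
  }
  pi <- rep(0.3 / max(n - 4, 1), n)
  pi[roles == "orientation"] <- 0.4
  pi[1:3] <- 0.1 # primes: the cue band draws the first fixations
  pi <- pi / sum(pi)
  model <- gaze_hmm(
    pi = pi, A = A, means = means, variances = sds^2,
    state_roles = roles
  )
  structure(list(aois = aois, model = model, config = config),
    class = "search_scene"
  )
}

#' @export
print.search_scene <- function(x, ...) {
  cat("<search_scene> ")
  print(x$aois)
  cat("ground truth: ", x$model$n_states, " states (",
    paste(x$model$state_roles, collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

# scale the emission SDs of the states with AOI roles by `f`
scale_aoi_sds <- function(model, f) {
  idx <- which(model$state_roles %in% aoi_labels())
  for (j in idx) model$covs[, , j] <- model$covs[, , j] * f^2
  model
}

#' Expert-group variant of a scene's ground truth
#'
#' Experts focus on smaller image parts: their generative model has tighter
#' emissions on the AOI states (`sd_scale` < 1), higher AOI self-transition
#' mass, and optionally extra fine-grained distractor states (experts carve
#' the image into more regions).
#'
#' @param scene A `search_scene`.
#' @param sd_scale Multiplier on AOI-state emission SDs.
#' @param extra_states Number of added fine distractor states.
#' @param self_boost Added self-transition mass on AOI states (renormalised).
#' @param seed Seed for placing the extra states.
#' @return A `gaze_hmm`.
#' @export
expert_hmm <- function(scene, sd_scale = 0.6, extra_states = 1,
                       self_boost = 0.05, seed = 1L) {
  m <- scale_aoi_sds(scene$model, sd_scale)
  aoi_idx <- which(m$state_roles %in% aoi_labels())
  for (i in aoi_idx) {
    off <- setdiff(seq_len(m$n_states), i)
    add <- min(self_boost, sum(m$A[i, off]) - 1e-6)
    m$A[i, off] <- m$A[i, off] * (1 - (m$A[i, i] + add)) / sum(m$A[i, off])
    m$A[i, i] <- m$A[i, i] + add
  }
  if (extra_states > 0) {
    s <- scene$config$aoi_size
    cent <- withr::with_seed(seed, cbind(
      runif(extra_states, s, scene$config$prime_column_x - 2 * s),
      runif(extra_states, s, scene$config$canvas_height - s)
    ))
    for (k in seq_len(extra_states)) {
      m <- add_state(m, cent[k, ], rep((s / 4)^2, 2), paste0("fine_distractor", k))
    }
  }
  validate_gaze_hmm(m)
  m
}

# graft one state onto a model: small incoming mass from every state,
# persistent self-transition, uniform outgoing mass
add_state <- function(m, mean_xy, var_xy, role, eps = 0.03, self = 0.7) {
  n <- m$n_states
  A <- matrix(0, n + 1, n + 1)
  A[seq_len(n), seq_len(n)] <- m$A * (1 - eps)
  A[seq_len(n), n + 1] <- eps
  A[n + 1, n + 1] <- self
  A[n + 1, seq_len(n)] <- (1 - self) / n
  covs <- array(0, dim = c(2, 2, n + 1))
  covs[, , seq_len(n)] <- m$covs
  covs[, , n + 1] <- diag(var_xy, 2)
  structure(
    list(
      n_states = n + 1L, pi = c(m$pi * (1 - eps), eps),
      A = A, means = rbind(m$means, mean_xy), covs = covs,
      covariance_kind = m$covariance_kind,
      state_roles = c(m$state_roles, role)
    ),
    class = "gaze_hmm"
  )
}

#' Novice-group variant of a scene's ground truth
#'
#' Non-experts use wider image parts: broader emissions on the AOI states
#' (`sd_scale` > 1), a broadened orientation state, and extra transition
#' mass shifted toward it.
#'
#' @param scene A `search_scene`.
#' @param sd_scale Multiplier on AOI-state emission SDs.
#' @param orientation_shift Transition mass moved toward the orientation
#'   state from every other state.
#' @param orientation_broaden Multiplier on the orientation state's SDs.
#' @return A `gaze_hmm`.
#' @export
novice_hmm <- function(scene, sd_scale = 1.5, orientation_shift = 0.08,
                       orientation_broaden = 1.2) {
  m <- scale_aoi_sds(scene$model, sd_scale)
  o <- which(m$state_roles == "orientation")
  if (length(o) == 1) {
    m$covs[, , o] <- m$covs[, , o] * orientation_broaden^2
    for (i in setdiff(seq_len(m$n_states), o)) {
      shift <- orientation_shift * (1 - m$A[i, o])
      m$A[i, -o] <- m$A[i, -o] * (1 - shift / sum(m$A[i, -o]))
      m$A[i, o] <- 1 - sum(m$A[i, -o])
    }
  }
  validate_gaze_hmm(m)
  m
}

#' Simulate one scanpath from an HMM
#'
#' Samples a hidden-state path from `pi` and `A`, then a fixation
#' coordinate from each state's 2D Gaussian (clipped to the canvas) and a
#' duration from a lognormal model; onsets accumulate durations plus a
#' 30 ms saccade gap. Deterministic given the seed.
#'
#' @param model A `gaze_hmm`.
#' @param n_fixations Sequence length, at least 1.
#' @param canvas Length-2 canvas size (width, height) in pixels.
#' @param seed Integer seed.
#' @param subject_id,group,image_id Identifiers stamped on the rows.
#' @param duration_meanlog,duration_sdlog Lognormal fixation-duration
#'   parameters (defaults: median 280 ms, realistic spread).
#' @param return_states Also return the true hidden state per fixation
#'   (column `true_state`), for recovery experiments.
#' @return A fixation tibble in the standard column layout.
#' @export
simulate_scanpath <- function(model, n_fixations, canvas = c(1920, 1200),
                              seed = 1L, subject_id = "s1", group = "sim",
                              image_id = "img1",
                              duration_meanlog = log(280),
                              duration_sdlog = 0.6,
                              return_states = FALSE) {
  stopifnot(n_fixations >= 1)
  validate_gaze_hmm(model)
  n <- model$n_states
  withr::with_seed(seed, {
    st <- integer(n_fixations)
    st[1] <- sample.int(n, 1, prob = model$pi)
    for (t in seq_len(n_fixations - 1L)) {
      st[t + 1L] <- sample.int(n, 1, prob = model$A[st[t], ])
    }
    xy <- t(vapply(st, function(j) {
      S <- model$covs[, , j]
      z <- rnorm(2)
      L <- t(chol(S))
      model$means[j, ] + as.numeric(L %*% z)
    }, numeric(2)))
    xy[, 1] <- pmin(pmax(xy[, 1], 0), canvas[1])
    xy[, 2] <- pmin(pmax(xy[, 2], 0), canvas[2])
    dur <- rlnorm(n_fixations, duration_meanlog, duration_sdlog)
    onset <- cumsum(c(0, head(dur, -1) + 30))
    out <- tibble::tibble(
      subject_id = subject_id, group = group, image_id = image_id,
      fixation_index = seq_len(n_fixations), onset_ms = onset,
      duration_ms = dur, x_px = xy[, 1], y_px = xy[, 2]
    )
    if (return_states) out$true_state <- st
    out
  })
}

#' Cohort simulation configuration
#'
#' Statistical shape of a simulated observer cohort. Defaults emulate the
#' recorded search task: sequence lengths lognormal with median about 120
#' fixations (clamped to the observed 40-350 range), fixation durations
#' lognormal with median about 280 ms, and group-dependent touch accuracy
#' producing a realistic gap in targets found.
#'
#' @param n_per_group Subjects per group.
#' @param len_meanlog,len_sdlog,len_range Lognormal sequence-length model
#'   and clamp range.
#' @param duration_meanlog,duration_sdlog Fixation-duration model.
#' @param hit_prob Named per-group probability that a target is identified.
#' @param touch_sd SD (pixels) of touch scatter around an identified
#'   target's centre.
#' @param miss_offset Distance (pixels) of a registered-but-wrong touch
#'   from the target centre.
#' @param motor_overhead_ms Added non-gaze time per image.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 25, len_meanlog = log(120),
                          len_sdlog = 0.45, len_range = c(40, 350),
                          duration_meanlog = log(280), duration_sdlog = 0.6,
                          hit_prob = c(expert = 0.84, novice = 0.80),
                          touch_sd = 15, miss_offset = 150,
                          motor_overhead_ms = 1500) {
  structure(
    list(
      n_per_group = n_per_group, len_meanlog = len_meanlog,
      len_sdlog = len_sdlog, len_range = len_range,
      duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
      hit_prob = hit_prob, touch_sd = touch_sd, miss_offset = miss_offset,
      motor_overhead_ms = motor_overhead_ms
    ),
    class = "cohort_config"
  )
}

#' Simulate a two-group cohort on one or more scenes
#'
#' Generates, for every subject and image: a scanpath from the subject's
#' group model, touch events near target centres with group-dependent hit
#' probability and scatter, and a completion time (sum of fixation
#' durations plus motor overhead). Fully seeded: every subject x image
#' stream derives from `seed`.
#'
#' @param scenes A `search_scene` or list of them (one per image).
#' @param expert_model,novice_model Group generative models (defaults:
#'   [expert_hmm()] / [novice_hmm()] of each scene).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `gaze_cohort` list: tibbles `fixations`, `touches`,
#'   `task_times`, plus `scenes`.
#' @export
simulate_cohort <- function(scenes, expert_model = NULL, novice_model = NULL,
                            config = cohort_config(), seed = 1L) {
  if (inherits(scenes, "search_scene")) scenes <- list(scenes)
  groups <- c("expert", "novice")
  fixes <- list()
  touches <- list()
  times <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (si in seq_len(config$n_per_group)) {
      sub <- sprintf("%s%02d", substr(g, 1, 1), si)
      for (ii in seq_along(scenes)) {
        sc <- scenes[[ii]]
        model <- if (g == "expert") {
          expert_model %||% expert_hmm(sc)
        } else {
          novice_model %||% novice_hmm(sc)
        }
        canvas <- c(sc$aois$canvas_width, sc$aois$canvas_height)
        len_seed <- derive_seed(seed, gi, si, ii, 1)
        len <- withr::with_seed(len_seed, {
          round(min(
            max(rlnorm(1, config$len_meanlog, config$len_sdlog), config$len_range[1]),
            config$len_range[2]
          ))
        })
        fx <- simulate_scanpath(model, len,
          canvas = canvas,
          seed = derive_seed(seed, gi, si, ii, 2), subject_id = sub,
          group = g, image_id = sc$aois$image_id,
          duration_meanlog = config$duration_meanlog,
          duration_sdlog = config$duration_sdlog
        )
        fixes[[length(fixes) + 1L]] <- fx
        tr <- dplyr::filter(sc$aois$regions, grepl("^T[0-9]+$", .data$label))
        tch <- withr::with_seed(derive_seed(seed, gi, si, ii, 3), {
          purrr::map_dfr(seq_len(nrow(tr)), function(k) {
            ctr <- tr$center[[k]]
            hit <- runif(1) < config$hit_prob[[g]]
            if (hit) {
              pos <- ctr + rnorm(2, 0, config$touch_sd)
            } else {
              ang <- runif(1, 0, 2 * pi)
              pos <- ctr + config$miss_offset * c(cos(ang), sin(ang))
            }
            tibble::tibble(
              subject_id = sub, image_id = sc$aois$image_id,
              x_px = min(max(pos[1], 0), canvas[1]),
              y_px = min(max(pos[2], 0), canvas[2]),
              time_ms = sum(fx$duration_ms) * k / nrow(tr)
            )
          })
        })
        touches[[length(touches) + 1L]] <- tch
        times[[length(times) + 1L]] <- tibble::tibble(
          subject_id = sub, group = g, image_id = sc$aois$image_id,
          time_s = (sum(fx$duration_ms) + config$motor_overhead_ms) / 1000
        )
      }
    }
  }
  structure(
    list(
      fixations = dplyr::bind_rows(fixes),
      touches = dplyr::bind_rows(touches),
      task_times = dplyr::bind_rows(times),
      scenes = scenes
    ),
    class = "gaze_cohort"
  )
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat("<gaze_cohort> ", dplyr::n_distinct(x$fixations$subject_id),
    " subjects, ", length(x$scenes), " image(s), ",
    nrow(x$fixations), " fixations\n",
    sep = ""
  )
  invisible(x)
}
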