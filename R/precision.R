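#' Classify every fixation to a hidden state
#'
#' Assigns each fixation exhaustively and disjunctively to exactly one
#' hidden state of a fitted model — the data-driven AOIs. The default takes
#' the per-fixation argmax of the smoothed (forward-backward) posterior;
#' `mode = "viterbi"` uses the jointly most probable path instead. Ties go
#' to the lower state index.
#'
#' @param fixations Fixation tibble (the sequences the model was fitted to,
#'   or compatible ones).
#' @param fit A `gaze_hmm_fit` (or bare `gaze_hmm`).
#' @param mode `"posterior"` (default) or `"viterbi"`.
#' @return The identifying columns plus `x_px`, `y_px`, `duration_ms` when
#'   present, and a 1-based integer `state` column; one row per fixation.
#' @export
classify_fixations <- function(fixations, fit, mode = c("posterior", "viterbi")) {
  mode <- match.arg(mode)
  model <- if (inherits(fit, "gaze_hmm_fit")) fit$model else fit
  stopifnot(inherits(model, "gaze_hmm"))
  fx <- dplyr::arrange(
    fixations, .data$subject_id, .data$image_id,
    .data$fixation_index
  )
  if (mode == "viterbi") {
    st <- viterbi_path(fx, model)$state
  } else {
    post <- posterior_state_probs(fx, model)
    pm <- as.matrix(post[, paste0("p_state_", seq_len(model$n_states))])
    st <- max.col(pm, ties.method = "first")
  }
  out <- dplyr::select(fx, dplyr::any_of(c(
    "subject_id", "group", "image_id",
    "fixation_index", "onset_ms", "duration_ms", "x_px", "y_px"
  )))
  out$state <- st
  out
}

#' Cross-tabulate hidden states against predefined AOIs
#'
#' Counts, for every hidden state, how many of its assigned fixations fall
#' in each predefined region (and white space). The grand total equals the
#' number of classified fixations.
#'
#' @param assignment Output of [classify_fixations()] (must carry `x_px`,
#'   `y_px` and `state`).
#' @param aoiset The image's [aoi_set()].
#' @param n_states Number of model states (defaults to the largest state
#'   index observed).
#' @return An `overlap_matrix`: integer matrix, rows = states, columns =
#'   region labels plus `WS`.
#' @export
overlap_matrix <- function(assignment, aoiset, n_states = max(assignment$state)) {
  labs <- c(aoiset$regions$label, "WS")
  lab <- aoi_label_of(assignment$x_px, assignment$y_px, aoiset)
  counts <- table(
    factor(assignment$state, levels = seq_len(n_states)),
    factor(lab, levels = labs)
  )
  m <- matrix(as.integer(counts), nrow = n_states,
    dimnames = list(state = seq_len(n_states), label = labs)
  )
  structure(m, class = c("overlap_matrix", "matrix"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> fixation counts, states x AOI labels\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
tidy.overlap_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    setNames(c("state", "label", "n")) |>
    dplyr::mutate(state = as.integer(.data$state))
}

#' Link each predefined AOI to its dominant hidden state
#'
#' For every prime/target label, the hidden state holding the highest
#' number of that AOI's fixations (ties to the lower state index). The map
#' may be many-to-one: a state that absorbs several regions — e.g. one
#' state covering all three primes when observers shuttle between them —
#' links to each of them. An AOI containing no fixations at all gets an
#' undefined (`NA`) linkage and is flagged. White space is never linked.
#'
#' @param matrix An [overlap_matrix()].
#' @param labels Labels to link; defaults to the six primes/targets present
#'   in the matrix.
#' @return A tibble: `aoi_label`, `state` (NA when undefined),
#'   `n_fixations` (count in the linked state and AOI), `flagged`.
#' @export
link_states <- function(matrix, labels = intersect(aoi_labels(), colnames(matrix))) {
  purrr::map_dfr(labels, function(l) {
    col <- matrix[, l]
    if (sum(col) == 0) {
      tibble::tibble(
        aoi_label = l, state = NA_integer_, n_fixations = 0L,
        flagged = TRUE
      )
    } else {
      s <- which.max(col) # first maximum = lowest state index
      tibble::tibble(
        aoi_label = l, state = as.integer(s),
        n_fixations = as.integer(col[s]), flagged = FALSE
      )
    }
  })
}

#' Fixation-overlap precision of linked states
#'
#' The precision of an AOI is the percentage of fixations assigned to its
#' linked hidden state that actually land inside the AOI:
#' `100 * n(state = s_a & inside a) / n(state = s_a)`. High overlap between
#' a hidden state and its AOI indicates a precise search. In per-subject
#' mode both counts are restricted to one subject's fixations while the
#' linkage stays group-level (the group model defines the states); a
#' subject contributing no fixations to the linked state scores 0 and is
#' flagged.
#'
#' @param assignment Output of [classify_fixations()].
#' @param linkage Output of [link_states()].
#' @param aoiset The image's [aoi_set()].
#' @param per_subject Compute one row per subject and AOI instead of one
#'   pooled row per AOI.
#' @return A `PrecisionTable` tibble: `group`, `image_id`, (`subject_id`,)
#'   `aoi_label`, `linked_state`, `n_state_fixations`, `n_in_aoi`,
#'   `precision_percent`, `flagged`. AOIs with undefined linkage are
#'   omitted (they are already flagged in `linkage`).
#' @export
precision_scores <- function(assignment, linkage, aoiset, per_subject = FALSE) {
  assignment$aoi <- aoi_label_of(assignment$x_px, assignment$y_px, aoiset)
  link <- dplyr::filter(linkage, !is.na(.data$state))
  grp <- single_or_na(assignment$group)
  img <- single_or_na(assignment$image_id)
  score_one <- function(df, lab, s) {
    in_state <- df$state == s
    n_state <- sum(in_state)
    n_in <- sum(in_state & df$aoi == lab)
    tibble::tibble(
      aoi_label = lab, linked_state = s,
      n_state_fixations = n_state, n_in_aoi = n_in,
      precision_percent = if (n_state == 0) 0 else 100 * n_in / n_state,
      flagged = n_state == 0
    )
  }
  if (!per_subject) {
    out <- purrr::map2_dfr(link$aoi_label, link$state, score_one, df = assignment)
    out <- dplyr::mutate(out, group = grp, image_id = img, .before = 1)
  } else {
    subjects <- sort(unique(assignment$subject_id))
    out <- purrr::map_dfr(subjects, function(sub) {
      df <- dplyr::filter(assignment, .data$subject_id == sub)
      res <- purrr::map2_dfr(link$aoi_label, link$state, score_one, df = df)
      dplyr::mutate(res, subject_id = sub, .before = 1)
    })
    out <- dplyr::mutate(out, group = grp, image_id = img, .before = 1)
  }
  out
}

#' Score behavioural touch responses
#'
#' A target counts as identified when any of the subject's touches on that
#' image lies within `radius` pixels (Euclidean, boundary inclusive) of the
#' target region's centre; each target is counted at most once.
#'
#' @param touches Tibble with `subject_id`, `image_id`, `x_px`, `y_px`.
#' @param aoiset The image's [aoi_set()]; targets are the regions labelled
#'   `T1`, `T2`, `T3`.
#' @param radius Scoring radius in pixels (the task rule uses 50).
#' @return A tibble per subject x image: logical `T1`, `T2`, `T3` hit flags
#'   and `targets_found` (0-3).
#' @export
score_touches <- function(touches, aoiset, radius = 50) {
  tr <- dplyr::filter(aoiset$regions, grepl("^T[0-9]+$", .data$label))
  if (nrow(tr) == 0) abort("aoi_set has no target regions")
  centers <- do.call(rbind, tr$center)
  tt <- dplyr::filter(touches, .data$image_id == aoiset$image_id)
  base <- dplyr::distinct(tt, .data$subject_id, .data$image_id)
  for (k in seq_len(nrow(tr))) {
    hitcol <- vapply(seq_len(nrow(base)), function(i) {
      tk <- tt[tt$subject_id == base$subject_id[i], ]
      any(sqrt((tk$x_px - centers[k, 1])^2 + (tk$y_px - centers[k, 2])^2) <= radius)
    }, logical(1))
    base[[tr$label[k]]] <- hitcol
  }
  base$targets_found <- rowSums(as.matrix(base[, tr$label, drop = FALSE]))
  base
}
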