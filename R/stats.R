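#' Welch's two-sample t-test from summary statistics
#'
#' Computes the unequal-variance two-sample t statistic
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value, directly from group means,
#' sample standard deviations (n-1 denominator) and sizes. Working from
#' summaries lets published group tables be re-tested without raw data.
#'
#' @param mean1,sd1,n1 First group's mean, sample SD and size.
#' @param mean2,sd2,n2 Second group's.
#' @return A tibble: `statistic` (t), `df`, `p.value`, and the summaries.
#' @examples
#' welch_t(22.76, 1.69, 25, 21.56, 2.65, 25) # targets found, experts vs non-experts
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) abort("undefined statistic: both group variances are zero")
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(
    statistic = t, df = df, p.value = 2 * pt(-abs(t), df),
    mean1 = mean1, sd1 = sd1, n1 = n1, mean2 = mean2, sd2 = sd2, n2 = n2
  )
}

#' Welch's t-test on a long data frame
#'
#' Data-frame front end to [welch_t()]: summarises `value` by the two
#' levels of `group` and delegates to the summary-statistic form.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the
#'   two-level grouping factor.
#' @return As [welch_t()]; the first group is the lower factor level.
#' @export
welch_t_data <- function(data, value, group) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("welch_t_data needs exactly two groups")
  x <- data[[value]][g == levels(g)[1]]
  y <- data[[value]][g == levels(g)[2]]
  welch_t(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Split-plot ANOVA on precision percentages
#'
#' Univariate split-plot (mixed) ANOVA for the design used to compare
#' search precision: one between-subjects factor (expertise group), two
#' within-subject factors (AOI position 1-3 and image), every subject
#' measured in all within cells. The between effect is tested against the
#' subject-within-group stratum; each within effect and its group
#' interaction against the corresponding subject-by-factor stratum
#' (`Error(subject/(within1*within2))`). No sphericity correction is
#' applied. The design must be complete and balanced.
#'
#' @param data Long-format data frame.
#' @param value Response column name (e.g. precision percent).
#' @param subject,group,within1,within2 Column names of the subject
#'   identifier, between factor and the two within factors. `within2` may
#'   be `NULL` for a single within factor.
#' @return An `anova_table` tibble: `stratum`, `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value` (error rows have NA statistic).
#' @export
mixed_anova <- function(data, value, subject, group, within1, within2 = NULL) {
  df <- data.frame(
    y = as.numeric(data[[value]]),
    subject = factor(data[[subject]]),
    group = factor(data[[group]]),
    w1 = factor(data[[within1]])
  )
  wfs <- "w1"
  if (!is.null(within2)) {
    df$w2 <- factor(data[[within2]])
    wfs <- c("w1", "w2")
  }
  check_balance(df, wfs, within1, within2)
  form <- if (is.null(within2)) {
    y ~ group * w1 + Error(subject / w1)
  } else {
    y ~ group * w1 * w2 + Error(subject / (w1 * w2))
  }
  fit <- aov(form, data = df)
  out <- purrr::imap_dfr(summary(fit), function(s, stratum) {
    tab <- as.data.frame(s[[1]])
    term <- trimws(rownames(tab))
    tibble::tibble(
      stratum = sub("^Error: ", "", stratum),
      term = gsub("w1", within1, gsub("w2", within2 %||% "w2", term)),
      df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
      statistic = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
      p.value = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_
    )
  })
  class(out) <- c("anova_table", class(out))
  out
}

check_balance <- function(df, wfs, within1, within2) {
  cells <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(c("subject", wfs))))
  full <- nlevels(df$subject) * prod(vapply(wfs, function(w) nlevels(df[[w]]), integer(1)))
  if (nrow(cells) != full || any(cells$n != 1)) {
    have <- paste(cells$subject, do.call(paste, cells[wfs]))
    grid <- expand.grid(c(
      list(levels(df$subject)),
      lapply(wfs, function(w) levels(df[[w]]))
    ))
    want <- do.call(paste, grid)
    missing <- setdiff(want, have)
    abort(paste0(
      "design error: unbalanced or incomplete table; missing/duplicated cells: ",
      paste(head(missing, 5), collapse = "; "),
      if (length(missing) > 5) " ..." else ""
    ))
  }
  grp <- dplyr::distinct(df, .data$subject, .data$group)
  if (anyDuplicated(grp$subject) > 0) {
    abort("design error: a subject appears in more than one group")
  }
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return A tibble: `estimate` (r), `statistic` (t), `df`, `p.value`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(
    estimate = unname(ct$estimate), statistic = unname(ct$statistic),
    df = unname(ct$parameter), p.value = ct$p.value
  )
}

#' Behavioural summary per group and image
#'
#' Per-target error rates (1 minus the proportion of subjects identifying
#' the target) and completion-time summaries, aggregated by group and
#' image — the behavioural companion table to the gaze analysis.
#'
#' @param scores Output of [score_touches()] (rows per subject x image with
#'   target hit flags), plus a `group` column.
#' @param task_times Optional tibble `subject_id`, `image_id`, `time_s`;
#'   when given, mean/SD completion times are appended.
#' @return A tibble per group x image x target: `error_rate`, `n`, and when
#'   available `mean_time_s`, `sd_time_s`.
#' @export
behavioral_summary <- function(scores, task_times = NULL) {
  stopifnot("group" %in% names(scores))
  tcols <- grep("^T[0-9]+$", names(scores), value = TRUE)
  long <- tidyr::pivot_longer(scores,
    dplyr::all_of(tcols),
    names_to = "target", values_to = "hit"
  )
  out <- long |>
    dplyr::group_by(.data$group, .data$image_id, .data$target) |>
    dplyr::summarise(
      error_rate = 1 - mean(.data$hit),
      n = dplyr::n(), .groups = "drop"
    )
  if (!is.null(task_times)) {
    tt <- scores |>
      dplyr::distinct(.data$subject_id, .data$image_id, .data$group) |>
      dplyr::inner_join(task_times, by = c("subject_id", "image_id")) |>
      dplyr::group_by(.data$group, .data$image_id) |>
      dplyr::summarise(
        mean_time_s = mean(.data$time_s),
        sd_time_s = stats::sd(.data$time_s), .groups = "drop"
      )
    out <- dplyr::left_join(out, tt, by = c("group", "image_id"))
  }
  out
}
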