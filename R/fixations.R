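#' Read a fixation table
#'
#' Reads the package's standard fixation CSV: one row per fixation with
#' columns `subject_id`, `group`, `image_id`, `fixation_index`, `onset_ms`,
#' `duration_ms`, `x_px`, `y_px`. Coordinates are decimal pixels with the
#' origin at the top-left (x rightward, y downward). Rows are returned
#' sorted by subject, image and fixation index, so shuffled input yields an
#' identical table.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header
#'   mandatory, `.` decimal mark).
#' @return A tibble, one row per fixation, sorted.
#' @export
read_fixations <- function(path) {
  cols <- c(
    "subject_id", "group", "image_id", "fixation_index", "onset_ms",
    "duration_ms", "x_px", "y_px"
  )
  hdr <- names(suppressMessages(
    readr::read_csv(path, n_max = 0, show_col_types = FALSE)
  ))
  miss <- setdiff(cols, hdr)
  if (length(miss) > 0) {
    abort(paste0(
      "fixation table format error: missing column(s) ",
      paste(miss, collapse = ", ")
    ))
  }
  fx <- suppressWarnings(suppressMessages(readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      image_id = readr::col_character(),
      fixation_index = readr::col_integer(),
      onset_ms = readr::col_double(),
      duration_ms = readr::col_double(),
      x_px = readr::col_double(),
      y_px = readr::col_double()
    )
  )))
  pb <- readr::problems(fx)
  if (nrow(pb) > 0) {
    abort(paste0(
      "fixation table parse error at line ", pb$row[1],
      ", column ", pb$col[1], ": expected ", pb$expected[1]
    ))
  }
  validate_fixations(fx)
  dplyr::arrange(fx, .data$subject_id, .data$image_id, .data$fixation_index)
}

validate_fixations <- function(fx) {
  if (any(!is.finite(fx$x_px)) || any(!is.finite(fx$y_px))) {
    abort("fixation coordinates must be finite")
  }
  if (any(fx$duration_ms <= 0)) abort("fixation durations must be positive")
  dup <- duplicated(fx[, c("subject_id", "image_id", "fixation_index")])
  if (any(dup)) {
    d <- fx[dup, ][1, ]
    abort(paste0(
      "fixation table integrity error: duplicate fixation_index ",
      d$fixation_index, " for subject '", d$subject_id, "', image '",
      d$image_id, "'"
    ))
  }
  grp <- dplyr::distinct(fx, .data$subject_id, .data$group)
  if (anyDuplicated(grp$subject_id) > 0) {
    abort("integrity error: a subject appears in more than one group")
  }
  invisible(fx)
}

#' Write a fixation table
#'
#' Inverse of [read_fixations()]; the round trip is loss-free (coordinates
#' written in full double precision).
#'
#' @param fixations Fixation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  readr::write_csv(fixations, path)
  invisible(path)
}

#' Consistency report for a fixation/AOI dataset
#'
#' Report-only check run before modelling: flags fixations outside their
#' image's canvas, images that lack an AOI definition, and tabulates
#' per-group scanpath counts. Never mutates the data.
#'
#' @param fixations Fixation tibble.
#' @param aoisets A single [aoi_set()] or a (possibly named) list of them.
#' @return A `gaze_validation` object: a list with tibbles `issues` (columns
#'   `type`, `subject_id`, `image_id`, `detail`) and `group_counts`
#'   (`group`, `n_subjects`, `n_sequences`, `n_fixations`).
#' @export
validate_gaze_data <- function(fixations, aoisets) {
  if (inherits(aoisets, "aoi_set")) aoisets <- list(aoisets)
  ids <- vapply(aoisets, function(a) a$image_id, character(1))
  names(aoisets) <- ids
  issues <- list()
  for (img in unique(fixations$image_id)) {
    fi <- dplyr::filter(fixations, .data$image_id == img)
    if (!img %in% ids) {
      issues[[length(issues) + 1L]] <- tibble::tibble(
        type = "missing_aoi", subject_id = NA_character_, image_id = img,
        detail = "no AOI definition for this image"
      )
      next
    }
    a <- aoisets[[img]]
    out <- fi$x_px < 0 | fi$x_px > a$canvas_width |
      fi$y_px < 0 | fi$y_px > a$canvas_height
    if (any(out)) {
      bad <- fi[out, ]
      issues[[length(issues) + 1L]] <- tibble::tibble(
        type = "out_of_bounds", subject_id = bad$subject_id, image_id = img,
        detail = paste0(
          "fixation ", bad$fixation_index, " at (",
          round(bad$x_px, 1), ", ", round(bad$y_px, 1),
          ") outside canvas ", a$canvas_width, "x", a$canvas_height
        )
      )
    }
  }
  issues <- if (length(issues) > 0) {
    dplyr::bind_rows(issues)
  } else {
    tibble::tibble(
      type = character(), subject_id = character(),
      image_id = character(), detail = character()
    )
  }
  group_counts <- fixations |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_subjects = dplyr::n_distinct(.data$subject_id),
      n_sequences = dplyr::n_distinct(paste(.data$subject_id, .data$image_id)),
      n_fixations = dplyr::n(),
      .groups = "drop"
    )
  structure(list(issues = issues, group_counts = group_counts),
    class = "gaze_validation"
  )
}

#' @export
print.gaze_validation <- function(x, ...) {
  cat("<gaze_validation> ", nrow(x$issues), " issue(s)\n", sep = "")
  if (nrow(x$issues) > 0) print(x$issues, ...)
  cat("per-group counts:\n")
  print(x$group_counts, ...)
  invisible(x)
}
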