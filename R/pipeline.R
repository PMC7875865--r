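#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the full configuration of an end-to-end
#' run: input paths or a simulation block, the scanned state range,
#' restart counts, decoding mode, covariance kind, and the master seed.
#' Every field has an explicit default so a run is self-describing; the
#' manifest written by [run_pipeline()] records them all.
#'
#' @param fixations,aois,touches Input paths (CSV / JSON / CSV), or `NULL`
#'   when `simulate` is set.
#' @param simulate `NULL`, or a list with optional elements `n_per_group`,
#'   `n_images`, `seq_median` passed to the generator.
#' @param n_min,n_max Scanned state range.
#' @param restarts,extra_restarts Attempts per count, and extra attempts
#'   during discontinuity repair.
#' @param covariance_kind `"diagonal"` or `"full"`.
#' @param decode_mode `"posterior"` or `"viterbi"`.
#' @param per_subject Also write per-subject precision rows.
#' @param anova Run the split-plot ANOVA (needs >= 2 images).
#' @param figures Render density-map PNGs.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fixations = NULL, aois = NULL, touches = NULL,
                            simulate = NULL, n_min = 2, n_max = 14,
                            restarts = 3, extra_restarts = 5,
                            covariance_kind = "diagonal",
                            decode_mode = "posterior", per_subject = TRUE,
                            anova = TRUE, figures = FALSE, seed = 1L) {
  cfg <- list(
    fixations = fixations, aois = aois, touches = touches,
    simulate = simulate, n_min = n_min, n_max = n_max, restarts = restarts,
    extra_restarts = extra_restarts, covariance_kind = covariance_kind,
    decode_mode = decode_mode, per_subject = per_subject, anova = anova,
    figures = figures, seed = seed
  )
  if (is.null(cfg$simulate) && (is.null(cfg$fixations) || is.null(cfg$aois))) {
    abort("pipeline_config needs either input paths or a simulate block")
  }
  if (!cfg$n_min >= 1 || cfg$n_max < cfg$n_min) abort("invalid state range")
  if (is.null(cfg$seed)) abort("a seed is required: no silent nondeterminism")
  structure(cfg, class = "pipeline_config")
}

#' @param path YAML file with the fields of [pipeline_config()].
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, y)
}

#' Run the full scanpath-modelling pipeline
#'
#' Chains every stage: load (or simulate) the dataset, validate it, fit one
#' state-count scan per group and image with discontinuity repair, select
#' models by BIC, classify fixations, link states to AOIs, score precision
#' (group-level and optionally per subject), run the group statistics
#' (Welch t on targets found; split-plot ANOVA on precision when the design
#' supports it), and write all artefacts into `out_dir`: `scan_report.csv`,
#' `precision.csv`, `precision_subject.csv`, `stats.csv`, fitted models as
#' JSON, optional figures, a `manifest.json` (package version, full config,
#' seed) and a `log.txt`. Numeric outputs are reproducible bit-for-bit from
#' config + seed.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results (`scans`,
#'   `precision`, `stats`, `paths`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...), "\n",
      sep = "", file = log_path, append = TRUE
    )
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED (%s)", name, conditionMessage(e))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  dat <- stage("gaze_io", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      scenes <- lapply(seq_len(sim$n_images %||% 1), function(i) {
        make_search_scene(
          seed = derive_seed(config$seed, 100, i),
          image_id = paste0("img", i)
        )
      })
      cc <- cohort_config(n_per_group = sim$n_per_group %||% 25)
      if (!is.null(sim$seq_median)) cc$len_meanlog <- log(sim$seq_median)
      cohort <- simulate_cohort(scenes, config = cc, seed = config$seed)
      list(
        fixations = cohort$fixations, touches = cohort$touches,
        task_times = cohort$task_times,
        aois = setNames(
          lapply(scenes, function(s) s$aois),
          vapply(scenes, function(s) s$aois$image_id, character(1))
        )
      )
    } else {
      list(
        fixations = read_fixations(config$fixations),
        touches = if (!is.null(config$touches)) {
          readr::read_csv(config$touches, show_col_types = FALSE)
        },
        task_times = NULL,
        aois = read_aois(config$aois)
      )
    }
  })
  rep <- validate_gaze_data(dat$fixations, dat$aois)
  logf(
    "validation: %d issue(s), %d group(s)", nrow(rep$issues),
    nrow(rep$group_counts)
  )

  scans <- stage("state_selection", {
    fit_group_scans(dat$fixations,
      n_min = config$n_min, n_max = config$n_max,
      restarts = config$restarts, base_seed = config$seed,
      extra_restarts = config$extra_restarts,
      covariance_kind = config$covariance_kind
    )
  })
  scan_report <- purrr::map_dfr(scans$scan, tidy)
  readr::write_csv(scan_report, file.path(out_dir, "scan_report.csv"))

  prec <- stage("aoi_precision", {
    purrr::pmap(scans, function(group, image_id, scan) {
      fit <- select_model(scan)
      fx <- dplyr::filter(
        dat$fixations, .data$group == !!group,
        .data$image_id == !!image_id
      )
      asg <- classify_fixations(fx, fit,
        mode = if (config$decode_mode == "viterbi") "viterbi" else "posterior"
      )
      aoi <- dat$aois[[image_id]]
      om <- overlap_matrix(asg, aoi, n_states = fit$model$n_states)
      lk <- link_states(om)
      write_hmm(fit$model, file.path(out_dir, paste0(
        "model_", group, "_", image_id, ".json"
      )))
      list(
        group_table = precision_scores(asg, lk, aoi),
        subject_table = if (config$per_subject) {
          precision_scores(asg, lk, aoi, per_subject = TRUE)
        },
        assignment = asg, aoi = aoi
      )
    })
  })
  precision <- purrr::map_dfr(prec, "group_table")
  readr::write_csv(precision, file.path(out_dir, "precision.csv"))
  precision_subject <- purrr::map_dfr(prec, "subject_table")
  if (nrow(precision_subject) > 0) {
    readr::write_csv(
      precision_subject,
      file.path(out_dir, "precision_subject.csv")
    )
  }

  stats_tbl <- stage("group_stats", {
    rows <- list()
    if (!is.null(dat$touches)) {
      found <- purrr::map_dfr(names(dat$aois), function(img) {
        score_touches(dat$touches, dat$aois[[img]])
      }) |>
        dplyr::inner_join(
          dplyr::distinct(dat$fixations, .data$subject_id, .data$group),
          by = "subject_id"
        ) |>
        dplyr::group_by(.data$subject_id, .data$group) |>
        dplyr::summarise(targets = sum(.data$targets_found), .groups = "drop")
      wt <- welch_t_data(found, "targets", "group")
      rows$targets <- tibble::tibble(
        test = "welch_t_targets_found",
        statistic = wt$statistic, df = wt$df, p.value = wt$p.value
      )
    }
    if (isTRUE(config$anova) && !is.null(precision_subject) &&
      nrow(precision_subject) > 0) {
      ps <- precision_subject |>
        dplyr::mutate(
          kind = substr(.data$aoi_label, 1, 1),
          position = substr(.data$aoi_label, 2, 2)
        )
      n_img <- dplyr::n_distinct(ps$image_id)
      for (k in c("P", "T")) {
        pk <- dplyr::filter(ps, .data$kind == k)
        an <- tryCatch(
          {
            if (n_img > 1) {
              mixed_anova(pk, "precision_percent", "subject_id", "group",
                "position",
                within2 = "image_id"
              )
            } else {
              mixed_anova(pk, "precision_percent", "subject_id", "group",
                "position")
            }
          },
          error = function(e) NULL
        )
        if (!is.null(an)) {
          eff <- dplyr::filter(an, !is.na(.data$statistic))
          rows[[paste0("anova_", k)]] <- tibble::tibble(
            test = paste0("anova_", tolower(k), "_", gsub(":", "_x_", eff$term)),
            statistic = eff$statistic, df = eff$df, p.value = eff$p.value
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(stats_tbl) > 0) {
    readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
  }

  if (isTRUE(config$figures)) {
    stage("viz_reports", {
      for (p in prec) {
        asg <- p$assignment
        grids <- state_density_map(
          asg, c(p$aoi$canvas_width, p$aoi$canvas_height),
          grid_step = 16
        )
        render_overlays(grids, p$aoi, file.path(
          out_dir, "figures",
          paste0(asg$group[1], "_", p$aoi$image_id)
        ))
      }
    })
  }

  manifest <- list(
    package = "gazehmm",
    version = as.character(packageVersion("gazehmm")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_fixations = nrow(dat$fixations),
    groups = sort(unique(dat$fixations$group)),
    images = sort(unique(dat$fixations$image_id))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  logf("pipeline complete")
  invisible(list(
    scans = scans, precision = precision,
    precision_subject = precision_subject, stats = stats_tbl,
    validation = rep, out_dir = out_dir
  ))
}

#' Write a simulated dataset to disk
#'
#' Generates a seeded synthetic dataset (scenes, cohort scanpaths, touches)
#' and writes the standard artefacts: fixation CSV, AOI JSON, touches CSV,
#' task-times CSV and a manifest recording the configuration and seed.
#'
#' @param dir Output directory.
#' @param n_images Number of synthetic stimuli.
#' @param cohort A [cohort_config()].
#' @param seed Master seed.
#' @return Invisibly, the list of written paths.
#' @export
simulate_dataset <- function(dir, n_images = 1, cohort = cohort_config(),
                             seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scenes <- lapply(seq_len(n_images), function(i) {
    make_search_scene(seed = derive_seed(seed, 100, i), image_id = paste0("img", i))
  })
  ch <- simulate_cohort(scenes, config = cohort, seed = seed)
  paths <- list(
    fixations = file.path(dir, "fixations.csv"),
    aois = file.path(dir, "aois.json"),
    touches = file.path(dir, "touches.csv"),
    task_times = file.path(dir, "task_times.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_fixations(ch$fixations, paths$fixations)
  write_aois(lapply(scenes, function(s) s$aois), paths$aois)
  readr::write_csv(ch$touches, paths$touches)
  readr::write_csv(ch$task_times, paths$task_times)
  jsonlite::write_json(
    list(
      package = "gazehmm",
      version = as.character(packageVersion("gazehmm")),
      seed = seed, n_images = n_images, cohort = unclass(cohort)
    ),
    paths$manifest,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(paths)
}
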