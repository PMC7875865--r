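#' Kernel density grid of fixations
#'
#' Gaussian product-kernel density of fixation coordinates evaluated on a
#' regular grid over the canvas, normalised to sum to one whenever any
#' fixation contributes. Used per hidden state ([state_density_map()]) to
#' draw the 2D contour maps of the decoded states, or pooled
#' ([fixation_heatmap()]) as a conventional heatmap.
#'
#' @param x,y Fixation coordinates (pixels).
#' @param canvas Length-2 canvas size (width, height).
#' @param bandwidth Gaussian kernel SD in pixels.
#' @param grid_step Grid cell size in pixels.
#' @param weights Optional non-negative kernel weights (e.g. durations).
#' @return A `density_grid`: list with matrix `grid` (rows = y, columns =
#'   x), cell-centre coordinates `xs`, `ys`, the `bandwidth` and an
#'   `empty` flag (all-zero grid from zero fixations).
#' @export
density_grid <- function(x, y, canvas, bandwidth = 30, grid_step = 4,
                         weights = NULL) {
  xs <- seq(grid_step / 2, canvas[1], by = grid_step)
  ys <- seq(grid_step / 2, canvas[2], by = grid_step)
  g <- matrix(0, nrow = length(ys), ncol = length(xs))
  if (length(x) > 0) {
    w <- weights %||% rep(1, length(x))
    for (i in seq_along(x)) {
      # separable Gaussian kernel: outer product of the axis profiles
      g <- g + w[i] * outer(dnorm(ys, y[i], bandwidth), dnorm(xs, x[i], bandwidth))
    }
    tot <- sum(g)
    if (tot > 0) g <- g / tot
  }
  structure(
    list(
      grid = g, xs = xs, ys = ys, bandwidth = bandwidth,
      grid_step = grid_step, empty = length(x) == 0
    ),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid> ", nrow(x$grid), "x", ncol(x$grid), " cells, bandwidth ",
    x$bandwidth, " px", if (x$empty) " (empty)", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.density_grid <- function(x, ...) {
  xs <- rep(x$xs, each = length(x$ys))
  ys <- rep(x$ys, times = length(x$xs))
  dens <- as.numeric(x$grid)
  tibble::tibble(x = xs, y = ys, density = dens)
}

#' Per-state 2D density maps
#'
#' One kernel density grid per hidden state, each built from the fixations
#' assigned to that state and normalised per state. States with no
#' fixations yield an all-zero grid flagged empty.
#'
#' @param assignment Output of [classify_fixations()] (columns `x_px`,
#'   `y_px`, `state`).
#' @param canvas Length-2 canvas size.
#' @param bandwidth,grid_step Kernel parameters in pixels.
#' @param n_states Number of states (defaults to the largest index seen).
#' @return Named list of [density_grid()] objects, `"state_1"` ...
#' @export
state_density_map <- function(assignment, canvas, bandwidth = 30,
                              grid_step = 4,
                              n_states = max(assignment$state)) {
  grids <- lapply(seq_len(n_states), function(s) {
    sel <- assignment$state == s
    density_grid(assignment$x_px[sel], assignment$y_px[sel], canvas,
      bandwidth = bandwidth, grid_step = grid_step
    )
  })
  names(grids) <- paste0("state_", seq_len(n_states))
  grids
}

#' Pooled fixation heatmap
#'
#' @param fixations Fixation tibble.
#' @param canvas Length-2 canvas size.
#' @param bandwidth,grid_step Kernel parameters in pixels.
#' @param weight_by_duration Weight each fixation's kernel by its duration
#'   (longer fixations contribute more, as in circle-size heatmaps).
#' @return A [density_grid()].
#' @export
fixation_heatmap <- function(fixations, canvas, bandwidth = 30,
                             grid_step = 4, weight_by_duration = FALSE) {
  w <- if (weight_by_duration) fixations$duration_ms else NULL
  density_grid(fixations$x_px, fixations$y_px, canvas,
    bandwidth = bandwidth, grid_step = grid_step, weights = w
  )
}

#' Plot a density grid
#'
#' @param object A `density_grid`.
#' @param aoiset Optional [aoi_set()] whose region outlines are overlaid.
#' @param ... Unused.
#' @return A ggplot (raster of the density, y-axis flipped to screen
#'   convention, AOI outlines on top).
#' @export
autoplot.density_grid <- function(object, aoiset = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (!is.null(aoiset)) {
    poly <- purrr::map_dfr(seq_len(nrow(aoiset$regions)), function(i) {
      p0 <- aoiset$regions$polygon[[i]]
      tibble::tibble(
        label = aoiset$regions$label[i],
        x = p0[, 1], y = p0[, 2]
      )
    })
    p <- p + ggplot2::geom_polygon(
      data = poly,
      ggplot2::aes(.data$x, .data$y, group = .data$label),
      inherit.aes = FALSE, fill = NA, colour = "white", linewidth = 0.4
    )
  }
  p
}

#' Render per-state density overlays to PNG files
#'
#' Writes one PNG per state grid: the density raster with the AOI outlines,
#' titled by state (empty states marked "(empty)"). Rendering never alters
#' the numeric grids.
#'
#' @param grids Named list from [state_density_map()] (or a single
#'   `density_grid`).
#' @param aoiset The image's [aoi_set()].
#' @param dir Output directory (created if needed).
#' @param width,height,dpi Device size (inches) and resolution.
#' @return Character vector of written file paths, invisibly.
#' @export
render_overlays <- function(grids, aoiset, dir, width = 7, height = 4.5,
                            dpi = 96) {
  if (inherits(grids, "density_grid")) grids <- list(density = grids)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(grids)) {
    g <- grids[[nm]]
    ttl <- if (g$empty) paste0(nm, " (empty)") else nm
    p <- autoplot(g, aoiset = aoiset) + ggplot2::ggtitle(ttl)
    path <- file.path(dir, paste0(nm, ".png"))
    ggplot2::ggsave(path, p,
      width = width, height = height, dpi = dpi,
      device = grDevices::png, type = "cairo"
    )
    paths <- c(paths, path)
  }
  invisible(paths)
}
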