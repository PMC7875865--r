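#' Construct a labelled AOI set for one image
#'
#' An AOI set holds the canvas size of one stimulus image plus its labelled
#' polygonal regions: three primes (`P1`-`P3`, the detail cues shown in the
#' right-hand band) and three targets (`T1`-`T3`, their occurrences inside
#' the image), optionally plus named distractor regions. Image area covered
#' by no region is white space (`WS`).
#'
#' @param image_id Image identifier.
#' @param canvas_width,canvas_height Canvas size in pixels.
#' @param regions A tibble/data frame with columns `label` (character),
#'   `polygon` (list of two-column vertex matrices) and `center` (list of
#'   length-2 numeric vectors; for targets, the touch-scoring centre). The
#'   centre defaults to the polygon's vertex centroid when `NULL`.
#' @return An object of class `aoi_set`.
#' @export
aoi_set <- function(image_id, canvas_width, canvas_height, regions) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("label", "polygon") %in% names(regions)))
  if (!"center" %in% names(regions)) regions$center <- list(NULL)
  regions$polygon <- lapply(regions$polygon, function(p) {
    p <- matrix(as.numeric(as.matrix(p)), ncol = 2)
    if (nrow(p) < 3) abort("an AOI polygon needs at least 3 vertices")
    p
  })
  regions$center <- lapply(seq_len(nrow(regions)), function(i) {
    c0 <- regions$center[[i]]
    if (is.null(c0) || length(c0) == 0 || any(is.na(c0))) {
      colMeans(regions$polygon[[i]])
    } else {
      as.numeric(c0)
    }
  })
  x <- structure(
    list(
      image_id = image_id, canvas_width = canvas_width,
      canvas_height = canvas_height, regions = regions
    ),
    class = "aoi_set"
  )
  validate_aoi_set(x)
  x
}

validate_aoi_set <- function(x) {
  r <- x$regions
  if (anyDuplicated(r$label) > 0) abort("AOI labels must be unique within an image")
  for (i in seq_len(nrow(r))) {
    p <- r$polygon[[i]]
    if (polygon_area(p) <= 0) {
      abort(paste0("AOI '", r$label[i], "' has zero area"))
    }
    if (any(p[, 1] < 0 | p[, 1] > x$canvas_width |
      p[, 2] < 0 | p[, 2] > x$canvas_height)) {
      abort(paste0(
        "bounds error: AOI '", r$label[i],
        "' has a vertex outside the canvas"
      ))
    }
  }
  core <- which(r$label %in% aoi_labels())
  if (length(core) > 1) {
    for (i in core) {
      for (j in core[core > i]) {
        if (polygons_overlap(r$polygon[[i]], r$polygon[[j]])) {
          abort(paste0(
            "integrity error: AOIs '", r$label[i], "' and '",
            r$label[j], "' overlap"
          ))
        }
      }
    }
  }
  invisible(x)
}

aoi_labels <- function() c("P1", "P2", "P3", "T1", "T2", "T3")

#' @export
print.aoi_set <- function(x, ...) {
  cat("<aoi_set> image '", x$image_id, "', canvas ", x$canvas_width, "x",
    x$canvas_height, ", ", nrow(x$regions), " region(s): ",
    paste(x$regions$label, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read / write AOI definitions as JSON
#'
#' The JSON document is either one object
#' `{image_id, canvas: [w, h], regions: [{label, polygon: [[x, y], ...],
#' center: [x, y]}, ...]}` or an array of such objects (one per image).
#' Vertex coordinates survive a round trip bit-exactly.
#'
#' @param path JSON file path.
#' @return `read_aois` returns a named list of `aoi_set` objects (single
#'   object input still yields a length-1 list); `write_aois` returns
#'   `path` invisibly.
#' @export
read_aois <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(doc$image_id)) doc <- list(doc)
  sets <- lapply(doc, function(o) {
    regions <- tibble::tibble(
      label = vapply(o$regions, function(r) r$label, character(1)),
      polygon = lapply(o$regions, function(r) {
        do.call(rbind, lapply(r$polygon, function(v) as.numeric(unlist(v))))
      }),
      center = lapply(o$regions, function(r) {
        as.numeric(unlist(r$center))
      })
    )
    aoi_set(
      image_id = o$image_id, canvas_width = as.numeric(o$canvas[[1]]),
      canvas_height = as.numeric(o$canvas[[2]]), regions = regions
    )
  })
  names(sets) <- vapply(sets, function(a) a$image_id, character(1))
  sets
}

#' @param aoisets A single `aoi_set` or a list of them.
#' @rdname read_aois
#' @export
write_aois <- function(aoisets, path) {
  if (inherits(aoisets, "aoi_set")) aoisets <- list(aoisets)
  doc <- lapply(aoisets, function(a) {
    list(
      image_id = a$image_id,
      canvas = c(a$canvas_width, a$canvas_height),
      regions = lapply(seq_len(nrow(a$regions)), function(i) {
        p <- a$regions$polygon[[i]]
        list(
          label = a$regions$label[i],
          polygon = lapply(seq_len(nrow(p)), function(v) p[v, ]),
          center = a$regions$center[[i]]
        )
      })
    )
  })
  jsonlite::write_json(unname(doc), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Label points by containing AOI
#'
#' Maps pixel coordinates to the label of the containing region, or `"WS"`
#' (white space) when no region contains the point. Membership uses the
#' even-odd rule with boundary points counting as inside; regions are tested
#' in their stored order, so the first containing region wins (prime/target
#' regions are disjoint by construction).
#'
#' @param x,y Numeric vectors of pixel coordinates.
#' @param aoiset An `aoi_set`.
#' @return Character vector of labels.
#' @export
aoi_label_of <- function(x, y, aoiset) {
  stopifnot(inherits(aoiset, "aoi_set"), length(x) == length(y))
  if (any(x < 0 | x > aoiset$canvas_width | y < 0 | y > aoiset$canvas_height)) {
    abort("bounds error: point outside canvas")
  }
  lab <- rep("WS", length(x))
  todo <- rep(TRUE, length(x))
  for (i in seq_len(nrow(aoiset$regions))) {
    if (!any(todo)) break
    hit <- todo
    hit[todo] <- point_in_polygon(x[todo], y[todo], aoiset$regions$polygon[[i]])
    lab[hit] <- aoiset$regions$label[i]
    todo <- todo & !hit
  }
  lab
}
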