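#' Segment fluorescent objects in a reference image
#'
#' Global threshold (Otsu's method by default, or a fixed value), followed
#' by 8-connected component labelling and removal of objects below
#' `min_area` pixels. Labels are contiguous from 1 in raster order of each
#' object's first pixel; 0 is background.
#'
#' @param image 2-D numeric matrix (a single grayscale frame, typically the
#'   frame of complete on-switching).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value, required for `method = "fixed"`.
#' @param min_area Minimum object area, pixels.
#' @return An object of class `object_map`: list with the label matrix
#'   `labels`, `n_objects`, per-object `areas` and `centroids` (0-based
#'   row/col, row-major convention) and the `threshold` used. An image with
#'   no above-threshold pixels yields an empty map with a warning, not an
#'   error.
#' @export
segment_objects <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL, min_area = 1L) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  min_area <- check_count(min_area, "min_area")
  if (method == "fixed") {
    if (is.null(threshold)) stop("`threshold` is required for method = \"fixed\"",
                                 call. = FALSE)
  } else {
    rng <- range(image)
    if (diff(rng) == 0) {
      threshold <- rng[1]  # flat image: nothing exceeds the threshold
    } else {
      scaled <- (image - rng[1]) / diff(rng)
      threshold <- rng[1] +
        diff(rng) * EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    }
  }
  mask <- image > threshold
  if (!any(mask)) {
    warning("no pixels above threshold: returning an empty object map")
    return(structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                          n_objects = 0L, areas = integer(0),
                          centroids = matrix(numeric(0), 0, 2),
                          threshold = threshold),
                     class = "object_map"))
  }
  labels <- label_components8(mask)
  # drop small objects, relabel contiguously
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_area)
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  labels[labels > 0] <- remap[labels[labels > 0]]
  n_obj <- length(keep)
  areas <- tab[keep]
  centroids <- matrix(0, n_obj, 2)
  if (n_obj > 0) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    centroids[, 1] <- tapply(idx[, 1] - 1, lab, mean)
    centroids[, 2] <- tapply(idx[, 2] - 1, lab, mean)
  }
  structure(list(labels = labels, n_objects = n_obj, areas = areas,
                 centroids = centroids, threshold = threshold),
            class = "object_map")
}

# 8-connected component labelling of a logical mask via the pixel adjacency
# graph (vertices = foreground pixels; edges to the W/NW/N/NE neighbours)
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0) return(matrix(0L, nr, nc))
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  edges <- NULL
  for (d in list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- vid[nb] > 0L
    if (any(has)) {
      edges <- rbind(edges, cbind(vid[fg[ok]][has], vid[nb][has]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel by raster order of first occurrence
  relab <- match(comp, unique(comp))
  out <- matrix(0L, nr, nc)
  out[fg] <- relab
  out
}

#' @export
print.object_map <- function(x, ...) {
  cat(sprintf("Object map: %d object(s) (threshold %.4g)\n",
              x$n_objects, x$threshold))
  invisible(x)
}

#' Extract per-object fluorescence traces from an image stack
#'
#' For each labelled object, the trace is the mean pixel intensity inside
#' the object per frame, optionally background-subtracted using the
#' per-frame median of unlabelled pixels. The population mean trace (mean
#' over objects) is normalised to the point of complete on-switching — the
#' last frame of the first on-illumination block.
#'
#' @param stack Numeric array (rows x cols x frames).
#' @param objects An [segment_objects()] `object_map` from the same
#'   geometry.
#' @param protocol The [switching_protocol()] the stack was acquired under;
#'   its frame count must match the stack.
#' @param background_subtract Subtract the per-frame median of non-object
#'   pixels (default `TRUE`; if there are no background pixels the
#'   subtraction is 0).
#' @return A `switch_experiment` whose `traces` hold the raw
#'   (background-subtracted, un-normalised) per-object traces, with the
#'   normalised population `mean_trace` and `normalization_frame_index`.
#' @export
extract_traces <- function(stack, objects, protocol,
                           background_subtract = TRUE) {
  stopifnot(inherits(objects, "object_map"),
            inherits(protocol, "switching_protocol"))
  d <- dim(stack)
  if (length(d) != 3 || d[1] != nrow(objects$labels) ||
      d[2] != ncol(objects$labels)) {
    stop("stack geometry does not match the object map", call. = FALSE)
  }
  if (d[3] != n_frames(protocol)) {
    stop("stack frame count does not match the protocol", call. = FALSE)
  }
  if (objects$n_objects == 0) {
    stop("object map is empty; nothing to extract", call. = FALSE)
  }
  labv <- as.integer(objects$labels)
  bg_px <- labv == 0L
  n_obj <- objects$n_objects
  traces <- matrix(0, d[3], n_obj)
  for (f in seq_len(d[3])) {
    frame <- as.numeric(stack[, , f])
    bg <- if (background_subtract && any(bg_px)) {
      stats::median(frame[bg_px])
    } else 0
    means <- tapply(frame[!bg_px], labv[!bg_px], mean)
    traces[f, ] <- means[as.character(seq_len(n_obj))] - bg
  }
  schedule <- frame_schedule(protocol)
  df <- data.frame(
    frame = rep(schedule$frame, n_obj),
    time_s = rep(schedule$time_s, n_obj),
    cycle = rep(schedule$cycle, n_obj),
    half_cycle = rep(schedule$half_cycle, n_obj),
    illumination = rep(schedule$illumination, n_obj),
    object_id = rep(seq_len(n_obj), each = d[3]),
    intensity = as.numeric(traces),
    stringsAsFactors = FALSE)
  out <- new_switch_experiment(protocol, df)
  out$object_map <- objects
  out
}

#' Average maximum object brightness
#'
#' Per-object maximum fluorescence over all frames, and their mean — the
#' colony brightness statistic (the per-colony maximum is preferred over the
#' per-colony mean because it is insensitive to how generously the
#' threshold outlines each colony).
#'
#' @param experiment A `switch_experiment` with at least one object. Maxima
#'   are taken over the raw (un-normalised) traces.
#' @return List with `mean_max` and the per-object table `per_object`
#'   (`object_id`, `max_intensity`).
#' @export
object_brightness <- function(experiment) {
  stopifnot(inherits(experiment, "switch_experiment"))
  if (experiment$n_objects < 1) stop("no objects in experiment", call. = FALSE)
  mx <- tapply(experiment$traces$intensity, experiment$traces$object_id, max)
  list(mean_max = mean(mx),
       per_object = data.frame(object_id = as.integer(names(mx)),
                               max_intensity = as.numeric(mx)))
}
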