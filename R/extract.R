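#' Parameters for particle extraction from a predicted mask
#'
#' @param binarize_threshold mask value at or above which a pixel is
#'   foreground (default 0.5, the midpoint of the generator output range).
#' @param connectivity pixel adjacency, 4 or 8 (default 8).
#' @param min_area_px components smaller than this are discarded (default 4,
#'   suppressing single-pixel generator noise).
#' @param n_groups number of size groups for [cluster_sizes()] (default 2).
#' @param pixel_size_nm pixel size used for the equivalent-circle diameter
#'   estimate.
#' @return an `extraction_params` list.
#' @export
extraction_params <- function(binarize_threshold = 0.5, connectivity = 8L,
                              min_area_px = 4L, n_groups = 2L,
                              pixel_size_nm = 1.11) {
  stopifnot(connectivity %in% c(4L, 8L), min_area_px >= 0, n_groups >= 1,
            pixel_size_nm > 0)
  structure(list(binarize_threshold = binarize_threshold,
                 connectivity = as.integer(connectivity),
                 min_area_px = as.integer(min_area_px),
                 n_groups = as.integer(n_groups),
                 pixel_size_nm = pixel_size_nm),
            class = "extraction_params")
}

#' Binarize a mask
#'
#' @param mask numeric matrix.
#' @param threshold pixels with value `>= threshold` become foreground.
#' @return logical matrix.
#' @export
binarize <- function(mask, threshold) {
  as_plain_matrix(unclass(mask)) >= threshold
}

#' Label connected components of a binary mask
#'
#' Foreground pixels are partitioned into maximal connected sets under 4- or
#' 8-adjacency. Labels are 1..n in order of first encounter in a row-major
#' raster scan, so the labeling is deterministic.
#'
#' @param binary logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background), with attribute
#'   `n_components`.
#' @export
connected_components <- function(binary, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  b <- as_plain_matrix(unclass(binary)) != 0
  lab <- cpp_label_components(b, as.integer(connectivity))
  attr(lab, "n_components") <- max(lab)
  lab
}

#' Centroid and area of each labeled component
#'
#' The centroid is the unweighted mean of member pixel coordinates (0-based,
#' `x_px` = column, `y_px` = row); the area is the member count.
#'
#' @param labels integer label matrix from [connected_components()].
#' @return data frame with `label`, `x_px`, `y_px`, `area_px`, ordered by
#'   label.
#' @export
component_stats <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0)))
  lab <- labels[idx]
  H <- nrow(labels)
  rows0 <- (idx - 1L) %% H
  cols0 <- (idx - 1L) %/% H
  x <- tapply(cols0, lab, mean)
  y <- tapply(rows0, lab, mean)
  a <- tapply(rows0, lab, length)
  ord <- order(as.integer(names(x)))
  data.frame(label = as.integer(names(x))[ord],
             x_px = as.numeric(x)[ord], y_px = as.numeric(y)[ord],
             area_px = as.integer(a)[ord])
}

#' Optimal one-dimensional clustering of particle areas into size groups
#'
#' Exact 1-D k-means on `sqrt(area)` (the length scale of a particle) via
#' the dynamic-programming optimal-partition algorithm, so the grouping is
#' deterministic and globally optimal in within-group sum of squares.
#' Groups are relabeled 0..k-1 in ascending mean-area order.
#'
#' @param areas vector of positive areas (length >= `n_groups`).
#' @param n_groups number of groups (>= 1).
#' @return list with `assignment` (0-based group per input area) and
#'   `group_mean_area` (mean raw area per group, ascending).
#' @export
cluster_sizes <- function(areas, n_groups = 2L) {
  n <- length(areas)
  stopifnot(n_groups >= 1)
  if (n < n_groups)
    stop("need at least n_groups (", n_groups, ") areas, got ", n)
  if (any(areas <= 0)) stop("areas must be positive")
  v <- sqrt(areas)
  ord <- order(v)
  s <- v[ord]
  k <- as.integer(n_groups)
  # DP over sorted values: optimal clusters are contiguous runs.
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  sse <- function(i, j) {        # within-SSE of s[i..j]
    su <- cs[j] - if (i > 1) cs[i - 1] else 0
    sq <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    sq - su^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)          # start index of last cluster
  for (j in seq_len(n)) { D[1, j] <- sse(1, j); B[1, j] <- 1L }
  if (k > 1) {
    for (g in 2:k) {
      for (j in g:n) {
        best <- Inf; barg <- g
        for (i in g:j) {
          val <- D[g - 1, i - 1] + sse(i, j)
          if (val < best) { best <- val; barg <- i }
        }
        D[g, j] <- best; B[g, j] <- barg
      }
    }
  }
  bounds <- integer(k + 1L)          # cluster g spans bounds[g] .. bounds[g+1]-1
  bounds[k + 1L] <- n + 1L
  j <- n
  for (g in k:1) { bounds[g] <- B[g, j]; j <- bounds[g] - 1L }
  grp_sorted <- integer(n)
  for (g in seq_len(k))
    grp_sorted[bounds[g]:(bounds[g + 1L] - 1L)] <- g - 1L
  assignment <- integer(n)
  assignment[ord] <- grp_sorted
  means <- vapply(0:(k - 1L), function(g) mean(areas[assignment == g]),
                  numeric(1))
  list(assignment = assignment, group_mean_area = means)
}

#' Extract particle records from a predicted mask
#'
#' Binarize, label connected components, measure centroid and area, drop
#' components below `min_area_px`, and cluster the surviving areas into
#' size groups. The estimated diameter uses the equivalent-circle formula
#' `2 * sqrt(area / pi) * pixel_size_nm` (masks are squares, so this is a
#' size index for group separation rather than a calibrated diameter).
#'
#' @param mask numeric mask matrix (e.g. from [detect_image()] or a target
#'   mask).
#' @param params an [extraction_params()] list.
#' @return data frame of particle records sorted by (`y_px`, `x_px`):
#'   `x_px`, `y_px`, `area_px`, `group` (0-based, ascending mean area),
#'   `diameter_nm_est`. Zero surviving components yield an empty frame.
#' @export
extract_particles <- function(mask, params = extraction_params()) {
  stopifnot(inherits(params, "extraction_params"))
  b <- binarize(mask, params$binarize_threshold)
  lab <- connected_components(b, params$connectivity)
  st <- component_stats(lab)
  st <- st[st$area_px >= params$min_area_px, , drop = FALSE]
  if (nrow(st) == 0L)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0), group = integer(0),
                      diameter_nm_est = numeric(0)))
  ng <- min(params$n_groups, nrow(st))
  cl <- cluster_sizes(st$area_px, ng)
  out <- data.frame(x_px = st$x_px, y_px = st$y_px, area_px = st$area_px,
                    group = cl$assignment,
                    diameter_nm_est = 2 * sqrt(st$area_px / pi) *
                      params$pixel_size_nm)
  out <- out[order(out$y_px, out$x_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}
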