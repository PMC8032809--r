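#' Parameters for the threshold-area-circularity baseline
#'
#' The classical fixed-parameter detector the network is compared against:
#' a global gray threshold (particles are electron-dense, i.e. dark, so
#' pixels `<= gray_threshold` are candidate foreground), per-size-class
#' area bands, and a roundness cut.
#'
#' When `area_bands` is omitted it is derived from nominal particle
#' diameters as `[0.5x, 2x]` the equivalent-disk pixel area of each size
#' class.
#'
#' @param gray_threshold intensity threshold in `[0, 1]`.
#' @param area_bands two-column matrix (or list of length-2 vectors), one
#'   row per size class: inclusive `[min, max]` component area in px^2.
#'   Bands must not overlap.
#' @param circularity_min minimal [circularity()] in `(0, 1]`.
#' @param diameters_nm,pixel_size_nm used to derive `area_bands` when not
#'   given.
#' @return a `tac_params` list.
#' @export
tac_params <- function(gray_threshold = 0.3, area_bands = NULL,
                       circularity_min = 0.6, diameters_nm = c(6, 12),
                       pixel_size_nm = 1.11) {
  if (is.null(area_bands)) {
    a <- pi * (diameters_nm / pixel_size_nm / 2)^2
    area_bands <- cbind(ceiling(0.5 * a), floor(2 * a))
  }
  if (is.list(area_bands)) area_bands <- do.call(rbind, area_bands)
  area_bands <- matrix(as.numeric(area_bands), ncol = 2L)
  stopifnot(gray_threshold >= 0, gray_threshold <= 1,
            circularity_min > 0, circularity_min <= 1,
            all(area_bands[, 1] < area_bands[, 2]))
  ord <- order(area_bands[, 1])
  area_bands <- area_bands[ord, , drop = FALSE]
  if (nrow(area_bands) > 1 &&
      any(area_bands[-1, 1] <= area_bands[-nrow(area_bands), 2]))
    stop("area bands must not overlap")
  structure(list(gray_threshold = gray_threshold, area_bands = area_bands,
                 circularity_min = circularity_min),
            class = "tac_params")
}

#' Circularity (roundness) of a pixel component
#'
#' `4 * pi * area / perimeter^2`, clipped to `[0, 1]`, with the perimeter
#' measured as the length of the closed boundary-following polygon through
#' boundary pixel centers (Moore tracing). A perfect disk scores near 1,
#' elongated shapes much less. A single-pixel component is defined as 1.
#'
#' @param component logical (or 0/1) matrix containing one connected
#'   component, or an integer label matrix together with `label`.
#' @param label when `component` is a label matrix, which label to measure.
#' @return circularity in `[0, 1]`.
#' @export
circularity <- function(component, label = NULL) {
  m <- as_plain_matrix(unclass(component))
  b <- if (is.null(label)) m != 0 else m == label
  area <- sum(b)
  if (area == 0) stop("empty component")
  if (area == 1) return(1.0)
  per <- cpp_trace_perimeter(b)
  if (!is.finite(per) || per <= 0) return(1.0)
  min(1, 4 * pi * area / per^2)
}

#' Threshold-area-circularity particle detection
#'
#' Thresholds the image (dark-object convention), labels connected
#' components, and keeps components whose area falls inside one of the
#' area bands and whose circularity reaches `circularity_min`. The group of
#' a record is the index of its area band (0-based, ascending band order),
#' i.e. the size class.
#'
#' @param image matrix or [image_plane()] with values in `[0, 1]`.
#' @param params a [tac_params()] list.
#' @param connectivity component adjacency (default 8).
#' @return data frame of particle records sorted by (`y_px`, `x_px`), same
#'   columns as [extract_particles()].
#' @export
tac_detect <- function(image, params = tac_params(), connectivity = 8L) {
  stopifnot(inherits(params, "tac_params"))
  m <- as_plain_matrix(unclass(image))
  ps <- pixel_size_nm(image)
  b <- m <= params$gray_threshold
  lab <- connected_components(b, connectivity)
  st <- component_stats(lab)
  if (nrow(st) == 0L)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0), group = integer(0),
                      diameter_nm_est = numeric(0)))
  band_of <- rep(NA_integer_, nrow(st))
  for (k in seq_len(nrow(params$area_bands)))
    band_of[st$area_px >= params$area_bands[k, 1] &
            st$area_px <= params$area_bands[k, 2]] <- k - 1L
  keep <- which(!is.na(band_of))
  keep <- keep[vapply(keep, function(i)
    circularity(lab, st$label[i]) >= params$circularity_min, logical(1))]
  st <- st[keep, , drop = FALSE]
  out <- data.frame(x_px = st$x_px, y_px = st$y_px, area_px = st$area_px,
                    group = band_of[keep],
                    diameter_nm_est = 2 * sqrt(st$area_px / pi) * ps)
  out <- out[order(out$y_px, out$x_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}
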