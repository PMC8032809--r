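#' Plan square windows covering an image
#'
#' Windows are `tile_px` x `tile_px`, laid out row-major with stride
#' `tile_px - overlap_px`. When the image exceeds one tile, the final
#' row/column of windows is shifted inward so it abuts the image edge
#' (end-anchored, no padding); when the image is smaller than one tile in a
#' dimension the single window extends past the edge and is filled by
#' reflection at extraction time. With `overlap_px = 0` every pixel is
#' covered exactly once.
#'
#' @param height,width image size in pixels (>= 1).
#' @param tile_px window side (default 256).
#' @param overlap_px overlap between adjacent windows (< `tile_px`).
#' @return a `tile_plan`: list with the image size, tile size, overlap and a
#'   data frame `windows` of 0-based half-open spans
#'   (`row0`, `col0`, `row1`, `col1`).
#' @export
plan_tiles <- function(height, width, tile_px = 256L, overlap_px = 0L) {
  stopifnot(height >= 1, width >= 1, tile_px >= 1, overlap_px >= 0)
  if (overlap_px >= tile_px) stop("overlap_px must be smaller than tile_px")
  stride <- tile_px - overlap_px
  starts_1d <- function(n) {
    if (n <= tile_px) return(0L)
    s <- seq.int(0L, n - tile_px, by = stride)
    if (tail_1(s) + tile_px < n) s <- c(s, n - tile_px)
    s
  }
  r0 <- starts_1d(height)
  c0 <- starts_1d(width)
  grid <- expand.grid(col0 = c0, row0 = r0)      # row-major ordering
  windows <- data.frame(row0 = grid$row0, col0 = grid$col0,
                        row1 = grid$row0 + tile_px, col1 = grid$col0 + tile_px)
  structure(list(height = as.integer(height), width = as.integer(width),
                 tile_px = as.integer(tile_px),
                 overlap_px = as.integer(overlap_px),
                 windows = windows, padding = "reflect"),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> %d x %d px; %d window(s) of %d px, overlap %d\n",
              x$height, x$width, nrow(x$windows), x$tile_px, x$overlap_px))
  invisible(x)
}

# Symmetric reflection of 0-based indices into [0, n).
reflect_index <- function(t, n) {
  m <- ((t %% (2 * n)) + 2 * n) %% (2 * n)
  ifelse(m < n, m, 2 * n - 1 - m)
}

#' Extract one padded tile from an image
#'
#' @param image matrix or [image_plane()].
#' @param plan a [plan_tiles()] result matching the image dimensions.
#' @param i window index (1-based, row-major).
#' @return a `tile_px` x `tile_px` matrix; parts outside the image are
#'   filled by symmetric reflection.
#' @export
get_tile <- function(image, plan, i) {
  m <- as_plain_matrix(unclass(image))
  check_plan(m, plan)
  w <- plan$windows[i, ]
  rows <- reflect_index(w$row0:(w$row1 - 1L), nrow(m)) + 1L
  cols <- reflect_index(w$col0:(w$col1 - 1L), ncol(m)) + 1L
  m[rows, cols, drop = FALSE]
}

check_plan <- function(m, plan) {
  stopifnot(inherits(plan, "tile_plan"))
  if (nrow(m) != plan$height || ncol(m) != plan$width)
    stop("tile plan is for ", plan$height, " x ", plan$width,
         " px but image is ", nrow(m), " x ", ncol(m), " px")
  invisible(TRUE)
}

#' Split an image into padded tiles
#'
#' Convenience wrapper returning all tiles of a plan as a list (suitable for
#' small images and tests). [detect_image()] processes windows one at a
#' time instead, so only one tile and the output mask are ever resident.
#'
#' @inheritParams get_tile
#' @return list of `tile_px` x `tile_px` matrices, row-major window order.
#' @export
split_tiles <- function(image, plan) {
  lapply(seq_len(nrow(plan$windows)), function(i) get_tile(image, plan, i))
}

#' Run a tile detector over a whole image and stitch the mask
#'
#' Applies the model to every window of the plan and combines overlapping
#' predictions by per-pixel maximum, which makes the result independent of
#' the window processing order. The default overlap of 32 px (about twice
#' the largest expected particle footprint at 1.11 nm/px) ensures a
#' particle split by one window boundary is seen whole in a neighboring
#' window.
#'
#' @param model a fitted [goldnet()] model, or any function
#'   `function(tile) -> mask matrix` (useful for testing).
#' @param image matrix or [image_plane()] of arbitrary size.
#' @param plan optional [plan_tiles()] result; computed from the model's
#'   tile size with `overlap_px` when omitted.
#' @param overlap_px overlap used when `plan` is omitted.
#' @return full-size mask matrix in the original image frame.
#' @export
detect_image <- function(model, image, plan = NULL, overlap_px = 32L) {
  m <- as_plain_matrix(unclass(image))
  predict_fun <- if (is.function(model)) model else {
    stopifnot(inherits(model, "goldnet"))
    function(tile) predict(model, tile)
  }
  if (is.null(plan)) {
    tile_px <- if (is.function(model)) 256L else model$tile_px
    plan <- plan_tiles(nrow(m), ncol(m), tile_px,
                       min(overlap_px, tile_px - 1L))
  }
  check_plan(m, plan)
  if (!is.function(model) && plan$tile_px != model$tile_px)
    stop("plan tile size (", plan$tile_px,
         ") does not match model tile size (", model$tile_px, ")")
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(plan$windows))) {
    tile <- get_tile(m, plan, i)
    pred <- tryCatch(predict_fun(tile), error = function(e)
      stop("tile ", i, " (", paste(unlist(plan$windows[i, ]), collapse = ","),
           "): ", conditionMessage(e)))
    w <- plan$windows[i, ]
    vr <- w$row0:min(w$row1 - 1L, nrow(m) - 1L)
    vc <- w$col0:min(w$col1 - 1L, ncol(m) - 1L)
    sub <- pred[vr - w$row0 + 1L, vc - w$col0 + 1L, drop = FALSE]
    out[vr + 1L, vc + 1L] <- pmax(out[vr + 1L, vc + 1L], sub)
  }
  stopifnot(all(is.finite(out)))   # coverage: every pixel written >= once
  out
}
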