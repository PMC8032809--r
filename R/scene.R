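#' Specification of a synthetic freeze-fracture-replica scene
#'
#' Describes one simulated electron micrograph: dark quasi-circular gold
#' particles of one or more nominal diameters on a smooth uneven background
#' with directional shadow streaks, optional blur and additive noise. The
#' simulator exists so that every downstream stage (training, tiling,
#' extraction, evaluation) is testable with exact ground truth.
#'
#' `particle_intensity` is the gray level of a particle core expressed as a
#' fraction of the local background, i.e. particles darken the background
#' multiplicatively. This makes particle gray track background unevenness,
#' which is what defeats a single global threshold on real replicas.
#'
#' @param height_px,width_px raster size in pixels.
#' @param pixel_size_nm physical pixel size (nm/pixel; default 1.11).
#' @param particle_diameters_nm nominal particle diameters in nm.
#' @param counts_per_diameter number of particles per diameter (aligned with
#'   `particle_diameters_nm`).
#' @param particle_intensity particle core gray as a fraction of local
#'   background, in `[0, 1]` (0 = black).
#' @param background_mean mean background gray in `[0, 1]`.
#' @param gradient_amplitude amplitude of the slow background unevenness
#'   (peak-to-trough roughly 1.5x this value).
#' @param shadow_count number of directional shadow streaks.
#' @param shadow_intensity maximal darkening of a streak (subtractive).
#' @param shadow_angle_deg dominant streak direction (degrees; individual
#'   streaks jitter around it).
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param blur_sigma_px Gaussian blur applied after rendering (pixels).
#' @param min_separation_px minimal center-to-center distance between
#'   particles; default 2x the largest particle pixel diameter, which keeps
#'   ground-truth-to-detection matching unambiguous.
#' @param allow_overlap if `TRUE`, the separation constraint is ignored.
#' @param mask_scale side of the square target mask relative to the particle
#'   pixel diameter (default 1).
#' @return a `scene_spec` object (a validated list).
#' @export
scene_spec <- function(height_px = 256L, width_px = 256L, pixel_size_nm = 1.11,
                       particle_diameters_nm = c(6, 12),
                       counts_per_diameter = c(3L, 3L),
                       particle_intensity = 0.25, background_mean = 0.55,
                       gradient_amplitude = 0.15, shadow_count = 2L,
                       shadow_intensity = 0.18, shadow_angle_deg = 35,
                       noise_sigma = 0.03, blur_sigma_px = 0.6,
                       min_separation_px = NULL, allow_overlap = FALSE,
                       mask_scale = 1.0) {
  stopifnot(height_px >= 1, width_px >= 1, pixel_size_nm > 0,
            all(particle_diameters_nm > 0), all(counts_per_diameter >= 0),
            particle_intensity >= 0, particle_intensity <= 1,
            background_mean >= 0, background_mean <= 1,
            gradient_amplitude >= 0, shadow_count >= 0, shadow_intensity >= 0,
            noise_sigma >= 0, blur_sigma_px >= 0, mask_scale > 0)
  if (length(counts_per_diameter) != length(particle_diameters_nm))
    stop("counts_per_diameter must align with particle_diameters_nm")
  d_px <- particle_diameters_nm / pixel_size_nm
  if (is.null(min_separation_px)) min_separation_px <- 2 * max(d_px)
  stopifnot(min_separation_px >= 0)
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    pixel_size_nm = pixel_size_nm,
    particle_diameters_nm = particle_diameters_nm,
    counts_per_diameter = as.integer(counts_per_diameter),
    particle_intensity = particle_intensity,
    background_mean = background_mean,
    gradient_amplitude = gradient_amplitude,
    shadow_count = as.integer(shadow_count),
    shadow_intensity = shadow_intensity,
    shadow_angle_deg = shadow_angle_deg,
    noise_sigma = noise_sigma, blur_sigma_px = blur_sigma_px,
    min_separation_px = min_separation_px,
    allow_overlap = isTRUE(allow_overlap), mask_scale = mask_scale
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px @ %.3g nm/px; particles %s nm (counts %s)\n",
              x$height_px, x$width_px, x$pixel_size_nm,
              paste(x$particle_diameters_nm, collapse = "/"),
              paste(x$counts_per_diameter, collapse = "/")))
  invisible(x)
}

empty_truth <- function() {
  data.frame(x_px = numeric(0), y_px = numeric(0), diameter_nm = numeric(0))
}

# Rejection-sample particle centers with an edge margin large enough that
# both the disk footprint and the square mask stay inside the raster.
place_particles <- function(spec) {
  n_total <- sum(spec$counts_per_diameter)
  if (n_total == 0L) return(empty_truth())
  d_px <- spec$particle_diameters_nm / spec$pixel_size_nm
  side_max <- max(1, round(spec$mask_scale * max(d_px)))
  margin <- max(ceiling(max(d_px) / 2), ceiling(side_max / 2)) + 1
  if (spec$width_px - 1 - 2 * margin <= 0 || spec$height_px - 1 - 2 * margin <= 0)
    stop("scene too small for the requested particle sizes")
  diam <- rep(spec$particle_diameters_nm, spec$counts_per_diameter)
  xs <- numeric(0); ys <- numeric(0)
  max_attempts <- 300L * n_total
  attempts <- 0L
  for (i in seq_len(n_total)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("scene too crowded: could not place ", n_total,
             " particles with min_separation_px = ",
             signif(spec$min_separation_px, 4))
      x <- runif(1, margin, spec$width_px - 1 - margin)
      y <- runif(1, margin, spec$height_px - 1 - margin)
      ok <- spec$allow_overlap || length(xs) == 0L ||
        all((xs - x)^2 + (ys - y)^2 >= spec$min_separation_px^2)
      if (ok) { xs <- c(xs, x); ys <- c(ys, y); break }
    }
  }
  data.frame(x_px = xs, y_px = ys, diameter_nm = diam)
}

# Background field: mean + directional ramp + one broad blob, minus shadows.
render_background <- function(spec) {
  H <- spec$height_px; W <- spec$width_px
  X <- matrix(0:(W - 1), H, W, byrow = TRUE)
  Y <- matrix(0:(H - 1), H, W)
  bg <- matrix(spec$background_mean, H, W)
  if (spec$gradient_amplitude > 0) {
    th <- runif(1, 0, 2 * pi)
    u <- X * cos(th) + Y * sin(th)
    u <- (u - min(u)) / max(1e-12, diff(range(u))) - 0.5
    cx <- runif(1, 0, W - 1); cy <- runif(1, 0, H - 1)
    sg <- 0.5 * max(H, W)
    blob <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
    bg <- bg + spec$gradient_amplitude * (u + sample(c(-0.5, 0.5), 1) * blob)
  }
  if (spec$shadow_count > 0 && spec$shadow_intensity > 0) {
    for (s in seq_len(spec$shadow_count)) {
      ang <- (spec$shadow_angle_deg + runif(1, -15, 15)) * pi / 180
      px <- runif(1, 0, W - 1); py <- runif(1, 0, H - 1)
      w <- runif(1, 2, 6)
      depth <- spec$shadow_intensity * runif(1, 0.6, 1)
      d <- -(X - px) * sin(ang) + (Y - py) * cos(ang)
      bg <- bg - depth * exp(-d^2 / (2 * w^2))
    }
  }
  bg
}

# Anti-aliased disk coverage, then multiplicative darkening of the local
# background toward particle_intensity * background.
render_particles_onto <- function(img, truth, spec) {
  if (nrow(truth) == 0L) return(img)
  H <- nrow(img); W <- ncol(img)
  for (i in seq_len(nrow(truth))) {
    r <- truth$diameter_nm[i] / spec$pixel_size_nm / 2
    x0 <- truth$x_px[i]; y0 <- truth$y_px[i]
    rr <- ceiling(r + 1.5)
    i0 <- max(0, floor(y0) - rr); i1 <- min(H - 1, ceiling(y0) + rr)
    j0 <- max(0, floor(x0) - rr); j1 <- min(W - 1, ceiling(x0) + rr)
    ii <- i0:i1; jj <- j0:j1
    dist <- sqrt(outer((ii - y0)^2, (jj - x0)^2, "+"))
    alpha <- pmin(pmax(r + 0.5 - dist, 0), 1)
    sub <- img[ii + 1, jj + 1, drop = FALSE]
    img[ii + 1, jj + 1] <- sub * (1 - alpha * (1 - spec$particle_intensity))
  }
  img
}

#' Render one synthetic scene with ground truth and its target mask
#'
#' Deterministic for a fixed `(spec, seed)`. Particles are placed by
#' rejection sampling under the spec's separation constraint; an explicit
#' error is raised when the scene is too crowded to place all particles.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a `rendered_pair`: list with `input` (an [image_plane()]),
#'   `mask` (numeric 0/1 matrix of the square-mask targets), and `truth`
#'   (data frame `x_px`, `y_px`, `diameter_nm`; 0-based sub-pixel centers).
#' @export
render_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, function() {
    truth <- place_particles(spec)
    img <- render_background(spec)
    img <- render_particles_onto(img, truth, spec)
    if (spec$blur_sigma_px > 0) img <- gaussian_blur(img, spec$blur_sigma_px)
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
    img <- pmin(pmax(img, 0), 1)
    mask <- render_target_mask(truth, spec$height_px, spec$width_px,
                               spec$pixel_size_nm, spec$mask_scale)
    structure(list(input = image_plane(img, spec$pixel_size_nm),
                   mask = mask, truth = truth, spec = spec, seed = seed),
              class = "rendered_pair")
  })
}

#' @export
print.rendered_pair <- function(x, ...) {
  cat(sprintf("<rendered_pair> %d x %d px, %d particle(s), seed %s\n",
              nrow(x$input), ncol(x$input), nrow(x$truth),
              format(x$seed)))
  invisible(x)
}

#' Render the square-mask training target for a set of particles
#'
#' Each particle contributes an axis-aligned square of foreground (value 1)
#' centered on its rounded center; the side is `mask_scale` times the
#' particle pixel diameter (rounded, at least 1). Overlapping squares merge
#' into their union.
#'
#' @param truth data frame with `x_px`, `y_px`, `diameter_nm` (0-based).
#' @param height_px,width_px raster size.
#' @param pixel_size_nm pixel size in nm/pixel.
#' @param mask_scale square side relative to particle pixel diameter.
#' @return numeric 0/1 matrix of size `height_px` x `width_px`.
#' @export
render_target_mask <- function(truth, height_px, width_px, pixel_size_nm = 1.11,
                               mask_scale = 1.0) {
  stopifnot(mask_scale > 0, height_px >= 1, width_px >= 1)
  mask <- matrix(0, height_px, width_px)
  if (is.null(truth) || nrow(truth) == 0L) return(mask)
  cx <- round(truth$x_px); cy <- round(truth$y_px)
  if (any(cx < 0 | cx >= width_px | cy < 0 | cy >= height_px))
    stop("particle center outside raster")
  for (i in seq_len(nrow(truth))) {
    side <- max(1L, round(mask_scale * truth$diameter_nm[i] / pixel_size_nm))
    r0 <- cy[i] - side %/% 2L
    c0 <- cx[i] - side %/% 2L
    rows <- max(0L, r0):min(height_px - 1L, r0 + side - 1L)
    cols <- max(0L, c0):min(width_px - 1L, c0 + side - 1L)
    mask[rows + 1L, cols + 1L] <- 1
  }
  mask
}

#' Generate a dataset of paired scenes, balanced in empty tiles
#'
#' A fraction `empty_fraction` of the pairs (default 0.5, i.e. equal numbers
#' of tiles with and without particles) is rendered with zero particles;
#' which pairs are empty, and each pair's seed, are derived
#' deterministically from `seed`.
#'
#' @param spec_template a [scene_spec()] used for every pair.
#' @param n_pairs number of pairs (>= 1).
#' @param empty_fraction fraction of particle-free pairs in `[0, 1]`.
#' @param seed integer seed.
#' @return list of `rendered_pair` objects.
#' @export
make_dataset <- function(spec_template, n_pairs, empty_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(spec_template, "scene_spec"), n_pairs >= 1,
            empty_fraction >= 0, empty_fraction <= 1)
  n_empty <- round(empty_fraction * n_pairs)
  if (n_empty < n_pairs && sum(spec_template$counts_per_diameter) == 0L)
    stop("spec_template has zero particle counts but empty_fraction < 1")
  empty_idx <- with_seed(derive_seed(seed, 0L), function()
    sample(n_pairs, n_empty))
  lapply(seq_len(n_pairs), function(i) {
    sp <- spec_template
    if (i %in% empty_idx) {
      sp$counts_per_diameter <- rep(0L, length(sp$counts_per_diameter))
      class(sp) <- "scene_spec"
    }
    render_scene(sp, seed = derive_seed(seed, i))
  })
}

bilinear_resize <- function(m, H2, W2) {
  H1 <- nrow(m); W1 <- ncol(m)
  sy <- H2 / H1; sx <- W2 / W1
  src_i <- pmin(pmax(((0:(H2 - 1)) + 0.5) / sy - 0.5, 0), H1 - 1)
  src_j <- pmin(pmax(((0:(W2 - 1)) + 0.5) / sx - 0.5, 0), W1 - 1)
  i0 <- pmin(floor(src_i), H1 - 1); fi <- src_i - i0
  j0 <- pmin(floor(src_j), W1 - 1); fj <- src_j - j0
  i1 <- pmin(i0 + 1, H1 - 1); j1 <- pmin(j0 + 1, W1 - 1)
  a <- m[i0 + 1, j0 + 1, drop = FALSE] * ((1 - fi) %o% (1 - fj)) +
       m[i1 + 1, j0 + 1, drop = FALSE] * (fi %o% (1 - fj)) +
       m[i0 + 1, j1 + 1, drop = FALSE] * ((1 - fi) %o% fj) +
       m[i1 + 1, j1 + 1, drop = FALSE] * (fi %o% fj)
  a
}

#' Rescale a rendered pair to emulate a different magnification
#'
#' Image, mask and truth coordinates are rescaled consistently; particle
#' diameters are unchanged in nm while their pixel footprints scale, i.e.
#' the effective pixel size is divided by `scale` (a 2x upscale of a
#' 1.11 nm/px scene emulates 0.55 nm/px imaging).
#'
#' @param pair a `rendered_pair`.
#' @param scale magnification factor (> 0).
#' @return a `rendered_pair` at the new scale.
#' @export
faux_magnification <- function(pair, scale) {
  stopifnot(inherits(pair, "rendered_pair"), scale > 0)
  H1 <- nrow(pair$input); W1 <- ncol(pair$input)
  H2 <- round(H1 * scale); W2 <- round(W1 * scale)
  if (H2 < 1 || W2 < 1) stop("faux_magnification: output smaller than 1 px")
  ps <- pixel_size_nm(pair$input) * H1 / H2   # == /scale up to rounding
  img2 <- bilinear_resize(as_plain_matrix(unclass(pair$input)), H2, W2)
  mask2 <- (bilinear_resize(pair$mask, H2, W2) >= 0.5) * 1
  truth2 <- pair$truth
  if (nrow(truth2) > 0) {
    truth2$x_px <- (truth2$x_px + 0.5) * (W2 / W1) - 0.5
    truth2$y_px <- (truth2$y_px + 0.5) * (H2 / H1) - 0.5
  }
  sp <- pair$spec
  if (!is.null(sp)) {
    sp$height_px <- H2; sp$width_px <- W2; sp$pixel_size_nm <- ps
  }
  structure(list(input = image_plane(img2, ps), mask = mask2, truth = truth2,
                 spec = sp, seed = pair$seed),
            class = "rendered_pair")
}

#' Write a dataset of rendered pairs to a directory
#'
#' Per scene: a 16-bit TIFF input (`scene_<i>.tif`), a PNG mask
#' (`scene_<i>_mask.png`) and a ground-truth CSV (`scene_<i>_truth.csv`
#' with header `x_px,y_px,diameter_nm`).
#'
#' @param pairs list of `rendered_pair` objects.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    stem <- file.path(dir, sprintf("scene_%03d", i))
    write_image(p$input, paste0(stem, ".tif"))
    write_image(p$mask, paste0(stem, "_mask.png"))
    utils::write.csv(p$truth, paste0(stem, "_truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}
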