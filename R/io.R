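#' Particle table with provenance
#'
#' Wraps a particle record frame (see [extract_particles()]) together with
#' the image identifier, pixel size and detector provenance, for CSV
#' export.
#'
#' @param records data frame with `x_px`, `y_px`, `area_px`, `group`,
#'   `diameter_nm_est` (0-based pixel coordinates).
#' @param image_id identifier of the source image.
#' @param pixel_size_nm pixel size in nm/pixel.
#' @param detector `"cgan"` or `"tac"`.
#' @param params_digest short string identifying the detector parameters.
#' @return a `particle_table`.
#' @export
particle_table <- function(records, image_id = "", pixel_size_nm = 1.11,
                           detector = c("cgan", "tac"), params_digest = "") {
  detector <- match.arg(detector)
  need <- c("x_px", "y_px", "area_px", "group", "diameter_nm_est")
  stopifnot(all(need %in% names(records)))
  records <- records[order(records$y_px, records$x_px), need, drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, image_id = image_id,
                 pixel_size_nm = pixel_size_nm, detector = detector,
                 params_digest = params_digest),
            class = "particle_table")
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("<particle_table> %d record(s), detector %s, %.3g nm/px, image '%s'\n",
              nrow(x$records), x$detector, x$pixel_size_nm, x$image_id))
  invisible(x)
}

fmt_records <- function(records) {
  data.frame(x_px = sprintf("%.2f", records$x_px),
             y_px = sprintf("%.2f", records$y_px),
             area_px = as.integer(records$area_px),
             group = as.integer(records$group),
             diameter_nm_est = sprintf("%.3f", records$diameter_nm_est))
}

write_one_csv <- function(tab, records, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    sprintf("# image_id: %s", tab$image_id),
    sprintf("# pixel_size_nm: %.6g", tab$pixel_size_nm),
    sprintf("# detector: %s", tab$detector),
    sprintf("# params: %s", tab$params_digest),
    "# coordinates are 0-based pixel positions (x = column, y = row)"
  ), con)
  utils::write.table(fmt_records(records), con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Write particle records to CSV
#'
#' The layout is plain CSV with header
#' `x_px,y_px,area_px,group,diameter_nm_est` preceded by `#`-prefixed
#' provenance lines (image id, pixel size, detector, parameter digest).
#' Centroids are written with 2 decimals, areas as integers, diameters with
#' 3 decimals; coordinates are 0-based. With `split_by_group` one file per
#' size group is written, suffixed `_g<k>`.
#'
#' @param table a [particle_table()].
#' @param path output CSV path.
#' @param split_by_group write one file per group instead of one file.
#' @return character vector of the path(s) written, invisibly.
#' @export
write_particle_csv <- function(table, path, split_by_group = FALSE) {
  stopifnot(inherits(table, "particle_table"))
  if (!split_by_group) {
    write_one_csv(table, table$records, path)
    return(invisible(path))
  }
  groups <- sort(unique(table$records$group))
  stem <- sub("\\.csv$", "", path)
  paths <- character(0)
  for (g in groups) {
    p <- sprintf("%s_g%d.csv", stem, g)
    write_one_csv(table, table$records[table$records$group == g, , drop = FALSE], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a particle CSV written by [write_particle_csv()]
#'
#' @param path CSV path.
#' @return a [particle_table()]; malformed headers or rows raise an error
#'   with the offending line number.
#' @export
read_particle_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body_at <- which(!grepl("^#", lines))
  if (length(body_at) == 0L) stop("no header line in ", path)
  hdr_line <- body_at[1]
  header <- strsplit(lines[hdr_line], ",", fixed = TRUE)[[1]]
  need <- c("x_px", "y_px", "area_px", "group", "diameter_nm_est")
  if (!identical(header, need))
    stop("malformed header at line ", hdr_line, " of ", path,
         " (expected '", paste(need, collapse = ","), "')")
  get_meta <- function(key, default = "") {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else default
  }
  rows <- lines[-seq_len(hdr_line)]
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0L) {
    recs <- data.frame(x_px = numeric(0), y_px = numeric(0),
                       area_px = integer(0), group = integer(0),
                       diameter_nm_est = numeric(0))
  } else {
    parts <- strsplit(rows, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 5L)
    if (length(bad))
      stop("malformed row at line ", hdr_line + bad[1], " of ", path)
    m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
    num <- suppressWarnings(apply(m, 2L, as.numeric))
    num <- matrix(num, ncol = 5L)
    if (anyNA(num)) {
      bad <- which(apply(num, 1L, anyNA))[1]
      stop("non-numeric value at line ", hdr_line + bad, " of ", path)
    }
    recs <- data.frame(x_px = num[, 1], y_px = num[, 2],
                       area_px = as.integer(num[, 3]),
                       group = as.integer(num[, 4]),
                       diameter_nm_est = num[, 5])
  }
  particle_table(recs, image_id = get_meta("image_id"),
                 pixel_size_nm = as.numeric(get_meta("pixel_size_nm", "1.11")),
                 detector = get_meta("detector", "cgan"),
                 params_digest = get_meta("params"))
}

group_colors <- function(n) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#FF7F00", "#984EA3", "#FFFF33")
  rep(base, length.out = max(1L, n))
}

#' Overlay particle markers on a grayscale image
#'
#' Returns (and optionally writes as PNG) an RGB copy of the image with a
#' colored cross per record, one color per size group; gray values outside
#' the markers are untouched. Records whose center falls outside the image
#' are skipped with a warning.
#'
#' @param image matrix or [image_plane()] in `[0, 1]`.
#' @param table a [particle_table()] or plain record frame.
#' @param path optional PNG output path.
#' @param marker_radius cross half-length in pixels.
#' @return H x W x 3 RGB array, invisibly `path` attached as attribute when
#'   written.
#' @export
render_overlay <- function(image, table, path = NULL, marker_radius = 3L) {
  m <- pmin(pmax(as_plain_matrix(unclass(image)), 0), 1)
  recs <- if (inherits(table, "particle_table")) table$records else table
  H <- nrow(m); W <- ncol(m)
  rgb <- array(rep(m, 3L), dim = c(H, W, 3L))
  if (nrow(recs) > 0) {
    cols <- group_colors(max(recs$group) + 1L)
    for (i in seq_len(nrow(recs))) {
      cx <- round(recs$x_px[i]); cy <- round(recs$y_px[i])
      if (cx < 0 || cx >= W || cy < 0 || cy >= H) {
        warning("record ", i, " outside image, skipped")
        next
      }
      rgbcol <- grDevices::col2rgb(cols[recs$group[i] + 1L]) / 255
      rr <- (cy - marker_radius):(cy + marker_radius)
      rr <- rr[rr >= 0 & rr < H]
      cc <- (cx - marker_radius):(cx + marker_radius)
      cc <- cc[cc >= 0 & cc < W]
      for (ch in 1:3) {
        rgb[rr + 1L, cx + 1L, ch] <- rgbcol[ch]
        rgb[cy + 1L, cc + 1L, ch] <- rgbcol[ch]
      }
    }
  }
  if (!is.null(path)) png::writePNG(rgb, path)
  invisible(rgb)
}
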