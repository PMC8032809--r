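#' Match detections to ground truth by optimal assignment
#'
#' One-to-one minimum-total-distance assignment between truth and detection
#' centers, restricted to pairs closer than `max_dist_px` (solved exactly
#' with the Hungarian algorithm, never greedily: among all maximum-
#' cardinality matchings within the radius, the one with minimal total
#' distance is returned). When a region-of-interest mask is supplied,
#' truth and detections outside it are excluded before matching.
#'
#' @param truth data frame with `x_px`, `y_px` (0-based centers).
#' @param detections data frame with `x_px`, `y_px`.
#' @param max_dist_px matching radius in pixels (> 0).
#' @param roi optional logical/0-1 matrix; points whose rounded position
#'   falls on a false/0 pixel (or outside the raster) are excluded.
#' @return a `match_result`: `pairs` (data frame `truth_idx`, `det_idx`,
#'   `dist_px`, indices into the input frames), `unmatched_truth`,
#'   `unmatched_detections`, `n_truth` / `n_detections` in scope, and
#'   `max_dist_px`.
#' @export
match_detections <- function(truth, detections, max_dist_px, roi = NULL) {
  stopifnot(max_dist_px > 0)
  t_idx <- seq_len(nrow(truth))
  d_idx <- seq_len(nrow(detections))
  if (!is.null(roi)) {
    r <- as_plain_matrix(unclass(roi)) != 0
    inside <- function(df, i) {
      ri <- round(df$y_px[i]) + 1L; ci <- round(df$x_px[i]) + 1L
      ri >= 1 && ri <= nrow(r) && ci >= 1 && ci <= ncol(r) && r[ri, ci]
    }
    t_idx <- t_idx[vapply(t_idx, function(i) inside(truth, i), logical(1))]
    d_idx <- d_idx[vapply(d_idx, function(i) inside(detections, i), logical(1))]
  }
  nt <- length(t_idx); nd <- length(d_idx)
  empty_pairs <- data.frame(truth_idx = integer(0), det_idx = integer(0),
                            dist_px = numeric(0))
  if (nt == 0L || nd == 0L) {
    return(structure(list(pairs = empty_pairs, unmatched_truth = t_idx,
                          unmatched_detections = d_idx, n_truth = nt,
                          n_detections = nd, max_dist_px = max_dist_px),
                     class = "match_result"))
  }
  dx <- outer(truth$x_px[t_idx], detections$x_px[d_idx], "-")
  dy <- outer(truth$y_px[t_idx], detections$y_px[d_idx], "-")
  dist <- sqrt(dx^2 + dy^2)
  big <- max_dist_px * min(nt, nd) + 1     # > any feasible total distance
  n <- max(nt, nd)
  cost <- matrix(big, n, n)
  feas <- dist <= max_dist_px
  cost[seq_len(nt), seq_len(nd)][feas] <- dist[feas]
  assign_col <- cpp_hungarian(cost)
  pr <- empty_pairs
  matched_t <- logical(nt); matched_d <- logical(nd)
  for (i in seq_len(nt)) {
    j <- assign_col[i]
    if (j <= nd && feas[i, j]) {
      pr <- rbind(pr, data.frame(truth_idx = t_idx[i], det_idx = d_idx[j],
                                 dist_px = dist[i, j]))
      matched_t[i] <- TRUE; matched_d[j] <- TRUE
    }
  }
  structure(list(pairs = pr, unmatched_truth = t_idx[!matched_t],
                 unmatched_detections = d_idx[!matched_d],
                 n_truth = nt, n_detections = nd,
                 max_dist_px = max_dist_px),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched, %d missed truth, %d false positives (radius %.3g px)\n",
              nrow(x$pairs), length(x$unmatched_truth),
              length(x$unmatched_detections), x$max_dist_px))
  invisible(x)
}

#' Detection accuracy
#'
#' True positives divided by the total number of ground-truth particles in
#' scope (false positives are reported separately and do not enter).
#'
#' @param match a [match_detections()] result with at least one truth
#'   particle in scope.
#' @return accuracy in `[0, 1]`.
#' @export
detection_accuracy <- function(match) {
  stopifnot(inherits(match, "match_result"))
  total <- nrow(match$pairs) + length(match$unmatched_truth)
  if (total == 0L) stop("accuracy undefined: no ground-truth particles in scope")
  nrow(match$pairs) / total
}

#' Center root-mean-square error of matched pairs
#'
#' @param match a [match_detections()] result with at least one matched
#'   pair.
#' @param groups optional vector of group labels, one per matched pair (in
#'   `match$pairs` order), for a per-group breakdown.
#' @return overall RMSE in pixels, or (with `groups`) a list with
#'   `overall` and `per_group`.
#' @export
center_rmse <- function(match, groups = NULL) {
  stopifnot(inherits(match, "match_result"))
  d <- match$pairs$dist_px
  if (length(d) == 0L) stop("RMSE undefined: no matched pairs")
  overall <- sqrt(mean(d^2))
  if (is.null(groups)) return(overall)
  stopifnot(length(groups) == length(d))
  per <- vapply(sort(unique(groups)),
                function(g) sqrt(mean(d[groups == g]^2)), numeric(1))
  names(per) <- sort(unique(groups))
  list(overall = overall, per_group = per)
}

#' Size-group confusion of matched pairs
#'
#' Rows are true nominal diameters, columns assigned size groups; entries
#' count matched pairs. A perfect two-size recovery is diagonal.
#'
#' @param match a [match_detections()] result.
#' @param truth_diameters_nm vector of nominal diameters, one per truth row
#'   of the original truth frame.
#' @param detection_groups vector of group labels, one per detection row of
#'   the original detections frame.
#' @return contingency table with per-class recall as attribute `recall`.
#' @export
size_confusion <- function(match, truth_diameters_nm, detection_groups) {
  stopifnot(inherits(match, "match_result"))
  td <- truth_diameters_nm[match$pairs$truth_idx]
  dg <- detection_groups[match$pairs$det_idx]
  tab <- table(true_diameter_nm = factor(td, levels = sort(unique(truth_diameters_nm))),
               assigned_group = factor(dg, levels = sort(unique(detection_groups))))
  totals <- table(factor(truth_diameters_nm,
                         levels = sort(unique(truth_diameters_nm))))
  attr(tab, "recall") <- as.numeric(rowSums(tab)) / as.numeric(totals)
  tab
}

#' Summarize a detector run against ground truth
#'
#' Convenience wrapper producing accuracy, false-positive count, RMSE
#' (overall and per group) and the size confusion table, with writers for a
#' CSV and a human-readable text report.
#'
#' @param truth truth frame (`x_px`, `y_px`, `diameter_nm`).
#' @param detections detection frame (`x_px`, `y_px`, `group`, ...).
#' @param max_dist_px matching radius; default
#'   `max(2 * max(diameter_nm) / pixel_size_nm, 5)`.
#' @param roi optional region-of-interest mask (see [match_detections()]).
#' @param pixel_size_nm pixel size for the default radius.
#' @return an `evaluation_report` list.
#' @export
evaluation_report <- function(truth, detections, max_dist_px = NULL,
                              roi = NULL, pixel_size_nm = 1.11) {
  if (is.null(max_dist_px)) {
    max_dist_px <- if (nrow(truth) > 0)
      max(2 * max(truth$diameter_nm) / pixel_size_nm, 5) else 5
  }
  match <- match_detections(truth, detections, max_dist_px, roi)
  acc <- if (nrow(match$pairs) + length(match$unmatched_truth) > 0)
    detection_accuracy(match) else NA_real_
  rmse <- if (nrow(match$pairs) > 0) {
    if (!is.null(detections$group))
      center_rmse(match, groups = detections$group[match$pairs$det_idx])
    else list(overall = center_rmse(match), per_group = numeric(0))
  } else list(overall = NA_real_, per_group = numeric(0))
  if (is.numeric(rmse)) rmse <- list(overall = rmse, per_group = numeric(0))
  conf <- if (!is.null(truth$diameter_nm) && !is.null(detections$group) &&
              nrow(match$pairs) > 0)
    size_confusion(match, truth$diameter_nm, detections$group) else NULL
  structure(list(match = match, accuracy = acc,
                 false_positives = length(match$unmatched_detections),
                 rmse = rmse, confusion = conf,
                 max_dist_px = max_dist_px),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy: %s  (TP %d / truth %d; FP %d)\n",
              ifelse(is.na(x$accuracy), "NA", sprintf("%.3f", x$accuracy)),
              nrow(x$match$pairs),
              nrow(x$match$pairs) + length(x$match$unmatched_truth),
              x$false_positives))
  if (!is.na(x$rmse$overall))
    cat(sprintf("center RMSE: %.3f px\n", x$rmse$overall))
  if (length(x$rmse$per_group)) {
    cat("  per group:",
        paste(sprintf("g%s %.3f", names(x$rmse$per_group),
                      x$rmse$per_group), collapse = ", "), "\n")
  }
  if (!is.null(x$confusion)) {
    cat("size confusion (rows true nm, cols assigned group):\n")
    print(unclass(x$confusion))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' @param report an [evaluation_report()].
#' @param csv_path,txt_path optional output paths; `NULL` skips a writer.
#' @return the report, invisibly.
#' @export
write_evaluation <- function(report, csv_path = NULL, txt_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(csv_path)) {
    df <- data.frame(metric = c("accuracy", "true_positives", "missed",
                                "false_positives", "rmse_px"),
                     value = c(report$accuracy, nrow(report$match$pairs),
                               length(report$match$unmatched_truth),
                               report$false_positives, report$rmse$overall))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w"); on.exit(close(con))
    sink(con); print(report); sink()
  }
  invisible(report)
}
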