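#' Match detected footprints to ground truth
#'
#' Greedy nearest-neighbour matching in the plate mm frame: candidate
#' detection-truth pairs are processed in ascending distance order and
#' accepted while both sides are unmatched and the distance is within
#' `tol_mm`.  The bookkeeping mirrors a manual benchmark audit:
#' `detected_artifacts` are false detections sitting on a known artifact,
#' `multi_pick` counts surplus detections of an already-matched colony,
#' `group_as_single` counts detections whose mask covers two or more truth
#' centres, and `not_pickable` truths are excluded from the pickable
#' metrics.
#'
#' @param fps measured `colony_footprints` (crop-local centroids).
#' @param gt a `gt_plate` ground truth.
#' @param crop_origin origin of the crop in image px (`c(x0, y0)`); taken
#'   from `fps$segmap$crop_origin` by default.
#' @param tol_mm matching tolerance, mm (> 0); 1 mm is the picking-tolerance
#'   default.
#' @param scale_mm_per_px mm per px used to convert pixel distances.
#' @return object of class `match_result` with counts `TP`, `FP`, `FN`,
#'   `detected`, `picked`, `detected_artifacts`, `not_pickable`,
#'   `not_detected`, `multi_pick`, `group_as_single`, `total_truth`,
#'   `pickable_truth`.
#' @export
match_detections <- function(fps, gt,
                             crop_origin = fps$segmap$crop_origin,
                             tol_mm = 1,
                             scale_mm_per_px = gt$dish$scale_mm_per_px) {
  if (tol_mm <= 0) stop_ctx("tol_mm must be > 0")
  fp <- fps$footprints
  co <- gt$colonies
  nd <- nrow(fp); nt <- nrow(co)

  det_x <- fp$x + crop_origin[1] - 1
  det_y <- fp$y + crop_origin[2] - 1
  match_det <- rep(NA_integer_, nd)
  match_truth <- rep(NA_integer_, nt)
  if (nd > 0 && nt > 0) {
    dmat <- sqrt(outer(det_x, co$x_px, `-`)^2 +
                   outer(det_y, co$y_px, `-`)^2) * scale_mm_per_px
    cand <- which(dmat <= tol_mm, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (is.na(match_det[i]) && is.na(match_truth[j])) {
          match_det[i] <- j; match_truth[j] <- i
        }
      }
    }
  }

  pickable <- if (nt > 0) co$pickable else logical(0)
  TP <- sum(!is.na(match_truth) & pickable)
  matched_nonpick <- sum(!is.na(match_truth) & !pickable)
  FN <- sum(is.na(match_truth) & pickable)

  unmatched_det <- which(is.na(match_det))
  det_art <- 0L
  if (length(unmatched_det) > 0 && nrow(gt$artifacts) > 0) {
    ad <- sqrt(outer(det_x[unmatched_det], gt$artifacts$x_px, `-`)^2 +
                 outer(det_y[unmatched_det], gt$artifacts$y_px, `-`)^2) *
      scale_mm_per_px
    det_art <- sum(apply(ad <= tol_mm, 1, any))
  }
  multi_pick <- 0L
  if (length(unmatched_det) > 0 && nt > 0) {
    matched_j <- which(!is.na(match_truth))
    if (length(matched_j) > 0) {
      md <- sqrt(outer(det_x[unmatched_det], co$x_px[matched_j], `-`)^2 +
                   outer(det_y[unmatched_det], co$y_px[matched_j], `-`)^2) *
        scale_mm_per_px
      multi_pick <- sum(apply(md <= tol_mm, 1, any))
    }
  }
  FP <- length(unmatched_det)

  group_as_single <- 0L
  if (nt > 0 && !is.null(fps$labels)) {
    lx <- round(co$x_px - crop_origin[1] + 1)
    ly <- round(co$y_px - crop_origin[2] + 1)
    W <- dim(fps$labels)[1]; H <- dim(fps$labels)[2]
    ok <- lx >= 1 & lx <= W & ly >= 1 & ly <= H
    covering <- rep(0L, nt)
    covering[ok] <- fps$labels[cbind(lx[ok], ly[ok])]
    tab <- table(covering[covering > 0])
    group_as_single <- sum(tab >= 2)
  }

  structure(list(
    TP = TP, FP = FP, FN = FN,
    detected = nd, picked = sum(!is.na(match_det)),
    detected_artifacts = det_art,
    not_pickable = sum(!pickable),
    matched_not_pickable = matched_nonpick,
    not_detected = FN,
    multi_pick = multi_pick,
    group_as_single = group_as_single,
    total_truth = nt,
    pickable_truth = sum(pickable)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FP=%d FN=%d (of %d truths, %d pickable)\n",
              x$TP, x$FP, x$FN, x$total_truth, x$pickable_truth))
  invisible(x)
}

#' Pool match results over several plates
#'
#' Counts add, so metrics on the pooled result equal metrics on pooled
#' counts.
#'
#' @param results list of `match_result` objects.
#' @return a pooled `match_result`.
#' @export
pool_matches <- function(results) {
  keys <- names(results[[1]])
  out <- lapply(keys, function(k) sum(vapply(results, `[[`, numeric(1), k)))
  names(out) <- keys
  structure(out, class = "match_result")
}

#' Detection metrics from matched counts
#'
#' Detection-style metrics without true negatives: sensitivity
#' `TP / (TP + FN)`, precision `TP / (TP + FP)`, accuracy
#' `TP / (TP + FP + FN)` (a Jaccard-type score, hence always below both),
#' misclassification rate `1 - accuracy`, raw performance `TP / truths`
#' over all and over pickable truths.  Metrics with zero denominators are
#' reported as `NA`.
#'
#' @param m a `match_result` (single plate or pooled).
#' @return object of class `eval_report`, fractions in \[0, 1\].
#' @export
compute_metrics <- function(m) {
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- sdiv(m$TP, m$TP + m$FP + m$FN)
  structure(list(
    raw_performance_all = sdiv(m$TP, m$total_truth),
    raw_performance_pickable = sdiv(m$TP, m$pickable_truth),
    accuracy = acc,
    misclassification_rate = if (is.na(acc)) NA_real_ else 1 - acc,
    sensitivity = sdiv(m$TP, m$TP + m$FN),
    precision = sdiv(m$TP, m$TP + m$FP),
    counts = m
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("Colony detection evaluation\n")
  cat(sprintf("  raw performance (all truths):      %s\n", pc(x$raw_performance_all)))
  cat(sprintf("  raw performance (pickable):        %s\n", pc(x$raw_performance_pickable)))
  cat(sprintf("  accuracy:                          %s\n", pc(x$accuracy)))
  cat(sprintf("  misclassification rate:            %s\n", pc(x$misclassification_rate)))
  cat(sprintf("  sensitivity:                       %s\n", pc(x$sensitivity)))
  cat(sprintf("  precision:                         %s\n", pc(x$precision)))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  doc <- report[c("raw_performance_all", "raw_performance_pickable",
                  "accuracy", "misclassification_rate", "sensitivity",
                  "precision")]
  doc$counts <- unclass(report$counts)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
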