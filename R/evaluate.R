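## Segmentation-vs-truth evaluation helpers used by tests, the acceptance
## script and the analysis drivers.

#' Centroids of a label image
#'
#' @param labels integer label image.
#' @return `data.frame` `label`, `row`, `col`.
#' @export
label_centroids <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  do.call(rbind, lapply(ids, function(k) {
    px <- which(labels == k, arr.ind = TRUE)
    data.frame(label = k, row = mean(px[, 1]), col = mean(px[, 2]))
  }))
}

#' Object-level match of a segmentation against ground truth
#'
#' Greedy IoU matching: each truth object is paired with the found object
#' of maximal intersection-over-union; pairs with IoU at or above the
#' threshold are true positives.
#'
#' @param truth,found integer label images.
#' @param iou_threshold minimum IoU for a match.
#' @return List `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `matches` (`data.frame` truth/found/iou).
#' @export
match_objects <- function(truth, found, iou_threshold = 0.5) {
  t_ids <- setdiff(sort(unique(as.vector(truth))), 0)
  f_ids <- setdiff(sort(unique(as.vector(found))), 0)
  matches <- data.frame(truth = integer(0), found = integer(0),
                        iou = numeric(0))
  used_f <- integer(0)
  for (t in t_ids) {
    tm <- truth == t
    cand <- setdiff(unique(found[tm]), c(0, used_f))
    best <- 0; best_f <- NA
    for (f in cand) {
      fm <- found == f
      i <- sum(tm & fm)
      u <- sum(tm | fm)
      if (i / u > best) { best <- i / u; best_f <- f }
    }
    if (!is.na(best_f) && best >= iou_threshold) {
      matches <- rbind(matches,
                       data.frame(truth = t, found = best_f, iou = best))
      used_f <- c(used_f, best_f)
    }
  }
  tp <- nrow(matches)
  fp <- length(f_ids) - tp
  fn <- length(t_ids) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
            else NA_real_,
       matches = matches)
}

## boundary pixels of a label image (label change across 4-neighbours,
## restricted to foreground)
label_boundaries <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  b <- matrix(FALSE, nr, nc)
  dr <- labels[-1, ] != labels[-nr, ]
  dc <- labels[, -1] != labels[, -nc]
  b[-1, ][dr] <- TRUE; b[-nr, ][dr] <- TRUE
  b[, -1][dc] <- TRUE; b[, -nc][dc] <- TRUE
  b & labels > 0
}

#' Mean boundary distance between a found and a truth segmentation
#'
#' Mean distance from each boundary pixel of the found labels to the
#' nearest truth boundary pixel.
#'
#' @param found,truth integer label images.
#' @return Mean distance in px (`NA` if either has no boundary).
#' @export
boundary_distance <- function(found, truth) {
  fb <- label_boundaries(found)
  tb <- label_boundaries(truth)
  if (!any(fb) || !any(tb)) return(NA_real_)
  ## distance-to-truth-boundary transform: distmap of the complement
  d <- as.matrix(EBImage::distmap(EBImage::Image(!tb)))
  mean(d[fb])
}
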