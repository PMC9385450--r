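#' Jaccard index of two binary masks
#'
#' `|A & B| / |A | B|`, computed as an exact integer ratio; two empty
#' masks return 0 by convention.
#'
#' @param a,b logical (or 0/1) matrices of the same shape.
#' @return Numeric in `[0, 1]`.
#' @export
pairwise_ji <- function(a, b) {
  if (!all(dim(a) == dim(b))) .stop2("mask shapes differ")
  a <- a > 0; b <- b > 0
  inter <- sum(a & b)
  union <- sum(a) + sum(b) - inter
  if (union == 0) 0 else inter / union
}

#' Multi-object Jaccard evaluation of an instance segmentation
#'
#' Pairs every ground-truth (GT) object with the predicted object of
#' maximum overlap; a GT object whose best overlap covers less than
#' `min_overlap` of it scores 0 and stays unmatched, otherwise it scores
#' the pairwise Jaccard index with its match. The summary is the
#' arithmetic mean over GT objects. By default a predicted object may
#' match several GT objects (per-GT greedy pairing); the optional
#' one-to-one mode assigns predictions greedily by descending overlap so
#' each is used at most once.
#'
#' @param gt,pred integer label masks of the same shape (0 = background).
#' @param min_overlap overlap gate, default 0.5.
#' @param denominator overlap fraction denominator: `"gt"` (fraction of
#'   the GT object covered, default) or `"union"` (the Jaccard value
#'   itself).
#' @param matching `"per_gt"` (default) or `"one_to_one"`.
#' @return List of class `ji_result`: `per_object` data frame (`gt_id`,
#'   `pred_id`, `overlap`, `ji`) and `mean_ji`.
#' @export
multi_object_ji <- function(gt, pred, min_overlap = 0.5,
                            denominator = c("gt", "union"),
                            matching = c("per_gt", "one_to_one")) {
  denominator <- match.arg(denominator)
  matching <- match.arg(matching)
  if (!all(dim(gt) == dim(pred))) .stop2("mask shapes differ")
  gt_ids <- sort(setdiff(unique(as.vector(gt)), 0L))
  if (length(gt_ids) == 0)
    .stop2("ground-truth mask contains no objects; mean JI is undefined")
  pred_area <- table(pred[pred > 0])
  gt_area <- table(gt[gt > 0])
  # pixel-level contingency of overlapping (gt, pred) object pairs
  sel <- gt > 0 & pred > 0
  pairs <- if (any(sel)) {
    tab <- table(gt = gt[sel], pred = pred[sel])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    df$gt <- as.integer(df$gt); df$pred <- as.integer(df$pred)
    df
  } else data.frame(gt = integer(0), pred = integer(0), Freq = integer(0))

  candidate <- function(gid, excluded = integer(0)) {
    cand <- pairs[pairs$gt == gid & !(pairs$pred %in% excluded), ,
                  drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(-cand$Freq, cand$pred), , drop = FALSE]
    cand[1, ]
  }
  score <- function(gid, best) {
    ga <- as.integer(gt_area[as.character(gid)])
    inter <- best$Freq
    pa <- as.integer(pred_area[as.character(best$pred)])
    ji <- inter / (ga + pa - inter)
    ov <- if (denominator == "gt") inter / ga else ji
    list(ov = ov, ji = ji)
  }

  res <- data.frame(gt_id = gt_ids, pred_id = NA_integer_, overlap = 0,
                    ji = 0)
  if (matching == "per_gt") {
    for (i in seq_along(gt_ids)) {
      best <- candidate(gt_ids[i])
      if (is.null(best)) next
      s <- score(gt_ids[i], best)
      res$overlap[i] <- s$ov
      if (s$ov >= min_overlap) {
        res$pred_id[i] <- best$pred
        res$ji[i] <- s$ji
      }
    }
  } else {
    # one-to-one: assign (gt, pred) pairs greedily by descending overlap
    used <- integer(0)
    ord <- pairs[order(-pairs$Freq, pairs$gt, pairs$pred), , drop = FALSE]
    assigned <- integer(0)
    for (k in seq_len(nrow(ord))) {
      gid <- ord$gt[k]
      if (gid %in% assigned || ord$pred[k] %in% used) next
      s <- score(gid, ord[k, ])
      i <- match(gid, gt_ids)
      res$overlap[i] <- max(res$overlap[i], s$ov)
      if (s$ov >= min_overlap) {
        res$pred_id[i] <- ord$pred[k]
        res$ji[i] <- s$ji
        used <- c(used, ord$pred[k])
        assigned <- c(assigned, gid)
      }
    }
  }
  structure(list(per_object = res, mean_ji = mean(res$ji)),
            class = "ji_result")
}

#' @export
print.ji_result <- function(x, ...) {
  cat(sprintf("multi-object Jaccard: %d GT objects, %d matched, mean JI %.4f\n",
              nrow(x$per_object), sum(!is.na(x$per_object$pred_id)),
              x$mean_ji))
  invisible(x)
}

#' Write a per-object Jaccard report
#'
#' @param result a `ji_result` from [multi_object_ji()].
#' @param path output CSV; per-object rows followed by a `mean` row.
#' @export
write_ji_report <- function(result, path) {
  stopifnot(inherits(result, "ji_result"))
  per <- result$per_object
  per$gt_id <- as.character(per$gt_id)
  per <- rbind(per, data.frame(gt_id = "mean", pred_id = NA,
                               overlap = NA, ji = result$mean_ji))
  write.csv(per, path, row.names = FALSE, na = "")
  invisible(path)
}
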