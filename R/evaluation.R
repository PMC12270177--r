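# Per-core quantitative metrics (Dice, pixel precision and recall over the
# three epithelium classes, background disregarded), the three aggregation
# rows, subgroup summaries, and the 0-5 qualitative scoring schema as a
# validated data format.
#
# Zero-denominator convention: any metric whose denominator is zero is set
# to one — for Dice this is the case when the class is absent from both the
# prediction and the ground truth.

EVAL_CLASSES <- c(invasive = 1L, benign = 2L, in_situ = 3L)

#' Per-core, per-class segmentation metrics
#'
#' dice = 2TP / (2TP + FP + FN), precision = TP / (TP + FP),
#' recall = TP / (TP + FN); any zero denominator gives 1.
#'
#' @param pred,gt \code{label_map}s (or integer matrices) of equal size with
#'   values in 0..3.
#' @param core_ref,case_id,subtype,grade metadata carried onto the rows.
#' @return tibble with one row per class: counts, metrics and the
#'   \code{present_in_gt} / \code{present_in_pred} flags feeding rows
#'   I/II/III.
#' @export
core_metrics <- function(pred, gt, core_ref = NA_character_,
                         case_id = NA_character_, subtype = "unknown",
                         grade = "unknown") {
  p <- if (inherits(pred, "label_map")) pred$raster else pred
  g <- if (inherits(gt, "label_map")) gt$raster else gt
  if (!all(dim(p) == dim(g)))
    stop("prediction/ground-truth size mismatch: ",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(g), collapse = "x"))
  rows <- lapply(names(EVAL_CLASSES), function(cls) {
    k <- EVAL_CLASSES[[cls]]
    pk <- p == k; gk <- g == k
    tp <- sum(pk & gk); fp <- sum(pk & !gk); fn <- sum(!pk & gk)
    safe <- function(num, den) if (den == 0) 1 else num / den
    tibble::tibble(core_ref = core_ref, case_id = case_id,
                   subtype = subtype, grade = as.character(grade),
                   class = cls, tp = tp, fp = fp, fn = fn,
                   dice = safe(2 * tp, 2 * tp + fp + fn),
                   precision = safe(tp, tp + fp),
                   recall = safe(tp, tp + fn),
                   present_in_gt = any(gk), present_in_pred = any(pk))
  })
  dplyr::bind_rows(rows)
}

#' Aggregate per-core metrics into rows I / II / III
#'
#' Row I averages over all cores; row II over cores where the class is
#' present in the ground truth or the prediction; row III over cores where
#' it is present in the ground truth. Empty subsets are reported with
#' \code{n = 0} and NA means (undefined, not zero).
#'
#' @param metrics tibble of \code{\link{core_metrics}} rows (several cores).
#' @param sd_type \code{"population"} (default, matching the reported
#'   mean +/- SD format) or \code{"sample"}.
#' @return tibble: class, row (I/II/III), n, mean/sd of dice, precision,
#'   recall.
#' @export
aggregate_rows <- function(metrics, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  sdf <- function(x) {
    if (length(x) <= 1L) return(if (length(x)) 0 else NA_real_)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  summarize_subset <- function(df, row) {
    tibble::tibble(row = row, n = nrow(df),
                   dice_mean = if (nrow(df)) mean(df$dice) else NA_real_,
                   dice_sd = sdf(df$dice),
                   precision_mean = if (nrow(df)) mean(df$precision) else NA_real_,
                   precision_sd = sdf(df$precision),
                   recall_mean = if (nrow(df)) mean(df$recall) else NA_real_,
                   recall_sd = sdf(df$recall))
  }
  metrics |>
    dplyr::group_by(class) |>
    dplyr::group_modify(function(df, key) {
      dplyr::bind_rows(
        summarize_subset(df, "I"),
        summarize_subset(df[df$present_in_gt | df$present_in_pred, ], "II"),
        summarize_subset(df[df$present_in_gt, ], "III"))
    }) |>
    dplyr::ungroup()
}

#' Mean Dice per subgroup (histological subtype or grade)
#'
#' Groups with no cores are omitted.
#'
#' @param metrics \code{\link{core_metrics}} tibble.
#' @param by \code{"subtype"} or \code{"grade"}.
#' @inheritParams aggregate_rows
#' @export
subgroup_summary <- function(metrics, by = c("subtype", "grade"),
                             sd_type = c("population", "sample")) {
  by <- match.arg(by)
  sd_type <- match.arg(sd_type)
  sdf <- function(x) {
    if (length(x) <= 1L) return(0)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  metrics |>
    dplyr::group_by(class, group = .data[[by]]) |>
    dplyr::summarise(n = dplyr::n(), dice_mean = mean(.data$dice),
                     dice_sd = sdf(.data$dice), .groups = "drop") |>
    dplyr::filter(.data$n > 0)
}

#' Validate qualitative 0-5 scores
#'
#' Score 0 means the class is not present in the image or segmentation, or
#' the image is unsuitable; 5 means all or almost all cells are correctly
#' segmented. Invalid records are rejected at ingest.
#'
#' @param scores data frame with columns case_id, class (one of
#'   all_epithelium, benign, in_situ, invasive), score (integer 0..5),
#'   rater.
#' @return validated tibble.
#' @export
validate_scores <- function(scores) {
  scores <- tibble::as_tibble(scores)
  need <- c("case_id", "class", "score", "rater")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing score columns: ", paste(miss, collapse = ", "))
  ok_class <- scores$class %in% c("all_epithelium", "benign", "in_situ", "invasive")
  ok_score <- scores$score %in% 0:5
  if (!all(ok_class)) stop("invalid class values: ",
                           paste(unique(scores$class[!ok_class]), collapse = ", "))
  if (!all(ok_score)) stop("invalid score values: ",
                           paste(unique(scores$score[!ok_score]), collapse = ", "))
  scores
}

#' Summarise qualitative scores, excluding score zero
#'
#' Mean +/- SD per class in two variants: "All" over every scored case, and
#' "Present" restricted to cases where the class is present in the ground
#' truth. Zero scores (class absent / image unsuitable) are excluded from
#' the means; N counts the contributing scores.
#'
#' @param scores validated scores (see \code{\link{validate_scores}}).
#' @param gt_presence optional data frame (case_id, class, present) defining
#'   the "Present" variant; omitted => "All" only.
#' @inheritParams aggregate_rows
#' @export
qualitative_report <- function(scores, gt_presence = NULL,
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  scores <- validate_scores(scores)
  sdf <- function(x) {
    if (length(x) <= 1L) return(if (length(x)) 0 else NA_real_)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  summarize <- function(df, variant) {
    df |>
      dplyr::group_by(class) |>
      dplyr::summarise(
        variant = variant,
        n = sum(.data$score != 0L),
        mean = ifelse(n > 0, mean(.data$score[.data$score != 0L]), NA_real_),
        sd = ifelse(n > 0, sdf(.data$score[.data$score != 0L]), NA_real_),
        .groups = "drop")
  }
  out <- summarize(scores, "All")
  if (!is.null(gt_presence)) {
    pres <- dplyr::inner_join(scores, tibble::as_tibble(gt_presence),
                              by = c("case_id", "class"))
    out <- dplyr::bind_rows(out, summarize(pres[pres$present, ], "Present"))
  }
  out
}

#' Evaluate a set of prediction/ground-truth core pairs
#'
#' Convenience wrapper: per-core metrics plus the three aggregation rows.
#'
#' @param pairs list of lists with \code{pred}, \code{gt} and optional
#'   metadata (\code{core_ref}, \code{case_id}, \code{subtype},
#'   \code{grade}).
#' @return list of class \code{ihc_evaluation}: \code{per_core} and
#'   \code{rows} tibbles.
#' @export
evaluate_cores <- function(pairs) {
  per_core <- dplyr::bind_rows(lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    core_metrics(p$pred, p$gt,
                 core_ref = p$core_ref %||% as.character(i),
                 case_id = p$case_id %||% NA_character_,
                 subtype = p$subtype %||% "unknown",
                 grade = p$grade %||% "unknown")
  }))
  structure(list(per_core = per_core, rows = aggregate_rows(per_core)),
            class = "ihc_evaluation")
}

#' @export
print.ihc_evaluation <- function(x, ...) {
  cat("<ihc_evaluation of", length(unique(x$per_core$core_ref)), "cores>\n")
  print(x$rows)
  invisible(x)
}

#' @method tidy ihc_evaluation
#' @export
tidy.ihc_evaluation <- function(x, ...) x$per_core

#' @method glance ihc_evaluation
#' @export
glance.ihc_evaluation <- function(x, ...) {
  x$rows |>
    dplyr::filter(.data$row == "I") |>
    dplyr::select("class", "dice_mean", "precision_mean", "recall_mean") |>
    tidyr::pivot_wider(names_from = "class",
                       values_from = c("dice_mean", "precision_mean",
                                       "recall_mean"))
}

#' Plot per-core Dice distributions by class and aggregation row
#' @param object \code{ihc_evaluation}.
#' @param ... unused.
#' @method autoplot ihc_evaluation
#' @export
autoplot.ihc_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$per_core,
                  ggplot2::aes(x = .data$class, y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "Dice (per core)") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#' @param object \code{agunet} with history.
#' @param ... unused.
#' @method autoplot agunet
#' @export
autoplot.agunet <- function(object, ...) {
  h <- object$history
  if (is.null(h)) stop("model has no training history")
  df <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Dice loss", colour = NULL) +
    ggplot2::theme_minimal()
}
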