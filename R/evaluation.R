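#' Confusion counts for one binary output
#'
#' @param tp,fp,fn,tn non-negative counts (true/false positive/negative).
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop_format("confusion counts must be non-negative numbers")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%g FP=%g FN=%g TN=%g (total %g)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Tally a confusion matrix for one binary output
#'
#' @param predicted logical or 0/1 vector of predicted flags.
#' @param actual logical or 0/1 vector of true flags, same length.
#' @return a [confusion_counts()].
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop_format("predicted (%d) and actual (%d) lengths differ",
                length(predicted), length(actual))
  }
  p <- as.logical(predicted)
  a <- as.logical(actual)
  if (anyNA(p) || anyNA(a)) stop_format("flags must be binary without NA")
  confusion_counts(tp = sum(p & a), fp = sum(p & !a),
                   fn = sum(!p & a), tn = sum(!p & !a))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy is `(TP + TN) / (TP + FP + FN + TN)`; precision
#' `TP / (TP + FP)`; recall `TP / (TP + FN)`; F1 the harmonic mean of
#' precision and recall. A metric whose denominator is zero is reported
#' as `NA` (the undefined sentinel) with a warning, and callers exclude
#' such values from averages.
#'
#' @param cc a [confusion_counts()].
#' @return named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
basic_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$fp + cc$fn + cc$tn
  if (total == 0) stop_format("cannot compute metrics of an empty matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  precision <- safe_div(cc$tp, cc$tp + cc$fp, "precision")
  recall <- safe_div(cc$tp, cc$tp + cc$fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall)) {
      warning("F1 undefined (precision + recall = 0)", call. = FALSE)
    }
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (cc$tp + cc$tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' Summary metrics for the detection head
#'
#' The detection output is reported per model as one accuracy and one F1.
#' Convention (fixed by requiring agreement between the published
#' per-class confusion blocks and the published summary table): macro
#' averaging over the two class blocks — accuracy is the mean of the
#' normal-block and stroke-block accuracies, F1 the mean of their F1
#' scores. For symmetric two-class blocks this coincides with the micro
#' value to the table's printed precision.
#'
#' @param normal [confusion_counts()] with normal gait as the positive
#'   class.
#' @param stroke [confusion_counts()] with stroke gait as the positive
#'   class.
#' @return named list `accuracy`, `f1`.
#' @export
detection_summary <- function(normal, stroke) {
  mn <- basic_metrics(normal)
  ms <- basic_metrics(stroke)
  list(accuracy = mean(c(mn$accuracy, ms$accuracy)),
       f1 = mean(c(mn$f1, ms$f1), na.rm = TRUE))
}

#' Summary metrics for the classification head
#'
#' Convention (fixed the same way as [detection_summary()]): accuracy is
#' the mean over the five output labels of the per-label accuracy (equal
#' to the pooled micro accuracy whenever all label blocks share one
#' total, which holds for every published model); F1 is micro-averaged —
#' TP/FP/FN are pooled over the five labels and the F1 formula applied to
#' the pooled counts.
#'
#' @param blocks list of five [confusion_counts()], one per output label
#'   (stroke, drop foot, circumduction, hip hiking, back knee).
#' @return named list `accuracy`, `f1`.
#' @export
classification_summary <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  accs <- vapply(blocks, function(cc) basic_metrics(cc)$accuracy,
                 numeric(1))
  tp <- sum(vapply(blocks, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(blocks, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(blocks, `[[`, numeric(1), "fn"))
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else
    2 * tp / (2 * tp + fp + fn)
  list(accuracy = mean(accs), f1 = f1)
}

.new_metrics_report <- function(models_df, detection_blocks = NULL,
                                classification_blocks = NULL) {
  avg <- data.frame(model = "Average",
                    t(colMeans(models_df[, -1, drop = FALSE])))
  names(avg) <- names(models_df)
  structure(list(per_model = models_df, average = avg,
                 detection_blocks = detection_blocks,
                 classification_blocks = classification_blocks),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  df <- rbind(x$per_model, x$average)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.4f",
                                                 round_half_up(v, digits)))
  cat("Validation results (per model and average)\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Reconstruct the published validation summary from confusion fixtures
#'
#' Applies [detection_summary()] and [classification_summary()] to the
#' packaged per-model confusion blocks, reproducing the published
#' per-model and averaged accuracy/F1 table from its printed confusion
#' matrices.
#'
#' @param fixtures output of [load_confusion_fixtures()]; loaded with the
#'   documented correction by default.
#' @return a `metrics_report` with columns `detection_accuracy`,
#'   `detection_f1`, `classification_accuracy`, `classification_f1`.
#' @examples
#' rep <- reconstruct_table7()
#' print(rep)
#' @export
reconstruct_table7 <- function(fixtures = load_confusion_fixtures()) {
  cls_labels <- c("stroke", "drop_foot", "circumduction", "hip_hiking",
                  "back_knee")
  fx_det <- fixtures[fixtures$task == "detection", ]
  fx_cls <- fixtures[fixtures$task == "classification", ]
  rows <- lapply(sort(unique(fixtures$model)), function(m) {
    det <- detection_summary(fixture_block(fx_det, m, "normal"),
                             fixture_block(fx_det, m, "stroke"))
    cls <- classification_summary(
      lapply(cls_labels, function(lb) fixture_block(fx_cls, m, lb)))
    data.frame(model = as.character(m),
               detection_accuracy = det$accuracy, detection_f1 = det$f1,
               classification_accuracy = cls$accuracy,
               classification_f1 = cls$f1)
  })
  .new_metrics_report(do.call(rbind, rows))
}

#' Full k-fold cross-validation of the gait network
#'
#' Implements the published protocol: the labelled cycles are split into
#' `k` stratified folds; for each fold, a fresh network is trained on the
#' other `k - 1` folds and evaluated on the held-out fold with the gated
#' decision rule of [predict_gait()]. Per model, the detection confusion
#' blocks treat normal and stroke gait in turn as the positive class over
#' the whole held-out fold; the classification confusion blocks are
#' tallied over the held-out samples that the detection head routed to
#' the classification part (predicted stroke), with the five outputs
#' thresholded at 0.5.
#'
#' @param dataset a [gait_dataset].
#' @param k number of folds (default 4).
#' @param config a [training_config()]; each fold's model trains with
#'   `config$seed + fold` so models differ only by fold and seed offset.
#' @param seed seed for the fold split.
#' @param folds optional subset of fold ids to run (default all).
#' @param verbose print per-fold progress.
#' @return a `metrics_report` with the per-model summaries, plus the raw
#'   detection and classification confusion blocks per model.
#' @export
crossvalidate <- function(dataset, k = 4, config = training_config(),
                          seed = 0, folds = NULL, verbose = FALSE) {
  split <- make_folds(dataset, k = k, seed = seed)
  folds <- folds %||% seq_len(k)
  tg <- target_matrices(dataset)
  rows <- list()
  det_blocks <- list()
  cls_blocks <- list()
  for (f in folds) {
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_network(dataset, split, holdout_fold = f, config = cfg)
    idx <- which(split$assignment == f)
    pred <- predict_gait(fit$net, dataset$cycles[idx, , drop = FALSE])
    true_sg <- dataset$labels$sg[idx] == 1
    pred_sg <- pred$labels$sg == 1
    normal_cc <- confusion(!pred_sg, !true_sg)
    stroke_cc <- confusion(pred_sg, true_sg)
    det <- detection_summary(normal_cc, stroke_cc)
    gated <- which(pred_sg)
    if (length(gated) == 0L) {
      warning(sprintf("fold %d: no sample predicted stroke; %s", f,
                      "classification metrics unavailable"),
              call. = FALSE)
      cls <- list(accuracy = NA_real_, f1 = NA_real_)
      blocks <- NULL
    } else {
      pred_flags <- cbind(pred$classification[gated, 1, drop = FALSE] > 0.5,
                          pred$labels[gated, c("sgw_df", "sgw_c", "sgw_hh",
                                               "sgw_bk")] == 1)
      true_flags <- tg$classification[idx[gated], , drop = FALSE]
      blocks <- lapply(seq_len(5), function(j) {
        confusion(pred_flags[, j], true_flags[, j] == 1)
      })
      names(blocks) <- c("stroke", "drop_foot", "circumduction",
                         "hip_hiking", "back_knee")
      cls <- classification_summary(blocks)
    }
    if (verbose) {
      message(sprintf(
        "fold %d: detection acc %.4f / F1 %.4f; classification acc %s",
        f, det$accuracy, det$f1, format(round_half_up(cls$accuracy, 4))))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model = as.character(f),
      detection_accuracy = det$accuracy, detection_f1 = det$f1,
      classification_accuracy = cls$accuracy,
      classification_f1 = cls$f1)
    det_blocks[[as.character(f)]] <- list(normal = normal_cc,
                                          stroke = stroke_cc)
    cls_blocks[[as.character(f)]] <- blocks
  }
  .new_metrics_report(do.call(rbind, rows), det_blocks, cls_blocks)
}

#' Write a metrics report as JSON or an aligned text table
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @param format `"json"` or `"text"`.
#' @return the path, invisibly.
#' @export
write_metrics_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(per_model = report$per_model, average = report$average),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(path)
}
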