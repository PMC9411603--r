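# Evaluation suite: 9 x 9 confusion matrix, one-vs-rest per-class F1 /
# accuracy / sensitivity / specificity, macro F1, and grouped
# "sub-abnormal" F1 (AF; Block = I-AVB + LBBB + RBBB; PC = PAC + PVC;
# ST = STD + STE) computed on the group-merged matrix.

#' Sub-abnormal group map
#'
#' @return named list mapping group name to member classes.
#' @export
subabnormal_groups <- function() {
  list(AF = "AF",
       Block = c("I-AVB", "LBBB", "RBBB"),
       PC = c("PAC", "PVC"),
       ST = c("STD", "STE"))
}

#' Confusion matrix over the nine rhythm classes
#'
#' Rows are reference labels, columns predicted labels, both in the fixed
#' class order of [ecg_classes()].
#'
#' @param references,predictions character vectors of class names (or
#'   factors), equal length.
#' @param classes class order (default [ecg_classes()]).
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(references, predictions, classes = ecg_classes()) {
  references <- as.character(references)
  predictions <- as.character(predictions)
  if (length(references) != length(predictions)) {
    stop("references and predictions must have equal length")
  }
  bad <- setdiff(unique(c(references, predictions)), classes)
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  cm <- table(factor(references, levels = classes),
              factor(predictions, levels = classes))
  cm <- unclass(cm)
  dimnames(cm) <- list(reference = classes, predicted = classes)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

ovr_counts <- function(cm, i) {
  tp <- cm[i, i]
  fp <- sum(cm[-i, i])
  fn <- sum(cm[i, -i])
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

f1_from_counts <- function(tp, fp, fn) {
  if (tp == 0 && (fp > 0 || fn > 0)) return(0)
  if (tp == 0) return(0)  # empty class: conservative zero
  fp_prec <- tp / (tp + fp)
  fr_rec <- tp / (tp + fn)
  2 * (fp_prec * fr_rec) / (fp_prec + fr_rec)
}

#' Per-class F1 scores
#'
#' One-vs-rest harmonic mean of precision and recall for each class; a
#' class with no true positives scores 0 (conservative convention when
#' precision + recall is undefined).
#'
#' @param cm a [confusion()] matrix.
#' @return named numeric vector, one value per class.
#' @export
f1_per_class <- function(cm) {
  vapply(seq_len(nrow(cm)), function(i) {
    n <- ovr_counts(cm, i)
    f1_from_counts(n["tp"], n["fp"], n["fn"])
  }, numeric(1)) |> stats::setNames(rownames(cm))
}

#' Macro F1
#'
#' Unweighted mean of the per-class F1 values.
#'
#' @param f1 vector of per-class F1 values (or a confusion matrix, from
#'   which they are computed).
#' @return scalar macro F1.
#' @export
macro_f1 <- function(f1) {
  if (inherits(f1, "confusion_matrix") || is.matrix(f1)) {
    f1 <- f1_per_class(f1)
  }
  mean(f1)
}

#' Per-class accuracy, sensitivity and specificity
#'
#' One-vs-rest on the 9 x 9 matrix.  Sensitivity is numerically identical
#' to recall.
#'
#' @param cm a [confusion()] matrix.
#' @return data frame with columns `class`, `acc`, `se`, `sp`, `precision`,
#'   `recall`.
#' @export
acc_se_sp <- function(cm) {
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    n <- ovr_counts(cm, i)
    tp <- n[["tp"]]; fp <- n[["fp"]]; fn <- n[["fn"]]; tn <- n[["tn"]]
    data.frame(
      class = rownames(cm)[i],
      acc = (tp + tn) / (tp + tn + fp + fn),
      se = if (tp + fn > 0) tp / (tp + fn) else 0,
      sp = if (tn + fp > 0) tn / (tn + fp) else 0,
      precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Merge confusion-matrix classes into sub-abnormal groups
#'
#' Sums the member rows and columns of each group into one super-class;
#' classes outside every group (Normal) are kept as they are.  Row and
#' column totals are conserved.
#'
#' @param cm a [confusion()] matrix.
#' @param groups named list of member-class vectors (default
#'   [subabnormal_groups()]); groups must not overlap.
#' @return merged confusion matrix.
#' @export
merge_groups <- function(cm, groups = subabnormal_groups()) {
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) stop("groups overlap")
  if (!all(members %in% rownames(cm))) {
    stop("group member(s) not present in the confusion matrix: ",
         paste(setdiff(members, rownames(cm)), collapse = ", "))
  }
  mapping <- stats::setNames(rownames(cm), rownames(cm))
  for (g in names(groups)) mapping[groups[[g]]] <- g
  new_classes <- unique(unname(mapping))
  agg <- matrix(0L, length(new_classes), length(new_classes),
                dimnames = list(reference = new_classes,
                                predicted = new_classes))
  for (i in rownames(cm)) {
    for (j in colnames(cm)) {
      agg[mapping[[i]], mapping[[j]]] <- agg[mapping[[i]], mapping[[j]]] +
        cm[i, j]
    }
  }
  class(agg) <- c("confusion_matrix", class(agg))
  agg
}

#' Sub-abnormal grouped F1 scores
#'
#' F1 of each group's super-class on the group-merged matrix: confusion
#' within a group vanishes after merging, so a single-member group (AF)
#' reproduces that class's own F1.
#'
#' @inheritParams merge_groups
#' @return named numeric vector, one value per group.
#' @export
subabnormal_f1 <- function(cm, groups = subabnormal_groups()) {
  merged <- merge_groups(cm, groups)
  f1 <- f1_per_class(merged)
  f1[names(groups)]
}

#' Full metrics report
#'
#' @param references,predictions class-name vectors.
#' @param classes class order.
#' @return a `metrics_report`: list with `confusion`, `per_class` (data
#'   frame incl. F1), `macro_f1`, `subabnormal_f1`.
#' @export
metrics_report <- function(references, predictions,
                           classes = ecg_classes()) {
  cm <- confusion(references, predictions, classes)
  per <- acc_se_sp(cm)
  per$f1 <- unname(f1_per_class(cm))
  structure(list(confusion = cm, per_class = per,
                 macro_f1 = macro_f1(cm),
                 subabnormal_f1 = subabnormal_f1(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> macro F1 = %.3f\n", x$macro_f1))
  cat("per-class F1: ",
      paste(sprintf("%s %.3f", x$per_class$class, x$per_class$f1),
            collapse = ", "), "\n")
  cat("sub-abnormal F1: ",
      paste(sprintf("%s %.3f", names(x$subabnormal_f1), x$subabnormal_f1),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(macro_f1 = report$macro_f1,
              per_class = report$per_class,
              subabnormal_f1 = as.list(report$subabnormal_f1),
              confusion = unclass(report$confusion))
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
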