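test_that("confusion matrices tally reference x prediction counts", {
  refs <- c("Normal", "AF", "AF", "STE")
  preds <- c("Normal", "AF", "Normal", "STD")
  cm <- confusion(refs, preds)
  expect_identical(dim(cm), c(9L, 9L))
  expect_equal(sum(cm), 4)
  expect_equal(cm["AF", "AF"], 1L)
  expect_equal(cm["AF", "Normal"], 1L)
  expect_equal(cm["STE", "STD"], 1L)

  perfect <- confusion(ecg_classes(), ecg_classes())
  expect_true(all(perfect == diag(9)))

  all_normal <- confusion(ecg_classes(), rep("Normal", 9))
  expect_true(all(all_normal[, -1] == 0))
  expect_true(all(all_normal[, 1] == 1))

  expect_error(confusion("AF", "WPW"), "unknown class")
  # brute-force tally on a random set
  cm2 <- random_confusion(n = 50, seed = 1)
  expect_equal(sum(cm2), 50)
})

test_that("per-class F1 follows the harmonic-mean formula", {
  # craft a matrix with known one-vs-rest counts for class AF:
  # TP = 8, FP = 2, FN = 2
  refs <- c(rep("AF", 10), rep("Normal", 10))
  preds <- c(rep("AF", 8), "Normal", "Normal",
             rep("Normal", 8), "AF", "AF")
  f1 <- f1_per_class(confusion(refs, preds))
  expect_equal(f1[["AF"]], 0.8)

  # TP = 6, FP = 2, FN = 4 -> precision 0.75, recall 0.6
  refs2 <- c(rep("PVC", 10), rep("Normal", 10))
  preds2 <- c(rep("PVC", 6), rep("Normal", 4),
              rep("Normal", 8), "PVC", "PVC")
  f1b <- f1_per_class(confusion(refs2, preds2))
  expect_equal(f1b[["PVC"]], 2 * 0.75 * 0.6 / 1.35)

  # TP = 0 with FN > 0 scores zero
  f1c <- f1_per_class(confusion(rep("STE", 5), rep("Normal", 5)))
  expect_equal(f1c[["STE"]], 0)
})

test_that("macro F1 averages the per-class scores", {
  em <- c(0.787, 0.949, 0.870, 0.970, 0.935, 0.764, 0.897, 0.748, 0.667)
  expect_equal(round(macro_f1(em), 3), 0.843)
  row5 <- c(0.787, 0.954, 0.876, 0.938, 0.941, 0.744, 0.907, 0.763, 0.606)
  expect_equal(round(macro_f1(row5), 3), 0.835)
  expect_equal(macro_f1(rep(0.5, 9)), 0.5)
})

test_that("accuracy, sensitivity and specificity follow their formulas", {
  # class AF one-vs-rest: TP = 8, FN = 4, FP = 3, TN = 85
  refs <- c(rep("AF", 12), rep("Normal", 88))
  preds <- c(rep("AF", 8), rep("Normal", 4),
             rep("AF", 3), rep("Normal", 85))
  tab <- acc_se_sp(confusion(refs, preds))
  af <- tab[tab$class == "AF", ]
  expect_equal(af$acc, 0.93)
  expect_equal(af$se, 2 / 3)
  expect_equal(af$sp, 85 / 88)

  diag_tab <- acc_se_sp(confusion(ecg_classes(), ecg_classes()))
  expect_true(all(diag_tab$acc == 1 & diag_tab$se == 1 & diag_tab$sp == 1))
})

test_that("sensitivity equals recall on random matrices", {
  for (s in 1:5) {
    tab <- acc_se_sp(random_confusion(n = 120, seed = s))
    expect_equal(tab$se, tab$recall)
  }
})

test_that("F1 lies between precision and recall; metrics are equivariant", {
  cm <- random_confusion(n = 150, seed = 9)
  tab <- acc_se_sp(cm)
  f1 <- f1_per_class(cm)
  for (i in seq_len(9)) {
    lo <- min(tab$precision[i], tab$recall[i])
    hi <- max(tab$precision[i], tab$recall[i])
    expect_gte(f1[[i]] + 1e-12, if (f1[[i]] == 0) 0 else lo)
    expect_lte(f1[[i]], hi + 1e-12)
  }
  # permuting class order permutes per-class F1 and keeps macro F1
  perm <- c(3, 1, 2, 9, 5, 4, 8, 7, 6)
  classes_p <- ecg_classes()[perm]
  refs <- rep(ecg_classes(), times = 5)
  preds <- with_fixed_seed(2, sample(rep(ecg_classes(), times = 5)))
  cm1 <- confusion(refs, preds)
  cm2 <- confusion(refs, preds, classes = classes_p)
  expect_equal(f1_per_class(cm2)[ecg_classes()], f1_per_class(cm1))
  expect_equal(macro_f1(cm1), macro_f1(cm2))
})

test_that("group merging conserves totals and reproduces member F1", {
  cm <- random_confusion(n = 200, seed = 4)
  merged <- merge_groups(cm)
  expect_equal(sum(merged), sum(cm))
  expect_equal(sum(merged["Normal", ]), sum(cm["Normal", ]))
  # AF is a singleton group: F1 unchanged
  expect_equal(subabnormal_f1(cm)[["AF"]], f1_per_class(cm)[["AF"]])

  # confusion only within Block vanishes after merging
  refs <- rep(c("I-AVB", "LBBB", "RBBB"), each = 4)
  preds <- c(rep("LBBB", 4), rep("RBBB", 4), rep("I-AVB", 4))
  cmb <- confusion(refs, preds)
  expect_equal(subabnormal_f1(cmb)[["Block"]], 1)

  expect_error(merge_groups(cm, list(A = "AF", B = c("AF", "PVC"))),
               "overlap")
})

test_that("merged-matrix F1 equals a relabel-then-score oracle", {
  groups <- subabnormal_groups()
  relabel <- function(x) {
    for (g in names(groups)) x[x %in% groups[[g]]] <- g
    x
  }
  for (s in 1:5) {
    n <- 150
    with_fixed_seed(s, {
      refs <- sample(ecg_classes(), n, replace = TRUE)
      preds <- ifelse(stats::runif(n) < 0.5, refs,
                      sample(ecg_classes(), n, replace = TRUE))
    })
    ours <- subabnormal_f1(confusion(refs, preds))
    # oracle: relabel the raw label vectors, rebuild a confusion matrix
    # over the merged class set, score one-vs-rest
    merged_classes <- c("Normal", names(groups))
    cm_o <- table(factor(relabel(refs), levels = merged_classes),
                  factor(relabel(preds), levels = merged_classes))
    oracle <- vapply(names(groups), function(g) {
      tp <- cm_o[g, g]
      fp <- sum(cm_o[, g]) - tp
      fn <- sum(cm_o[g, ]) - tp
      if (tp == 0) return(0)
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      2 * p * r / (p + r)
    }, numeric(1))
    expect_equal(unname(ours), unname(oracle))
  }
})

test_that("metrics_report assembles a consistent summary", {
  refs <- rep(ecg_classes(), times = 6)
  preds <- with_fixed_seed(11, ifelse(stats::runif(54) < 0.7, refs,
                                      sample(refs)))
  rep_ <- metrics_report(refs, preds)
  expect_equal(rep_$macro_f1, mean(rep_$per_class$f1))
  expect_true(all(rep_$per_class$f1 >= 0 & rep_$per_class$f1 <= 1))
  expect_equal(sum(rep_$confusion), 54)
  json <- report_to_json(rep_)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$macro_f1, rep_$macro_f1)
})
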