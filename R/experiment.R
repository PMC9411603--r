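# Training protocol: stratified record-level k-fold splits, per-combination
# training with single-optimal-model selection by lowest average validation
# loss, record-level prediction by mean slice softmax, and majority-vote
# ensembling.

#' Stratified record-level cross-validation folds
#'
#' Partitions record ids into `k` disjoint folds, stratified by class, so
#' that all slices of a record land in the same fold (no train/validation
#' leakage through overlapping windows).  Deterministic for a given seed.
#' Classes with fewer than `k` records are assigned round-robin with a
#' warning.
#'
#' @param record_ids character vector.
#' @param labels class labels, same length.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list of `k` character vectors of record ids.
#' @export
split_folds <- function(record_ids, labels, k = 5, seed = 1L) {
  stopifnot(length(record_ids) == length(labels), k >= 2)
  if (length(record_ids) < k) stop("fewer records than folds")
  if (anyDuplicated(record_ids)) stop("duplicate record ids")
  folds <- vector("list", k)
  with_seed(seed, {
    fill <- integer(0)  # round-robin cursor across classes
    cursor <- 0L
    for (cl in unique(labels)) {
      ids <- record_ids[labels == cl]
      ids <- if (length(ids) > 1L) sample(ids) else ids
      if (length(ids) < k) {
        warning(sprintf("class %s has %d record(s) < %d folds; %s",
                        cl, length(ids), k, "assigning round-robin"))
      }
      for (id in ids) {
        f <- (cursor %% k) + 1L
        folds[[f]] <- c(folds[[f]], id)
        cursor <- cursor + 1L
      }
    }
  })
  folds
}

#' Training configuration
#'
#' @param learning_rate,dropout,momentum the hyper-parameters screened by
#'   the covering array.
#' @param epochs maximum training epochs (default 50, with the best
#'   validation epoch checkpointed — no later checkpoint is ever selected).
#' @param folds number of cross-validation folds (default 5).
#' @param batch_size slices per SGD step.
#' @param seed RNG seed (fold shuffling, dropout, weight init offsets).
#' @param loss_window how many final epochs to average when ranking folds
#'   by validation loss (default 5).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.1, dropout = 0.5, momentum = 0.7,
                         epochs = 50, folds = 5, batch_size = 32,
                         seed = 1L, loss_window = 5) {
  stopifnot(epochs >= 1, folds >= 2, batch_size >= 1)
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 momentum = momentum, epochs = as.integer(epochs),
                 folds = as.integer(folds),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss_window = as.integer(loss_window)),
            class = "train_config")
}

#' Train one model with per-epoch validation tracking
#'
#' Runs SGD with momentum over mini-batches of labeled slices, recording
#' training and validation loss/accuracy each epoch.  The parameters of
#' the epoch with the lowest validation loss are restored at the end
#' (early-stopping checkpoint).  A NaN loss aborts with an error.
#'
#' @param model a `dse_resnet` (mutated in place).
#' @param train_slices,val_slices lists of labeled `two_dim_slice`s.
#' @param tc a [train_config()].
#' @return list with `model`, `history` (data frame: epoch, train_loss,
#'   train_acc, val_loss, val_acc), `best_epoch`, `val_loss` (average over
#'   the final `loss_window` epochs, the fold-ranking criterion).
#' @export
train_model <- function(model, train_slices, val_slices, tc) {
  ages <- vapply(train_slices, function(s) as.numeric(s$age), 0)
  if (any(!is.na(ages))) model$age_fill <- mean(ages, na.rm = TRUE) / 100
  train_batch_all <- make_batch(train_slices, model)
  val_batch <- make_batch(val_slices, model)
  if (anyNA(train_batch_all$labels) || anyNA(val_batch$labels)) {
    stop("all slices must be labeled for training")
  }
  n <- length(train_slices)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  best <- list(epoch = NA_integer_, loss = Inf, snap = NULL)
  with_seed(tc$seed, for (ep in seq_len(tc$epochs)) {
    ord <- sample(n)
    ep_losses <- numeric(0)
    for (s in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[s:min(s + tc$batch_size - 1L, n)]
      batch <- make_batch(train_slices[idx], model)
      loss <- train_step(model, batch, tc$learning_rate, tc$momentum)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
      }
      ep_losses <- c(ep_losses, loss)
    }
    tp <- predict_slices(model, train_batch_all)
    vp <- predict_slices(model, val_batch)
    tl <- cross_entropy(tp, train_batch_all$labels)
    vl <- cross_entropy(vp, val_batch$labels)
    if (!is.finite(vl)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = tl,
      train_acc = mean(max.col(tp) == train_batch_all$labels),
      val_loss = vl,
      val_acc = mean(max.col(vp) == val_batch$labels)))
    if (vl < best$loss) {
      best <- list(epoch = ep, loss = vl,
                   snap = snapshot_params(model$param_layers))
    }
  })
  if (!is.null(best$snap)) restore_params(model$param_layers, best$snap)
  win <- min(tc$loss_window, nrow(hist))
  list(model = model, history = hist, best_epoch = best$epoch,
       val_loss = mean(utils::tail(hist$val_loss, win)))
}

#' Cross-validate one hyper-parameter combination
#'
#' Trains `tc$folds` fold-models (stratified record-level folds) with the
#' combination's learning rate, dropout and momentum, then selects the
#' fold whose validation loss — averaged over the final `loss_window`
#' epochs — is lowest: the "single optimal model" for this combination.
#' Folds that diverge are excluded from selection with a diagnostic.
#'
#' @param slices list of labeled `two_dim_slice`s (all records,
#'   preprocessed).
#' @param base_config a [model_config()]; its dropout is overridden by the
#'   combination's.
#' @param tc a [train_config()].
#' @return list with `best` (the selected fold's result, incl. `model` and
#'   `fold`), `folds` (all fold results), `failed` (diagnostics of
#'   diverged folds).
#' @export
train_combination <- function(slices, base_config, tc) {
  rec_of_slice <- vapply(slices, `[[`, "", "record_id")
  lab_of_slice <- vapply(slices, `[[`, "", "label")
  recs <- !duplicated(rec_of_slice)
  fold_ids <- split_folds(rec_of_slice[recs], lab_of_slice[recs],
                          k = tc$folds, seed = tc$seed)
  cfg <- base_config
  cfg$dropout <- tc$dropout
  results <- list(); failed <- list()
  for (f in seq_along(fold_ids)) {
    val_mask <- rec_of_slice %in% fold_ids[[f]]
    cfg_f <- cfg
    cfg_f$seed <- base_config$seed + f
    model <- build_impl_seeded(cfg_f)
    tc_f <- tc
    tc_f$seed <- tc$seed * 131L + f
    res <- tryCatch(
      train_model(model, slices[!val_mask], slices[val_mask], tc_f),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <- list(fold = f,
                                            message = conditionMessage(res))
    } else {
      res$fold <- f
      results[[length(results) + 1L]] <- res
    }
  }
  if (!length(results)) stop("no valid fold: every fold diverged")
  losses <- vapply(results, `[[`, 0, "val_loss")
  list(best = results[[which.min(losses)]], folds = results,
       failed = failed)
}

build_impl_seeded <- function(cfg) with_seed(cfg$seed, build_impl(cfg))

#' Predict the class of one record
#'
#' Preprocesses the record, averages the per-slice softmax vectors and
#' takes the arg-max.
#'
#' @param model a `dse_resnet`.
#' @param record an [ecg_record].
#' @param fspec,policy preprocessing settings (see [preprocess_record()]).
#' @return list with `label` and `probs` (length-9 named vector).
#' @export
predict_record <- function(model, record, fspec = filter_spec(),
                           policy = slicing_policy()) {
  slices <- preprocess_record(record, fspec, policy)
  p <- predict_slices(model, slices)
  probs <- colMeans(p)
  list(label = names(probs)[which.max(probs)], probs = probs)
}

#' Majority vote over per-model predictions
#'
#' The plurality label wins ("the minority obeys the majority").  Ties are
#' broken by the highest summed probability among the tied labels, then by
#' lowest class index; `tie_broken` records whether the plurality alone
#' was decisive.
#'
#' @param labels character vector, one predicted label per model.
#' @param probs optional numeric matrix (models x 9, columns in
#'   [ecg_classes()] order) of the models' probability vectors.
#' @param classes class order.
#' @return an `ensemble_prediction`: list with `label`, `tally` (named
#'   vote counts over all classes), `tie_broken`.
#' @export
vote <- function(labels, probs = NULL, classes = ecg_classes()) {
  if (!length(labels)) stop("empty prediction list")
  bad <- setdiff(labels, classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tally <- stats::setNames(integer(length(classes)), classes)
  tb <- table(labels)
  tally[names(tb)] <- as.integer(tb)
  top <- which(tally == max(tally))
  tie_broken <- length(top) > 1L
  winner <- if (tie_broken && !is.null(probs)) {
    sums <- colSums(probs[, top, drop = FALSE])
    top[order(-sums, seq_along(top))][1L]
  } else {
    top[1L]  # lowest class index among tied
  }
  structure(list(label = classes[winner], tally = tally,
                 tie_broken = tie_broken),
            class = "ensemble_prediction")
}

#' Ensemble prediction for a set of records
#'
#' Applies every model to every record and majority-votes the labels.
#'
#' @param models list of `dse_resnet` models.
#' @param records list of [ecg_record]s.
#' @param fspec,policy preprocessing settings.
#' @return data frame with `record_id`, per-model labels are voted into
#'   `label`, plus `tie_broken`.
#' @export
ensemble_predict <- function(models, records, fspec = filter_spec(),
                             policy = slicing_policy()) {
  rows <- lapply(records, function(rec) {
    preds <- lapply(models, predict_record, record = rec, fspec = fspec,
                    policy = policy)
    v <- vote(vapply(preds, `[[`, "", "label"),
              do.call(rbind, lapply(preds, `[[`, "probs")))
    data.frame(record_id = rec$record_id, label = v$label,
               tie_broken = v$tie_broken, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
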