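# The residual network with a detached squeeze-and-excitation (SE) module:
# a trunk of residual blocks (two (K, 1) convolutions each, batch norm,
# ReLU, dropout, max-pool shortcuts), one SE channel-attention module
# applied outside all blocks to the trunk output, global average pooling,
# age/sex auxiliary inputs, and a 9-way softmax head.

#' Model configuration
#'
#' The default configuration is the full-scale network: input slices of
#' 8192 samples x 12 leads x 1 channel, kernel (32, 1), channel schedule
#' 12-24-48-96-192 with four convolutions (two residual blocks) per stage —
#' 20 trunk Conv2D layers in 1 dimension-preserving block plus 9
#' dimension-changing blocks, with temporal stride 2 in every
#' dimension-changing block (8192 -> 16 after 9 halvings; the lead axis is
#' never downsampled).  Reduced configurations (shorter input, narrower
#' channels) use the same code path for desk-scale training.
#'
#' @param input_len temporal input length; must be divisible by
#'   `2^(n_blocks - 1)`.
#' @param n_leads number of leads (12).
#' @param n_classes number of output classes (9).
#' @param kernel temporal kernel size of the (kernel, 1) convolutions.
#' @param channels per-stage channel counts.
#' @param blocks_per_stage residual blocks per stage (2 in the full model).
#' @param dropout dropout rate inside residual blocks.
#' @param use_age_sex concatenate encoded age and sex into the head?
#' @param se_reduction channel reduction ratio of the SE bottleneck.
#' @param se_n_dense number of dense layers in the SE module (4).
#' @param head_hidden width of the hidden classification-head layer.
#' @param seed weight-initialization seed.
#' @return a `model_config` list.
#' @export
model_config <- function(input_len = 8192, n_leads = 12, n_classes = 9,
                         kernel = 32, channels = c(12, 24, 48, 96, 192),
                         blocks_per_stage = 2, dropout = 0.3,
                         use_age_sex = TRUE, se_reduction = 4,
                         se_n_dense = 4, head_hidden = 32, seed = 42L) {
  n_blocks <- blocks_per_stage * length(channels)
  factor <- 2^(n_blocks - 1L)
  if (input_len %% factor != 0L) {
    stop(sprintf(paste("input_len %d must be divisible by the cumulative",
                       "downsampling factor 2^(n_blocks-1) = %d"),
                 input_len, factor))
  }
  if (kernel < 2L) stop("kernel must be >= 2 (stride-2 blocks need it)")
  stopifnot(length(channels) >= 1L, all(channels >= 1L),
            dropout >= 0, dropout < 1, se_n_dense >= 2L)
  structure(list(input_len = as.integer(input_len),
                 n_leads = as.integer(n_leads),
                 n_classes = as.integer(n_classes),
                 kernel = as.integer(kernel), channels = as.integer(channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 n_blocks = as.integer(n_blocks), dropout = dropout,
                 use_age_sex = isTRUE(use_age_sex),
                 se_reduction = as.integer(se_reduction),
                 se_n_dense = as.integer(se_n_dense),
                 head_hidden = as.integer(head_hidden),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build the network
#'
#' Constructs all layers with seeded truncated-normal initialization and
#' returns the model together with its [architecture description][describe].
#'
#' @param config a [model_config()].
#' @return list with `model` (a `dse_resnet`) and `description`
#'   (an `architecture_description`).
#' @export
build_dse_resnet <- function(config = model_config()) {
  model <- with_seed(config$seed, build_impl(config))
  list(model = model, description = describe(model))
}

build_impl <- function(config) {
  ch <- config$channels
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    stage <- ceiling(b / config$blocks_per_stage)
    c_out <- ch[stage]
    c_in <- if (b == 1L) 1L else ch[ceiling((b - 1L) / config$blocks_per_stage)]
    stride <- if (b == 1L) 1L else 2L
    blocks[[b]] <- list(
      c_in = c_in, c_out = c_out, stride = stride,
      conv1 = new_conv(config$kernel, c_in, c_out, stride),
      bn1 = new_bn(c_out), relu1 = new_relu(),
      do1 = new_dropout(config$dropout),
      conv2 = new_conv(config$kernel, c_out, c_out, 1L),
      bn2 = new_bn(c_out), relu2 = new_relu(),
      do2 = new_dropout(config$dropout))
  }
  C <- ch[length(ch)]
  mid <- max(1L, C %/% config$se_reduction)
  se_widths <- c(C, rep(mid, config$se_n_dense - 1L), C)
  se <- lapply(seq_len(config$se_n_dense), function(i) {
    new_dense(se_widths[i], se_widths[i + 1L])
  })
  head_in <- config$n_leads * C + if (config$use_age_sex) 2L else 0L
  head <- list(fc1 = new_dense(head_in, config$head_hidden),
               relu = new_relu(),
               fc2 = new_dense(config$head_hidden, config$n_classes))
  param_layers <- c(
    unlist(lapply(blocks, function(b)
      list(b$conv1, b$bn1, b$conv2, b$bn2)), recursive = FALSE),
    se, list(head$fc1, head$fc2))
  structure(list(config = config, blocks = blocks, se = se, head = head,
                 param_layers = param_layers, age_fill = 0.6),
            class = "dse_resnet")
}

#' Architecture description
#'
#' An inspectable, serializable summary of the built network: ordered layer
#' records plus the structural counts (trunk Conv2D layers, residual
#' blocks, SE dense layers, auxiliary inputs, output dimension) used for
#' verification against the printed design.
#'
#' @param model a `dse_resnet`.
#' @return an `architecture_description`: list with `layers` (data frame)
#'   and the summary counts.
#' @export
describe <- function(model) {
  cfg <- model$config
  rows <- list()
  add <- function(kind, kernel = NA, c_in = NA, c_out = NA, stride = NA,
                  pooling = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, kernel = kernel, c_in = c_in, c_out = c_out,
      stride = stride, pooling = pooling, stringsAsFactors = FALSE)
  }
  for (b in seq_along(model$blocks)) {
    bl <- model$blocks[[b]]
    add("conv2d", cfg$kernel, bl$c_in, bl$c_out, bl$stride)
    add("batch_norm", c_in = bl$c_out, c_out = bl$c_out)
    add("relu"); add("dropout")
    add("conv2d", cfg$kernel, bl$c_out, bl$c_out, 1L)
    add("batch_norm", c_in = bl$c_out, c_out = bl$c_out)
    add("relu"); add("dropout")
    add("shortcut_add", c_in = bl$c_in, c_out = bl$c_out, stride = bl$stride,
        pooling = if (bl$stride == 2L) "maxpool(2,1)" else "identity")
  }
  add("global_avg_pool")
  for (ly in model$se) add("dense", c_in = ly$c_in, c_out = ly$c_out)
  add("se_rescale")
  add("time_avg_pool_flatten_leads")
  if (cfg$use_age_sex) add("concat_age_sex")
  add("dense", c_in = model$head$fc1$c_in, c_out = model$head$fc1$c_out)
  add("relu")
  add("dense", c_in = model$head$fc2$c_in, c_out = model$head$fc2$c_out)
  add("softmax")
  layers <- do.call(rbind, rows)
  structure(list(
    layers = layers,
    total_conv2d = sum(layers$kind == "conv2d"),
    residual_blocks = length(model$blocks),
    block1_count = sum(vapply(model$blocks, function(b)
      b$stride == 1L, logical(1))),
    block2_count = sum(vapply(model$blocks, function(b)
      b$stride == 2L, logical(1))),
    kernel = c(cfg$kernel, 1L),
    channel_schedule = cfg$channels,
    dse_dense_layers = length(model$se),
    aux_inputs = cfg$use_age_sex,
    output_dim = cfg$n_classes,
    downsample_factor = 2L^(cfg$n_blocks - 1L)),
    class = "architecture_description")
}

#' @export
print.architecture_description <- function(x, ...) {
  cat(sprintf(paste0("<architecture_description> %d trunk conv2d, ",
                     "%d residual blocks (%d + %d), kernel (%d, 1)\n"),
              x$total_conv2d, x$residual_blocks, x$block1_count,
              x$block2_count, x$kernel[1L]))
  cat(sprintf("  channels: %s; DSE dense layers: %d; aux inputs: %s; out: %d\n",
              paste(x$channel_schedule, collapse = "-"), x$dse_dense_layers,
              x$aux_inputs, x$output_dim))
  invisible(x)
}

#' Serialize / deserialize an architecture description
#'
#' @param description an `architecture_description`.
#' @return `description_to_json()`: a JSON string;
#'   `description_from_json()`: the parsed `architecture_description`.
#' @export
description_to_json <- function(description) {
  jsonlite::toJSON(unclass(description), dataframe = "columns",
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname description_to_json
#' @param json JSON string produced by `description_to_json()`.
#' @export
description_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$layers <- as.data.frame(x$layers, stringsAsFactors = FALSE)
  for (nm in c("total_conv2d", "residual_blocks", "block1_count",
               "block2_count", "dse_dense_layers", "output_dim",
               "downsample_factor", "kernel", "channel_schedule")) {
    x[[nm]] <- as.integer(x[[nm]])
  }
  structure(x, class = "architecture_description")
}

#' Number of trainable parameters
#'
#' @param model a `dse_resnet`.
#' @return integer count of trainable scalars (convolution and dense
#'   weights and biases, batch-norm scales and shifts).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$param_layers, function(ly) {
    switch(ly$type,
           conv = length(ly$b) + sum(vapply(ly$W, length, 0L)),
           dense = length(ly$W) + length(ly$b),
           bn = 2L * length(ly$gamma),
           0L)
  }, numeric(1)))
}

# --- batches ---------------------------------------------------------------

encode_aux <- function(age, sex, age_fill) {
  age_n <- ifelse(is.na(age), age_fill, age / 100)
  sex_n <- ifelse(is.na(sex), 0.5, ifelse(sex == "male", 1, 0))
  cbind(age = age_n, sex = sex_n)
}

#' Assemble a batch from preprocessed slices
#'
#' Stacks `two_dim_slice` objects into the engine's (T * B) x 1 matrix
#' layout.  When the model input is shorter than the slice (reduced,
#' desk-scale configurations) the slice is decimated by an integer factor.
#'
#' @param slices list of `two_dim_slice` objects (from
#'   [preprocess_record()]).
#' @param model a `dse_resnet`.
#' @return a `batch` list with `X`, `N`, `age`, `sex`, `labels`
#'   (integer class indices or `NA`).
#' @export
make_batch <- function(slices, model) {
  cfg <- model$config
  S <- dim(slices[[1L]]$values)[1L]
  if (S %% cfg$input_len != 0L) {
    stop(sprintf("slice length %d is not a multiple of model input %d",
                 S, cfg$input_len))
  }
  f <- S %/% cfg$input_len
  keep <- seq(1L, S, by = f)
  cols <- lapply(slices, function(sl) {
    v <- sl$values[keep, , 1L, drop = FALSE]
    as.vector(v)
  })
  X <- matrix(unlist(cols), ncol = 1L)
  age <- vapply(slices, function(s) as.numeric(s$age %||% NA_real_), 0)
  sex <- vapply(slices, function(s) as.character(s$sex %||% NA_character_), "")
  labels <- vapply(slices, function(s) {
    if (is.null(s$label) || is.na(s$label)) NA_integer_
    else match(s$label, ecg_classes())
  }, 0L)
  list(X = X, N = length(slices), age = age, sex = sex, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full forward pass.  Returns probabilities plus (in training mode) the
# caches needed by dse_backward().
dse_forward <- function(model, batch, train = FALSE) {
  cfg <- model$config
  N <- batch$N
  B <- cfg$n_leads * N
  X <- batch$X
  T <- cfg$input_len
  sc_caches <- vector("list", length(model$blocks))
  for (b in seq_along(model$blocks)) {
    bl <- model$blocks[[b]]
    id_X <- X; id_T <- T
    r <- conv_fwd(bl$conv1, X, T, B); X <- r$Y; T <- r$T
    X <- bn_fwd(bl$bn1, X, train)
    X <- relu_fwd(bl$relu1, X, train)
    X <- dropout_fwd(bl$do1, X, train)
    r <- conv_fwd(bl$conv2, X, T, B); X <- r$Y
    X <- bn_fwd(bl$bn2, X, train)
    X <- relu_fwd(bl$relu2, X, train)
    X <- dropout_fwd(bl$do2, X, train)
    if (bl$stride == 2L) {
      pc <- pool_fwd(id_X, id_T, bl$c_out)
      X <- X + pc$Y
      sc_caches[[b]] <- pc
    } else {
      sc <- id_X
      if (bl$c_out > bl$c_in) {
        sc <- cbind(sc, matrix(0, nrow(sc), bl$c_out - bl$c_in))
      }
      X <- X + sc
      sc_caches[[b]] <- list(identity = TRUE, c_in = bl$c_in)
    }
  }
  C <- ncol(X)
  rows_per_sample <- T * cfg$n_leads
  grp <- rep(seq_len(N), each = rows_per_sample)
  # squeeze: one scalar per channel per sample (pool over time AND lead)
  G <- rowsum(X, grp) / rows_per_sample
  Z <- G
  se_pre <- vector("list", length(model$se))
  for (i in seq_along(model$se)) {
    Z <- dense_fwd(model$se[[i]], Z, train)
    if (i < length(model$se)) {
      se_pre[[i]] <- Z > 0
      Z <- Z * se_pre[[i]]
    }
  }
  gate <- 1 / (1 + exp(-Z))
  gate_rows <- gate[grp, , drop = FALSE]
  Xs <- X * gate_rows
  # head features: pool over time only, keep the 12 leads distinct so the
  # dense head can weight leads differently (inter-lead structure)
  grp_series <- rep(seq_len(B), each = T)
  M <- rowsum(Xs, grp_series) / T            # B x C, series-major
  F1 <- matrix(t(M), nrow = N, byrow = TRUE) # N x (12 * C)
  F2 <- if (cfg$use_age_sex) {
    cbind(F1, encode_aux(batch$age, batch$sex, model$age_fill))
  } else F1
  H <- dense_fwd(model$head$fc1, F2, train)
  H <- relu_fwd(model$head$relu, H, train)
  logits <- dense_fwd(model$head$fc2, H, train)
  probs <- softmax_rows(logits)
  cache <- if (train) {
    list(sc_caches = sc_caches, X_trunk = X, gate = gate,
         gate_rows = gate_rows, se_pre = se_pre, grp = grp,
         grp_series = grp_series, rows_per_sample = rows_per_sample,
         N = N, B = B, T = T, C = C)
  }
  list(probs = probs, cache = cache)
}

dse_backward <- function(model, batch, probs, cache) {
  cfg <- model$config
  N <- cache$N
  Y <- matrix(0, N, cfg$n_classes)
  Y[cbind(seq_len(N), batch$labels)] <- 1
  dlogits <- (probs - Y) / N
  dH <- dense_bwd(model$head$fc2, dlogits)
  dH <- relu_bwd(model$head$relu, dH)
  dF2 <- dense_bwd(model$head$fc1, dH)
  C <- cache$C
  dF1 <- dF2[, seq_len(cfg$n_leads * C), drop = FALSE]
  rps <- cache$rows_per_sample
  grp <- cache$grp
  dM <- matrix(t(dF1), ncol = C, byrow = TRUE)       # back to B x C
  dXs <- dM[cache$grp_series, , drop = FALSE] / cache$T
  dX <- dXs * cache$gate_rows
  dgate <- rowsum(dXs * cache$X_trunk, grp)
  dZ <- dgate * cache$gate * (1 - cache$gate)
  for (i in rev(seq_along(model$se))) {
    if (i < length(model$se)) dZ <- dZ * cache$se_pre[[i]]
    dZ <- dense_bwd(model$se[[i]], dZ)
  }
  dG <- dZ
  dX <- dX + dG[grp, , drop = FALSE] / rps
  for (b in rev(seq_along(model$blocks))) {
    bl <- model$blocks[[b]]
    sc <- cache$sc_caches[[b]]
    d_main <- dropout_bwd(bl$do2, dX)
    d_main <- relu_bwd(bl$relu2, d_main)
    d_main <- bn_bwd(bl$bn2, d_main)
    d_main <- conv_bwd(bl$conv2, d_main)
    d_main <- dropout_bwd(bl$do1, d_main)
    d_main <- relu_bwd(bl$relu1, d_main)
    d_main <- bn_bwd(bl$bn1, d_main)
    d_main <- conv_bwd(bl$conv1, d_main)
    d_sc <- if (bl$stride == 2L) {
      pool_bwd(sc, dX)
    } else {
      dX[, seq_len(sc$c_in), drop = FALSE]
    }
    dX <- d_main + d_sc
  }
  invisible(NULL)
}

#' Forward pass: class probabilities for a batch of slices
#'
#' @param model a `dse_resnet`.
#' @param slices list of `two_dim_slice` objects, or a prebuilt batch from
#'   [make_batch()].
#' @return N x 9 matrix of class probabilities (rows sum to 1), columns
#'   named by [ecg_classes()].
#' @export
predict_slices <- function(model, slices) {
  batch <- if (is.list(slices) && !is.null(slices$X)) slices
  else make_batch(slices, model)
  p <- dse_forward(model, batch, train = FALSE)$probs
  colnames(p) <- ecg_classes()[seq_len(model$config$n_classes)]
  p
}

#' Softmax cross-entropy loss of the model on a batch
#'
#' The training criterion: the mean over the batch of the negative log
#' probability assigned to the reference label.  A uniform predictor over
#' 9 classes scores `log(9)`.
#'
#' @param model a `dse_resnet`.
#' @param slices slices or a prebuilt batch with labels.
#' @return scalar loss.
#' @export
model_loss <- function(model, slices) {
  batch <- if (is.list(slices) && !is.null(slices$X)) slices
  else make_batch(slices, model)
  if (anyNA(batch$labels)) stop("all slices must be labeled")
  p <- dse_forward(model, batch, train = FALSE)$probs
  cross_entropy(p, batch$labels)
}

cross_entropy <- function(probs, labels) {
  -mean(log(pmax(probs[cbind(seq_along(labels), labels)], 1e-12)))
}

#' One SGD-with-momentum training step on a batch
#'
#' @param model a `dse_resnet`.
#' @param batch a labeled batch from [make_batch()].
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @return the batch loss before the update, invisibly mutating the model.
#' @export
train_step <- function(model, batch, lr, momentum) {
  fw <- dse_forward(model, batch, train = TRUE)
  loss <- cross_entropy(fw$probs, batch$labels)
  dse_backward(model, batch, fw$probs, fw$cache)
  sgd_step(model$param_layers, lr, momentum)
  loss
}
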