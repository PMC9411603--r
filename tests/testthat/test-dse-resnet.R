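test_that("the default build matches the printed architecture", {
  bd <- build_dse_resnet(model_config())
  d <- bd$description
  expect_equal(d$total_conv2d, 20)
  expect_equal(d$residual_blocks, 10)
  expect_equal(d$block1_count, 1)
  expect_equal(d$block2_count, 9)
  expect_equal(d$kernel, c(32L, 1L))
  expect_equal(d$channel_schedule, c(12L, 24L, 48L, 96L, 192L))
  expect_equal(d$dse_dense_layers, 4)
  expect_true(d$aux_inputs)
  expect_equal(d$output_dim, 9)
  expect_equal(d$downsample_factor, 512)  # 8192 -> 16

  convs <- d$layers[d$layers$kind == "conv2d", ]
  expect_true(all(convs$kernel == 32))
  expect_equal(convs$c_out[nrow(convs)], 192)   # last trunk conv
  expect_equal(convs$c_out[1], 12)              # first trunk conv
  # kernels double every 4 conv layers
  expect_equal(rle(convs$c_out)$lengths, rep(4L, 5L))
  expect_equal(rle(convs$c_out)$values, c(12L, 24L, 48L, 96L, 192L))
})

test_that("builds are reproducible and parameter counts behave", {
  cfg <- reduced_model_config()
  a <- build_dse_resnet(cfg)
  b <- build_dse_resnet(cfg)
  expect_equal(count_parameters(a$model), count_parameters(b$model))
  expect_identical(a$model$blocks[[1]]$conv1$W, b$model$blocks[[1]]$conv1$W)

  wide <- reduced_model_config()
  wide$channels <- c(8L, 16L)
  expect_gt(count_parameters(build_dse_resnet(wide)$model),
            count_parameters(a$model))
})

test_that("the architecture description survives JSON serialization", {
  d <- build_dse_resnet(reduced_model_config())$description
  back <- description_from_json(description_to_json(d))
  expect_equal(back$total_conv2d, d$total_conv2d)
  expect_equal(back$residual_blocks, d$residual_blocks)
  expect_equal(back$dse_dense_layers, d$dse_dense_layers)
  expect_equal(back$channel_schedule, d$channel_schedule)
  expect_equal(back$layers$kind, d$layers$kind)
})

test_that("builds reject input lengths that cannot be downsampled", {
  expect_error(model_config(input_len = 8000), "divisible")
  expect_error(model_config(input_len = 260, channels = c(4, 8)),
               "divisible")
})

test_that("forward output rows are probability vectors", {
  m <- build_dse_resnet(reduced_model_config())$model
  slices <- separable_slices(per_class = 2)[1:4]
  p <- predict_slices(m, slices)
  expect_identical(dim(p), c(4L, 9L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-5)

  # identical slices give identical rows (deterministic eval mode)
  p2 <- predict_slices(m, slices[c(1, 1)])
  expect_equal(p2[1, ], p2[2, ])
})

test_that("the age/sex auxiliary inputs can be ablated", {
  cfg <- reduced_model_config()
  cfg_no <- model_config(input_len = 256, kernel = 8, channels = c(4, 8),
                         dropout = 0, head_hidden = 16, use_age_sex = FALSE,
                         seed = 1)
  bd <- build_dse_resnet(cfg_no)
  expect_false(bd$description$aux_inputs)
  slices <- separable_slices(per_class = 2)[1:2]
  p <- predict_slices(bd$model, slices)
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-5)

  # with aux on, changing age changes the output; with aux off it cannot
  m_aux <- build_dse_resnet(cfg)$model
  s_young <- slices[[1]]; s_young$age <- 20
  s_old <- slices[[1]]; s_old$age <- 90
  expect_false(isTRUE(all.equal(predict_slices(m_aux, list(s_young)),
                                predict_slices(m_aux, list(s_old)))))
  expect_equal(predict_slices(bd$model, list(s_young)),
               predict_slices(bd$model, list(s_old)))
})

test_that("a uniform predictor scores ln 9 under the training loss", {
  # zero the final-layer weights so logits are constant -> uniform softmax
  m <- build_dse_resnet(reduced_model_config())$model
  m$head$fc2$W[] <- 0
  m$head$fc2$b[] <- 0
  slices <- separable_slices(per_class = 2)[1:5]
  expect_equal(model_loss(m, slices), log(9), tolerance = 1e-9)
})

test_that("one SGD step reduces the loss on the same batch", {
  m <- build_dse_resnet(reduced_model_config())$model
  slices <- separable_slices(per_class = 4)
  batch <- make_batch(slices[1:12], m)
  with_fixed_seed(3, {
    fw0 <- dseresnet:::dse_forward(m, batch, train = TRUE)
    l0 <- dseresnet:::cross_entropy(fw0$probs, batch$labels)
    train_step(m, batch, lr = 0.02, momentum = 0)
    fw1 <- dseresnet:::dse_forward(m, batch, train = TRUE)
    l1 <- dseresnet:::cross_entropy(fw1$probs, batch$labels)
    expect_lt(l1, l0)
  })
})

test_that("the network is sensitive to lead order", {
  m <- build_dse_resnet(reduced_model_config())$model
  slices <- separable_slices(per_class = 2)
  # a few steps so weights are not at their symmetric init
  with_fixed_seed(4, for (i in 1:5) {
    train_step(m, make_batch(slices[1:8], m), lr = 0.05, momentum = 0.7)
  })
  s <- slices[[1]]
  sp <- s
  sp$values <- s$values[, c(2:12, 1), , drop = FALSE]  # rotate leads
  p1 <- predict_slices(m, list(s))
  p2 <- predict_slices(m, list(sp))
  expect_gt(max(abs(p1 - p2)), 1e-6)
})

test_that("analytic gradients match finite differences on a tiny net", {
  cfg <- model_config(input_len = 8, n_leads = 2, n_classes = 3,
                      kernel = 3, channels = c(2, 3), blocks_per_stage = 1,
                      dropout = 0, head_hidden = 4, se_reduction = 1,
                      seed = 7)
  m <- dseresnet:::build_impl_seeded(cfg)
  slice_vals <- with_fixed_seed(8, array(stats::rnorm(8 * 2), c(8, 2, 1)))
  batch <- list(X = matrix(as.vector(slice_vals), ncol = 1), N = 1L,
                age = 50, sex = "male", labels = 2L)
  loss_of <- function() {
    fw <- dseresnet:::dse_forward(m, batch, train = TRUE)
    dseresnet:::cross_entropy(fw$probs, batch$labels)
  }
  fw <- dseresnet:::dse_forward(m, batch, train = TRUE)
  dseresnet:::dse_backward(m, batch, fw$probs, fw$cache)
  eps <- 1e-5
  # check a sample of conv, dense and bn parameters
  checks <- list(
    list(get = function() m$blocks[[2]]$conv1$W[[1]][1, 1],
         set = function(v) m$blocks[[2]]$conv1$W[[1]][1, 1] <- v,
         grad = function() m$blocks[[2]]$conv1$gW[[1]][1, 1]),
    list(get = function() m$se[[1]]$W[1, 1],
         set = function(v) m$se[[1]]$W[1, 1] <- v,
         grad = function() m$se[[1]]$gW[1, 1]),
    list(get = function() m$head$fc1$W[2, 1],
         set = function(v) m$head$fc1$W[2, 1] <- v,
         grad = function() m$head$fc1$gW[2, 1]),
    list(get = function() m$blocks[[1]]$bn1$gamma[1],
         set = function(v) m$blocks[[1]]$bn1$gamma[1] <- v,
         grad = function() m$blocks[[1]]$bn1$ggamma[1]))
  for (chk in checks) {
    v0 <- chk$get()
    chk$set(v0 + eps); lp <- loss_of()
    chk$set(v0 - eps); lm <- loss_of()
    chk$set(v0)
    expect_equal(unname(chk$grad()), (lp - lm) / (2 * eps),
                 tolerance = 1e-3)
  }
})
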