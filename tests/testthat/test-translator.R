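test_that("model building is seed-deterministic with a fixed parameter count", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(digest::digest(m1$params), digest::digest(m2$params))
  m3 <- build_model(tiny_model_config(seed = 12))
  expect_false(identical(digest::digest(m1$params),
                         digest::digest(m3$params)))
  expect_error(model_config(hidden_units = 0), "positive")
  expect_error(model_config(dropout_rate = 1.5), "dropout")
})

test_that("forward pass preserves length for arbitrary input lengths", {
  m <- build_model(tiny_model_config())
  for (T in c(3, 32, 100, 2048)) {
    x <- make_feature_stack(sin(seq_len(T) / 7))
    y <- ppg2abp:::lstm_forward_cpp(m$params, x)
    expect_identical(dim(y), c(as.integer(T), 1L))
    expect_true(all(is.finite(y)))
  }
})

test_that("backpropagation-through-time gradients agree with finite differences", {
  set.seed(3)
  T <- 9; B <- 2
  X <- array(rnorm(T * 2 * B), c(T, 2, B))
  Y <- array(rnorm(T * 1 * B), c(T, 1, B))
  p0 <- ppg2abp:::lstm_init_cpp(c(2L, 3L, 3L), 3L, 1L, 5L)
  loss_of <- function(p) {
    pr <- ppg2abp:::lstm_predict_cpp(p, X, 8L)
    mean((pr - Y)^2)
  }
  G <- ppg2abp:::lstm_grad_cpp(p0, X, Y)
  eps <- 1e-6
  probe <- function(get, set) {
    p_hi <- set(p0, get(p0) + eps)
    p_lo <- set(p0, get(p0) - eps)
    (loss_of(p_hi) - loss_of(p_lo)) / (2 * eps)
  }
  # a selection of parameters from every tensor family
  cases <- list(
    list(g = function(p) p$layers[[1]]$Wx[2, 5],
         s = function(p, v) { p$layers[[1]]$Wx[2, 5] <- v; p },
         a = G$layers[[1]]$Wx[2, 5]),
    list(g = function(p) p$layers[[2]]$Wh[1, 8],
         s = function(p, v) { p$layers[[2]]$Wh[1, 8] <- v; p },
         a = G$layers[[2]]$Wh[1, 8]),
    list(g = function(p) p$layers[[1]]$b[4],
         s = function(p, v) { p$layers[[1]]$b[4] <- v; p },
         a = G$layers[[1]]$b[4]),
    list(g = function(p) p$W[2, 1],
         s = function(p, v) { p$W[2, 1] <- v; p },
         a = G$W[2, 1]),
    list(g = function(p) p$b[1],
         s = function(p, v) { p$b[1] <- v; p },
         a = G$b[1]))
  for (cs in cases)
    expect_equal(probe(cs$g, cs$s), cs$a, tolerance = 1e-5)
})

test_that("reconstruction training reduces the loss and is seed-reproducible", {
  set.seed(21)
  stacks <- lapply(1:24, function(i)
    make_feature_stack(sin(2 * pi * (1:48) / runif(1, 8, 16))))
  m <- build_model(tiny_model_config(max_epochs = 8))
  out <- train_reconstruction(m, stacks)
  expect_lt(tail(out$report$train_loss, 1), out$report$initial_train_loss)
  expect_lt(tail(out$report$train_loss, 1),
            0.5 * out$report$initial_train_loss)
  out2 <- train_reconstruction(m, stacks)
  expect_identical(out$report$param_digest, out2$report$param_digest)
  expect_identical(out$report$train_loss, out2$report$train_loss)
})

test_that("zero-epoch training is a no-op returning the initialization", {
  m <- build_model(tiny_model_config())
  before <- digest::digest(m$params)
  out <- train_reconstruction(m, tiny_task(4)$stacks, epochs = 0)
  expect_identical(digest::digest(out$model$params), before)
  expect_length(out$report$train_loss, 0)
})

test_that("the frozen encoder is bit-identical across translation training", {
  task <- tiny_task(16)
  m <- build_model(tiny_model_config(max_epochs = 4))
  m <- train_reconstruction(m, task$stacks)$model
  m <- freeze_encoder(m)
  expect_identical(m$stage, "translation")
  expect_true(m$encoder_frozen)
  expect_identical(freeze_encoder(m), m)  # idempotent

  enc_before <- encoder_digest(m)
  dec_before <- decoder_digest(m)
  out <- train_translation(m, task$stacks, task$targets)
  expect_identical(encoder_digest(out$model), enc_before)
  expect_false(identical(decoder_digest(out$model), dec_before))
})

test_that("translation training refuses an unfrozen encoder", {
  task <- tiny_task(4)
  m <- build_model(tiny_model_config())
  expect_error(train_translation(m, task$stacks, task$targets), "frozen")
})

test_that("translate maps PPG to mmHg with length preservation and needs the sidecar", {
  task <- tiny_task(16)
  m <- build_model(tiny_model_config(max_epochs = 4))
  m <- freeze_encoder(train_reconstruction(m, task$stacks)$model)
  m <- train_translation(m, task$stacks, task$targets)$model
  expect_error(translate(m, rnorm(100)), "sidecar|norm")

  norm <- list(ppg = list(mu_bar = 0, sigma_bar = 1),
               abp = list(mu_bar = 100, sigma_bar = 20), step_h = 1 / 125)
  for (T in c(64, 200)) {
    y <- translate(m, rnorm(T), norm)
    expect_length(y, T)
    expect_true(all(is.finite(y)))
  }
  expect_error(translate(m, c(1, 2), norm), "too short")
})

test_that("checkpoints round trip the model", {
  m <- build_model(tiny_model_config())
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(digest::digest(back$params), digest::digest(m$params))
  expect_identical(back$config, m$config)
})
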