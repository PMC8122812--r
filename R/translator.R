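#' Model configuration for the LSTM autoencoder translator
#'
#' Defaults follow the reference training setup: two LSTM layers of 128
#' hidden nodes in each phase (encoder and decoder), a dropout layer of rate
#' 0.2 at the end of the decoding phase, learning rate 0.0025 with the Adam
#' optimizer, and at most 50 training epochs.  Every field can be overridden
#' for desk-scale runs.
#'
#' @param hidden_units Hidden nodes per LSTM layer.
#' @param encoder_layers,decoder_layers Stacked LSTM layers per phase.
#' @param dropout_rate Dropout rate applied to the last decoder layer's
#'   output during training.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Epoch cap per training stage.
#' @param batch_size Mini-batch size (segments).
#' @param input_channels Input channels (PPG, dPPG, sdPPG).
#' @param output_channels Output channels (one waveform).
#' @param patience Early-stopping patience on validation loss (epochs); 0
#'   disables early stopping.
#' @param grad_clip Global gradient-norm clip (0 disables).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A validated `model_config` list.
#' @export
model_config <- function(hidden_units = 128, encoder_layers = 2,
                         decoder_layers = 2, dropout_rate = 0.2,
                         learning_rate = 0.0025, max_epochs = 50,
                         batch_size = 128, input_channels = 3,
                         output_channels = 1, patience = 5, grad_clip = 5,
                         seed = 42L) {
  cfg <- list(hidden_units = as.integer(hidden_units),
              encoder_layers = as.integer(encoder_layers),
              decoder_layers = as.integer(decoder_layers),
              dropout_rate = dropout_rate, learning_rate = learning_rate,
              max_epochs = as.integer(max_epochs),
              batch_size = as.integer(batch_size),
              input_channels = as.integer(input_channels),
              output_channels = as.integer(output_channels),
              patience = as.integer(patience), grad_clip = grad_clip,
              seed = as.integer(seed))
  bad <- character()
  for (f in c("hidden_units", "encoder_layers", "decoder_layers",
              "max_epochs", "batch_size", "input_channels",
              "output_channels"))
    if (cfg[[f]] < if (f == "max_epochs") 0 else 1)
      bad <- c(bad, sprintf("%s must be positive", f))
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    bad <- c(bad, "dropout_rate must be in [0, 1)")
  if (cfg$learning_rate <= 0) bad <- c(bad, "learning_rate must be positive")
  if (length(bad))
    stop("invalid model_config: ", paste(bad, collapse = "; "),
         call. = FALSE)
  class(cfg) <- "model_config"
  cfg
}

#' Build an untrained translator model
#'
#' The encoder maps the `(T x 3)` feature stack to a per-timestep latent
#' sequence `(T x hidden_units)`; the decoder maps the latent sequence back
#' to a single waveform channel through a per-timestep linear head.  The
#' latent representation is the full hidden-state sequence rather than a
#' single bottleneck vector, so the model emits same-length output for any
#' input length.
#'
#' @param config A [model_config()].
#' @return A `translator_model` in the `"reconstruction"` stage with an
#'   unfrozen encoder.  Initialization is deterministic in `config$seed`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  n_layers <- config$encoder_layers + config$decoder_layers
  layer_inputs <- c(config$input_channels,
                    rep(config$hidden_units, n_layers - 1))
  params <- lstm_init_cpp(as.integer(layer_inputs), config$hidden_units,
                          config$output_channels, config$seed)
  structure(list(params = params, config = config, stage = "reconstruction",
                 encoder_frozen = FALSE, norm = NULL, history = list()),
            class = "translator_model")
}

#' @export
print.translator_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<translator_model> stage=%s encoder_frozen=%s | %d+%d LSTM layers x %d units, %d->%d channels\n",
    x$stage, x$encoder_frozen, cfg$encoder_layers, cfg$decoder_layers,
    cfg$hidden_units, cfg$input_channels, cfg$output_channels))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

encoder_layer_idx <- function(model) seq_len(model$config$encoder_layers)

decoder_layer_idx <- function(model) {
  cfg <- model$config
  cfg$encoder_layers + seq_len(cfg$decoder_layers)
}

encoder_params <- function(model) {
  list(layers = model$params$layers[encoder_layer_idx(model)], W = NULL,
       b = NULL)
}

decoder_params <- function(model) {
  list(layers = model$params$layers[decoder_layer_idx(model)],
       W = model$params$W, b = model$params$b)
}

# list of (T x C) matrices or (T, C, N) array -> cube array
as_stack_array <- function(stacks, channels = NULL) {
  if (is.array(stacks) && length(dim(stacks)) == 3) return(stacks)
  if (is.matrix(stacks)) stacks <- list(stacks)
  stopifnot(is.list(stacks), length(stacks) >= 1)
  d <- dim(stacks[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(stacks)))
  for (i in seq_along(stacks)) arr[, , i] <- stacks[[i]]
  arr
}

# targets: list of vectors or (T x N) matrix -> (T, 1, N) array
as_target_array <- function(targets) {
  if (is.array(targets) && length(dim(targets)) == 3) return(targets)
  if (is.list(targets)) targets <- do.call(cbind, targets)
  if (is.vector(targets)) targets <- matrix(targets, ncol = 1)
  array(targets, dim = c(nrow(targets), 1, ncol(targets)))
}

empty_cube <- function(channels) array(0, dim = c(0, channels, 0))

run_training <- function(params, X, Y, Xval, Yval, config, epochs, seed) {
  lstm_train_cpp(params, X, Y, Xval, Yval, as.integer(epochs),
                 config$batch_size, config$learning_rate,
                 config$dropout_rate, as.integer(seed), config$patience,
                 config$grad_clip)
}

train_report <- function(fit, stage) {
  structure(list(stage = stage, train_loss = fit$train_loss,
                 val_loss = fit$val_loss, best_epoch = fit$best_epoch,
                 stopped_early = fit$stopped_early,
                 initial_train_loss = fit$initial_train_loss,
                 initial_val_loss = fit$initial_val_loss,
                 param_digest = digest::digest(fit$params)),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf(
    "<train_report %s> %d epochs (best %d%s) loss %.5g -> %.5g\n",
    x$stage, length(x$train_loss), x$best_epoch,
    if (x$stopped_early) ", early stop" else "",
    x$initial_train_loss,
    if (length(x$train_loss)) tail(x$train_loss, 1) else
      x$initial_train_loss))
  invisible(x)
}

#' Parameter digests
#'
#' Hashes over the exact parameter values; used to verify the
#' frozen-encoder contract bit-for-bit.
#'
#' @param model A `translator_model`.
#' @return Character hash.
#' @export
encoder_digest <- function(model) digest::digest(encoder_params(model))

#' @rdname encoder_digest
#' @export
decoder_digest <- function(model) digest::digest(decoder_params(model))

# ---- training stages --------------------------------------------------------

#' Stage 1: train the autoencoder to reconstruct the PPG waveform
#'
#' The model is trained to reproduce channel 1 (the PPG itself) of each
#' feature stack from the full 3-channel input, teaching the encoder a
#' latent representation of PPG morphology.
#'
#' @param model A `translator_model` in the `"reconstruction"` stage.
#' @param stacks Training feature stacks: list of `(T x 3)` matrices or a
#'   `(T, 3, N)` array.
#' @param val_stacks Optional validation stacks (enables early stopping).
#' @param epochs Number of epochs (default `config$max_epochs`).
#' @return List with the updated `model` and a `train_report` (per-epoch
#'   training/validation losses, best epoch, early-stop flag, parameter
#'   digest).
#' @export
train_reconstruction <- function(model, stacks, val_stacks = NULL,
                                 epochs = model$config$max_epochs) {
  stopifnot(inherits(model, "translator_model"))
  if (model$stage != "reconstruction")
    stop("model is not in the reconstruction stage", call. = FALSE)
  X <- as_stack_array(stacks)
  Y <- array(X[, 1, , drop = FALSE], dim = c(dim(X)[1], 1, dim(X)[3]))
  if (!is.null(val_stacks)) {
    Xv <- as_stack_array(val_stacks)
    Yv <- array(Xv[, 1, , drop = FALSE], dim = c(dim(Xv)[1], 1, dim(Xv)[3]))
  } else {
    Xv <- empty_cube(dim(X)[2]); Yv <- empty_cube(1)
  }
  fit <- run_training(model$params, X, Y, Xv, Yv, model$config, epochs,
                      model$config$seed + 1L)
  model$params <- fit$params
  report <- train_report(fit, "reconstruction")
  model$history$reconstruction <- report
  list(model = model, report = report)
}

#' Freeze the encoder and switch to the translation stage
#'
#' After the reconstruction stage the encoding layers are frozen —
#' bit-identical before and after any subsequent training — and only the
#' decoding layers (carried over, not re-initialized) plus the linear head
#' keep learning, now against ABP targets.  Idempotent.
#'
#' @param model A `translator_model`.
#' @return The model with `encoder_frozen = TRUE` and
#'   `stage = "translation"`.
#' @export
freeze_encoder <- function(model) {
  stopifnot(inherits(model, "translator_model"))
  model$encoder_frozen <- TRUE
  model$stage <- "translation"
  model
}

#' Stage 2: train the decoder to emit the ABP waveform
#'
#' Requires a frozen encoder (preventing silent full fine-tuning).  The
#' frozen encoder's latent sequences are computed once and the decoding
#' layers are optimized against the normalized ABP targets.
#'
#' @param model A frozen `translator_model` (see [freeze_encoder()]).
#' @param stacks Training feature stacks (as in [train_reconstruction()]).
#' @param targets Normalized ABP targets: list of vectors or `(T x N)`
#'   matrix, matching the stacks.
#' @param val_stacks,val_targets Optional validation pairs.
#' @param epochs Number of epochs.
#' @return List with the updated `model` and a `train_report`.
#' @export
train_translation <- function(model, stacks, targets, val_stacks = NULL,
                              val_targets = NULL,
                              epochs = model$config$max_epochs) {
  stopifnot(inherits(model, "translator_model"))
  if (!isTRUE(model$encoder_frozen))
    stop("encoder must be frozen before translation training; ",
         "call freeze_encoder() first", call. = FALSE)
  enc_before <- encoder_digest(model)
  X <- as_stack_array(stacks)
  Y <- as_target_array(targets)
  L <- lstm_predict_cpp(encoder_params(model), X, model$config$batch_size)
  if (!is.null(val_stacks)) {
    Xv <- as_stack_array(val_stacks)
    Lv <- lstm_predict_cpp(encoder_params(model), Xv,
                           model$config$batch_size)
    Yv <- as_target_array(val_targets)
  } else {
    Lv <- empty_cube(model$config$hidden_units); Yv <- empty_cube(1)
  }
  fit <- run_training(decoder_params(model), L, Y, Lv, Yv, model$config,
                      epochs, model$config$seed + 2L)
  model$params$layers[decoder_layer_idx(model)] <- fit$params$layers
  model$params$W <- fit$params$W
  model$params$b <- fit$params$b
  stopifnot(identical(enc_before, encoder_digest(model)))
  report <- train_report(fit, "translation")
  model$history$translation <- report
  list(model = model, report = report)
}

#' Translate a PPG signal into an ABP waveform in mmHg
#'
#' The PPG is scaled with the global (training-averaged) normalization
#' parameters, expanded into the 3-channel feature stack, passed through the
#' network, and the output is inverted from normalized units back to mmHg
#' with the global ABP parameters.  Input of any length at least 3 is
#' supported and the output always matches the input length.
#'
#' @param model A trained translation-stage `translator_model`.
#' @param ppg Preprocessed (filtered, aligned) PPG signal, pre-normalization.
#' @param norm Normalization sidecar: list with elements `ppg` and `abp`,
#'   each a `list(mu_bar, sigma_bar)` from [fit_global_norm()], and `step_h`.
#'   Defaults to `model$norm` (set by the pipeline after training).
#' @return Predicted ABP waveform in mmHg, same length as `ppg`.
#' @export
translate <- function(model, ppg, norm = model$norm) {
  stopifnot(inherits(model, "translator_model"))
  if (model$stage != "translation")
    stop("model has not been trained for translation", call. = FALSE)
  if (is.null(norm))
    stop("normalization parameters are required: supply `norm` or attach ",
         "them to the model (missing sidecar)", call. = FALSE)
  if (length(ppg) < 3) stop("input too short to translate", call. = FALSE)
  x <- (ppg - norm$ppg$mu_bar) / norm$ppg$sigma_bar
  stack <- make_feature_stack(x, norm$step_h)
  y <- lstm_forward_cpp(model$params, stack)[, 1]
  invert_zscore(y, norm$abp)
}

#' Save / load a translator model checkpoint
#'
#' Checkpoints carry parameters, configuration, stage, frozen flag, the
#' normalization sidecar, and training history.
#'
#' @param model A `translator_model`.
#' @param path Checkpoint file path (RDS).
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "translator_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "translator_model")
}
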