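#' @title Window classifiers and transfer learning
#' @description Three small deep architectures for fixed-length sensor
#'   windows — CNN-LSTM (input, two convolutions, two LSTMs, dense softmax:
#'   six layers), a ResNet-style stack (input plus repeated blocks of three
#'   convolutions, batch normalization and an activation with an identity /
#'   projection skip), and DeepConvLSTM (input, four convolutions, two LSTMs,
#'   dense softmax: eight layers) — trained with Adam on categorical
#'   cross-entropy. Every model starts with an input standardization stage
#'   that scales each feature column by statistics of the training set.
#'   Transfer learning freezes all layers except the final dense layer and
#'   retrains briefly on a new subject's data.
#' @name models
NULL

#' Specify a model
#'
#' @param name Architecture: `"cnn_lstm"`, `"resnet"` or `"deepconvlstm"`.
#' @param window_len Window length in samples.
#' @param n_features Feature columns per sample.
#' @param classes Character vector of activity classes (output width).
#' @param filters Convolution filter count (default 32; the layer counts,
#'   not the widths, are the architectural contract).
#' @param units Recurrent units per LSTM layer (default 32).
#' @param kernel Convolution kernel length in samples (default 5).
#' @param seed Integer seed for deterministic initialization.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name = c("cnn_lstm", "resnet", "deepconvlstm"),
                       window_len, n_features, classes,
                       filters = 32L, units = 32L, kernel = 5L, seed = 1L) {
  name <- match.arg(name)
  classes <- as.character(classes)
  if (length(classes) < 2L) stop("need at least 2 classes")
  structure(list(name = name, window_len = as.integer(window_len),
                 n_features = as.integer(n_features), classes = classes,
                 n_classes = length(classes), filters = as.integer(filters),
                 units = as.integer(units), kernel = as.integer(kernel),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Instantiate an (untrained) model from a specification
#'
#' Layer stacks:
#' \itemize{
#'   \item cnn_lstm: input standardization, conv, conv, lstm, lstm,
#'     dense softmax — 6 layers.
#'   \item deepconvlstm: input standardization, conv x4, lstm x2,
#'     dense softmax — 8 layers.
#'   \item resnet: input standardization, two residual blocks (each: conv,
#'     conv, conv, batch-norm, activation, with an identity or 1x1-projection
#'     skip), global average pooling, dense softmax.
#' }
#' Initialization is deterministic under the spec seed.
#'
#' @param spec A `model_spec`.
#' @return Object of class `har_model`.
#' @export
build_architecture <- function(spec) {
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec")
  Fin <- spec$n_features; Fl <- spec$filters; U <- spec$units; K <- spec$kernel
  C <- spec$n_classes
  layers <- with_seed(spec$seed, switch(
    spec$name,
    cnn_lstm = list(
      input = .layer_input_norm(Fin),
      conv1 = .layer_conv1d(K, Fin, Fl),
      conv2 = .layer_conv1d(K, Fl, Fl),
      lstm1 = .layer_lstm(Fl, U, return_seq = TRUE),
      lstm2 = .layer_lstm(U, U, return_seq = FALSE),
      dense_softmax = .layer_dense(U, C)),
    deepconvlstm = list(
      input = .layer_input_norm(Fin),
      conv1 = .layer_conv1d(K, Fin, Fl),
      conv2 = .layer_conv1d(K, Fl, Fl),
      conv3 = .layer_conv1d(K, Fl, Fl),
      conv4 = .layer_conv1d(K, Fl, Fl),
      lstm1 = .layer_lstm(Fl, U, return_seq = TRUE),
      lstm2 = .layer_lstm(U, U, return_seq = FALSE),
      dense_softmax = .layer_dense(U, C)),
    resnet = list(
      input = .layer_input_norm(Fin),
      block1 = .layer_resblock(K, Fin, Fl),
      block2 = .layer_resblock(K, Fl, Fl),
      gap = .layer_gap(),
      dense_softmax = .layer_dense(Fl, C))
  ))
  structure(list(spec = spec, layers = layers,
                 trainable = .default_trainable(layers),
                 log = numeric(0), step = 0L),
            class = "har_model")
}

.default_trainable <- function(layers) {
  vapply(layers, function(l) isTRUE(l$trainable), logical(1))
}

#' Layer names of a model, in order
#' @param model A `har_model`.
#' @return Character vector.
#' @export
architecture_layers <- function(model) names(model$layers)

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("<har_model> %s: %d x %d -> %d classes (%s)\n",
              x$spec$name, x$spec$window_len, x$spec$n_features,
              x$spec$n_classes,
              if (length(x$log)) sprintf("trained %d epoch(s), last loss %.4f",
                                         length(x$log), utils::tail(x$log, 1))
              else "untrained"))
  cat("  layers:", paste(names(x$layers), collapse = " -> "), "\n")
  frozen <- names(x$layers)[!x$trainable &
                              vapply(x$layers, function(l) isTRUE(l$trainable),
                                     logical(1))]
  if (length(frozen)) cat("  frozen:", paste(frozen, collapse = ", "), "\n")
  invisible(x)
}

.model_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  out <- X
  for (i in seq_along(model$layers)) {
    # frozen batch-norm runs in inference mode (no batch stats, no updates)
    r <- .layer_forward(model$layers[[i]], out,
                        training && model$trainable[i])
    out <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$new_running)) {
      if (model$layers[[i]]$type == "batchnorm") {
        model$layers[[i]]$running_mean <- r$new_running$mean
        model$layers[[i]]$running_var <- r$new_running$var
      } else if (model$layers[[i]]$type == "resblock") {
        model$layers[[i]]$bn$running_mean <- r$new_running$mean
        model$layers[[i]]$bn$running_var <- r$new_running$var
      }
    }
  }
  list(scores = out, caches = caches, model = model)
}

.fit_input_norm <- function(model, X) {
  il <- which(vapply(model$layers, function(l) l$type == "input_norm",
                     logical(1)))
  if (length(il) && !model$layers[[il]]$fitted) {
    Xm <- .mat2(X)
    mu <- colMeans(Xm)
    sd <- sqrt(colMeans(sweep(Xm, 2L, mu, "-")^2))
    sd[sd < 1e-8] <- 1
    model$layers[[il]]$mu <- mu
    model$layers[[il]]$sd <- sd
    model$layers[[il]]$fitted <- TRUE
  }
  model
}

.dataset_targets <- function(model, dataset) {
  tg <- match(dataset$labels, model$spec$classes)
  if (anyNA(tg)) {
    stop("unseen class label(s): ",
         paste(unique(dataset$labels[is.na(tg)]), collapse = ", "))
  }
  tg
}

#' Train a model
#'
#' Mini-batch Adam on categorical cross-entropy (the same loss as
#' [cross_entropy()]). Only layers whose trainable flag is set change; the
#' training log gains one mean-loss entry per epoch. Deterministic for a
#' fixed seed and dataset.
#'
#' @param model A `har_model`.
#' @param dataset A `windowed_dataset` matching the model's input shape.
#' @param epochs Number of passes over the data.
#' @param lr Learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Seed for batch shuffling; defaults to the spec seed.
#' @return The updated `har_model`.
#' @export
train <- function(model, dataset, epochs, lr = 1e-4, batch_size = 32L,
                  seed = model$spec$seed) {
  if (n_windows(dataset) == 0L) stop("dataset is empty")
  d <- dim(dataset$X)
  if (d[2L] != model$spec$window_len || d[3L] != model$spec$n_features) {
    stop(sprintf("window shape %d x %d does not match model input %d x %d",
                 d[2L], d[3L], model$spec$window_len, model$spec$n_features))
  }
  targets <- .dataset_targets(model, dataset)
  model <- .fit_input_norm(model, dataset$X)
  if (epochs == 0L) return(model)
  n <- d[1L]
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b0 in seq(1L, n, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, n)]
        Xb <- dataset$X[bi, , , drop = FALSE]
        yb <- targets[bi]
        fw <- .model_forward(model, Xb, training = TRUE)
        model <- fw$model
        losses <- c(losses, .ce_batch(fw$scores, yb))
        # softmax cross-entropy gradient
        P <- .softmax_rows(fw$scores)
        P[cbind(seq_along(yb), yb)] <- P[cbind(seq_along(yb), yb)] - 1
        dOut <- P / length(yb)
        model$step <- model$step + 1L
        if (!any(model$trainable)) next
        min_tr <- min(which(model$trainable))
        for (i in rev(seq_along(model$layers))) {
          if (i < min_tr) break  # nothing below needs gradients
          bw <- .layer_backward(model$layers[[i]], fw$caches[[i]], dOut)
          if (model$trainable[i]) {
            model$layers[[i]] <- .layer_update(model$layers[[i]], bw$grads,
                                               lr, model$step)
          }
          if (i > 1L) dOut <- bw$dX
        }
      }
      model$log <- c(model$log, mean(losses))
    }
  })
  model
}

#' Classify one window
#'
#' @param model A trained `har_model`.
#' @param window Numeric matrix `window_len x n_features` (the -1 sentinel is
#'   allowed in pose columns).
#' @return List with `label` (argmax class, lowest index on ties) and
#'   `probabilities` (named, summing to 1).
#' @export
classify_window <- function(model, window) {
  window <- as.matrix(window)
  if (nrow(window) != model$spec$window_len ||
      ncol(window) != model$spec$n_features) {
    stop(sprintf("window shape %d x %d does not match model input %d x %d",
                 nrow(window), ncol(window),
                 model$spec$window_len, model$spec$n_features))
  }
  X <- array(window, c(1L, dim(window)))
  fw <- .model_forward(model, X, training = FALSE)
  p <- drop(.softmax_rows(fw$scores))
  names(p) <- model$spec$classes
  list(label = model$spec$classes[which.max(p)], probabilities = p)
}

#' Predict labels for a windowed dataset
#'
#' @param object A `har_model`.
#' @param dataset A `windowed_dataset`.
#' @param ... Unused.
#' @return List with `labels` and `probabilities` (n x C matrix).
#' @export
predict.har_model <- function(object, dataset, ...) {
  n <- n_windows(dataset)
  if (n == 0L) return(list(labels = character(0),
                           probabilities = matrix(0, 0, object$spec$n_classes)))
  fw <- .model_forward(object, dataset$X, training = FALSE)
  P <- .softmax_rows(fw$scores)
  colnames(P) <- object$spec$classes
  list(labels = object$spec$classes[max.col(P, ties.method = "first")],
       probabilities = P)
}

#' Fine-tune a model on a new subject's data (transfer learning)
#'
#' All layers except the final dense layer are frozen for the run; the head
#' is retrained for a few epochs on the new data. The new data are split into
#' a training and a held-out portion (by whole recordings when several are
#' present, mirroring a leave-recordings-out split; otherwise by windows),
#' and classification reports before and after fine-tuning on the held-out
#' portion are returned — the on-device "confusion matrix before and after"
#' view.
#'
#' @param model A pretrained `har_model`.
#' @param new_data A `windowed_dataset` whose classes are a subset of the
#'   model's.
#' @param epochs Fine-tuning epochs (default 10).
#' @param batch_size Mini-batch size (default 7).
#' @param lr Learning rate for the head (default 1e-3).
#' @param train_ratio Fraction of the new data used for fine-tuning
#'   (default 0.8).
#' @param seed Seed for the split and shuffling.
#' @return Object of class `har_finetune`: list with `model`, `before`,
#'   `after` (both `eval_report`s) and the index split.
#' @export
fine_tune <- function(model, new_data, epochs = 10L, batch_size = 7L,
                      lr = 1e-3, train_ratio = 0.8, seed = model$spec$seed) {
  .dataset_targets(model, new_data)  # validates the class set
  n <- n_windows(new_data)
  if (n < 2L) stop("need at least 2 windows to fine-tune")
  recs <- unique(new_data$recording_id)
  split <- NULL
  if (length(recs) >= 2L) {
    split <- tryCatch(
      leave_recordings_out_split(new_data, train_ratio, seed)$folds[[1L]],
      error = function(e) NULL)  # too few recordings to honor the ratio
  }
  if (is.null(split)) {
    idx <- with_seed(seed, sample.int(n))
    ntr <- max(1L, min(n - 1L, round(train_ratio * n)))
    split <- list(train = sort(idx[seq_len(ntr)]), test = sort(idx[-seq_len(ntr)]))
  }
  tr <- subset_windows(new_data, split$train)
  te <- subset_windows(new_data, split$test)
  before <- evaluate(predict(model, te)$labels, te$labels,
                     classes = model$spec$classes)
  old_flags <- model$trainable
  last <- length(model$layers)
  model$trainable <- rep(FALSE, last)
  model$trainable[last] <- TRUE
  model <- train(model, tr, epochs = epochs, lr = lr,
                 batch_size = batch_size, seed = seed)
  model$trainable <- old_flags
  after <- evaluate(predict(model, te)$labels, te$labels,
                    classes = model$spec$classes)
  structure(list(model = model, before = before, after = after,
                 split = split),
            class = "har_finetune")
}

#' @export
print.har_finetune <- function(x, ...) {
  cat(sprintf("<har_finetune> held-out accuracy %.3f -> %.3f (macro F1 %.3f -> %.3f)\n",
              x$before$accuracy, x$after$accuracy,
              x$before$macro_f1, x$after$macro_f1))
  invisible(x)
}

# flatten every parameter array of a model (composite layers included)
.model_params <- function(model) {
  out <- list()
  grab <- function(layer, prefix) {
    if (layer$type == "resblock") {
      for (sub in c("conv1", "conv2", "conv3", "bn", "proj")) {
        if (!is.null(layer[[sub]])) grab(layer[[sub]], paste0(prefix, ".", sub))
      }
      return(invisible())
    }
    for (nm in names(layer$params)) {
      out[[paste0(prefix, ".", nm)]] <<- layer$params[[nm]]
    }
  }
  for (i in seq_along(model$layers)) {
    grab(model$layers[[i]], names(model$layers)[i])
  }
  out
}

#' Save a model checkpoint
#'
#' JSON key-value container: the spec, the per-layer parameter arrays (with
#' dimensions), trainable flags, normalization statistics and the training
#' log. Full double precision; round-trips exactly through [load_model()].
#'
#' @param model A `har_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  enc_arr <- function(a) list(dim = dim(a) %||% length(a), data = as.vector(a))
  enc_layer <- function(layer) {
    o <- list(type = layer$type,
              params = lapply(layer$params, enc_arr))
    for (f in c("k", "units", "return_seq", "activation", "momentum", "eps",
                "mu", "sd", "fitted", "running_mean", "running_var")) {
      if (!is.null(layer[[f]])) o[[f]] <- layer[[f]]
    }
    if (layer$type == "resblock") {
      for (sub in c("conv1", "conv2", "conv3", "bn", "proj")) {
        if (!is.null(layer[[sub]])) o[[sub]] <- enc_layer(layer[[sub]])
      }
    }
    o
  }
  obj <- list(spec = unclass(model$spec),
              trainable = as.list(model$trainable),
              log = model$log, step = model$step,
              layers = lapply(model$layers, enc_layer))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return A `har_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  spec <- obj$spec
  spec <- model_spec(spec$name, spec$window_len, spec$n_features,
                     unlist(spec$classes), spec$filters, spec$units,
                     spec$kernel, spec$seed)
  dec_arr <- function(e) {
    d <- unlist(e$dim)
    v <- unlist(e$data)
    if (length(d) > 1L) array(v, d) else v
  }
  dec_layer <- function(el) {
    l <- list(type = el$type,
              trainable = el$type %in% c("conv1d", "lstm", "batchnorm",
                                         "dense", "resblock"),
              params = lapply(el$params, dec_arr))
    for (f in c("k", "units", "return_seq", "activation", "momentum", "eps",
                "fitted")) {
      if (!is.null(el[[f]])) l[[f]] <- el[[f]]
    }
    for (f in c("mu", "sd", "running_mean", "running_var")) {
      if (!is.null(el[[f]])) l[[f]] <- unlist(el[[f]])
    }
    if (el$type == "resblock") {
      for (sub in c("conv1", "conv2", "conv3", "bn", "proj")) {
        if (!is.null(el[[sub]])) l[[sub]] <- dec_layer(el[[sub]])
      }
      if (is.null(el$proj)) l["proj"] <- list(NULL)
    }
    l
  }
  layers <- lapply(obj$layers, dec_layer)
  structure(list(spec = spec, layers = layers,
                 trainable = unlist(obj$trainable),
                 log = as.numeric(unlist(obj$log)),
                 step = as.integer(obj$step %||% 0L)),
            class = "har_model")
}
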