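# Layer-spec constructors. Shapes are resolved at build time for a fixed
# input size; weights live in plain matrices handed to the C++ engine.

conv_out <- function(n, k, s, p) floor((n + 2 * p - k) / s) + 1

conv_layer <- function(in_c, out_c, k = 3, stride = 1, pad = 1, act = "relu") {
  list(type = "conv", in_c = in_c, out_c = out_c, k = k, stride = stride,
       pad = pad, act = act)
}
tconv_layer <- function(in_c, out_c, k = 3, stride = 2, pad = 1,
                        output_padding = 0, act = "relu") {
  list(type = "tconv", in_c = in_c, out_c = out_c, k = k, stride = stride,
       pad = pad, output_padding = output_padding, act = act)
}
fc_layer <- function(out_dim, act = "relu", drop = 0) {
  list(type = "fc", out_dim = out_dim, act = act, drop = drop)
}
gap_layer <- function() list(type = "gap", act = "none")
bnorm_layer <- function(act = "relu") list(type = "bnorm", act = act)
resblock_layer <- function(in_c, out_c, stride = 1) {
  list(type = "resblock", in_c = in_c, out_c = out_c, k = 3, stride = stride,
       pad = 1, act = "relu")
}

#' Network architecture specifications
#'
#' `depth_classifier_spec()` is a convolutional classifier over 20 depth bins:
#' a wide 9x9 first-stage convolution (blur width is a spatial-frequency
#' property, so the first stage needs large support), three 3x3 stages, global
#' average pooling over each feature map (depth is a global image property,
#' and pooling removes the positional degrees of freedom that would otherwise
#' be memorized) and a small fully connected head with dropout.
#' `encoder_decoder_spec()` is the 6-layer workhorse shared by the deblurring
#' and detection tasks: 3 strided convolutions then 3 transposed convolutions
#' restoring the 51x51 input size. `resnet_detector_spec()` is a residual
#' feature extractor (a first convolution plus eight two-convolution residual
#' blocks, stride 1 so the 2-convolution head can emit input-sized planes).
#'
#' @param channels convolution channel widths per stage.
#' @param fc width of the hidden fully connected layer.
#' @param dropout dropout probability on the hidden fully connected layer.
#' @param n_classes number of depth bins.
#' @param in_channels 1 for single-sensor input, 2 for the dual-sensor pair.
#' @param out_channels 1 (deblurring, depth map) or 4 (detector planes).
#' @param input_shape spatial input size.
#' @param width base channel width of the residual trunk.
#' @return A spec object consumed by the `train_*` functions.
#' @export
depth_classifier_spec <- function(channels = c(16, 32, 64, 64), fc = 96,
                                  n_classes = 20, in_channels = 1,
                                  dropout = 0.5, input_shape = c(51, 51)) {
  layers <- list(
    conv_layer(in_channels, channels[1], k = 9, stride = 2, pad = 4),
    conv_layer(channels[1], channels[2], stride = 2),
    conv_layer(channels[2], channels[3], stride = 2),
    conv_layer(channels[3], channels[4], stride = 1),
    gap_layer(),
    fc_layer(fc, act = "relu", drop = dropout),
    fc_layer(n_classes, act = "none"))
  structure(list(layers = layers, in_channels = in_channels,
                 input_shape = input_shape, out_dim = n_classes,
                 kind = "classifier"),
            class = "network_spec")
}

#' @rdname depth_classifier_spec
#' @export
encoder_decoder_spec <- function(in_channels = 1, out_channels = 1,
                                 channels = c(16, 32, 64),
                                 input_shape = c(51, 51)) {
  stopifnot(length(channels) == 3)
  # 51 -> 26 -> 13 -> 7 and back; output_padding restores the odd sizes
  sizes <- Reduce(function(n, .) conv_out(n, 3, 2, 1), 1:3,
                  accumulate = TRUE, init = input_shape[1])
  op <- function(target, from) target - ((from - 1) * 2 - 2 + 3)
  layers <- list(
    conv_layer(in_channels, channels[1], stride = 2),
    conv_layer(channels[1], channels[2], stride = 2),
    conv_layer(channels[2], channels[3], stride = 2),
    tconv_layer(channels[3], channels[2], stride = 2,
                output_padding = op(sizes[3], sizes[4])),
    tconv_layer(channels[2], channels[1], stride = 2,
                output_padding = op(sizes[2], sizes[3])),
    tconv_layer(channels[1], out_channels, stride = 2,
                output_padding = op(sizes[1], sizes[2]), act = "none"))
  structure(list(layers = layers, in_channels = in_channels,
                 input_shape = input_shape,
                 out_dim = prod(input_shape) * out_channels,
                 out_channels = out_channels, kind = "dense"),
            class = "network_spec")
}

#' @rdname depth_classifier_spec
#' @export
resnet_detector_spec <- function(in_channels = 2, out_channels = 4, width = 8,
                                 input_shape = c(51, 51)) {
  w <- width
  layers <- list(conv_layer(in_channels, w))
  plan <- c(w, w, 2 * w, 2 * w, 2 * w, 2 * w, 2 * w, 2 * w)
  c_in <- w
  for (ch in plan) {
    layers <- c(layers, list(resblock_layer(c_in, ch)))
    c_in <- ch
  }
  layers <- c(layers, list(conv_layer(c_in, w), # 2-conv detection head
                           conv_layer(w, out_channels, act = "none")))
  structure(list(layers = layers, in_channels = in_channels,
                 input_shape = input_shape,
                 out_dim = prod(input_shape) * out_channels,
                 out_channels = out_channels, kind = "dense"),
            class = "network_spec")
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# Resolve shapes and draw initial weights; returns the engine's layer list.
build_network <- function(spec, seed = 1) {
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  with_seed(seed, {
    layers <- list()
    for (l in spec$layers) {
      if (l$type == "conv") {
        oh <- conv_out(h, l$k, l$stride, l$pad)
        ow <- conv_out(w, l$k, l$stride, l$pad)
        l <- c(l, list(in_h = h, in_w = w, out_h = oh, out_w = ow))
        l$W <- he_init(l$out_c, l$in_c * l$k^2, l$in_c * l$k^2)
        l$b <- numeric(l$out_c)
        h <- oh; w <- ow
      } else if (l$type == "tconv") {
        oh <- (h - 1) * l$stride - 2 * l$pad + l$k + l$output_padding
        ow <- (w - 1) * l$stride - 2 * l$pad + l$k + l$output_padding
        # engine dims describe the equivalent conv: tconv output -> input
        l <- c(l, list(in_h = oh, in_w = ow, out_h = h, out_w = w))
        l$W <- he_init(l$in_c, l$out_c * l$k^2, l$in_c * l$k^2)
        l$b <- numeric(l$out_c)
        # engine convention: d.in_c = tconv out_c, d.out_c = tconv in_c
        tmp <- l$in_c; l$in_c <- l$out_c; l$out_c <- tmp
        h <- oh; w <- ow
      } else if (l$type == "gap") {
        l$in_h <- h; l$in_w <- w
        l$in_c <- prev_c(layers, spec$in_channels)
        h <- 1; w <- 1
      } else if (l$type == "bnorm") {
        l$in_h <- h; l$in_w <- w
        l$in_c <- prev_c(layers, spec$in_channels)
        l$gamma <- rep(1, l$in_c); l$beta <- rep(0, l$in_c)
        l$rmean <- rep(0, l$in_c); l$rvar <- rep(1, l$in_c)
      } else if (l$type == "fc") {
        in_dim <- h * w * prev_c(layers, spec$in_channels)
        if (length(layers) && layers[[length(layers)]]$type == "fc")
          in_dim <- layers[[length(layers)]]$out_dim
        l$W <- he_init(l$out_dim, in_dim, in_dim)
        l$b <- numeric(l$out_dim)
      } else if (l$type == "resblock") {
        oh <- conv_out(h, 3, l$stride, 1); ow <- conv_out(w, 3, l$stride, 1)
        l <- c(l, list(in_h = h, in_w = w, out_h = oh, out_w = ow))
        l$W <- he_init(l$out_c, l$in_c * 9, l$in_c * 9)
        l$b <- numeric(l$out_c)
        l$c2_in_c <- l$out_c; l$c2_out_c <- l$out_c; l$c2_k <- 3L
        l$c2_stride <- 1L; l$c2_pad <- 1L
        l$c2_in_h <- oh; l$c2_in_w <- ow; l$c2_out_h <- oh; l$c2_out_w <- ow
        l$W2 <- he_init(l$out_c, l$out_c * 9, l$out_c * 9)
        l$b2 <- numeric(l$out_c)
        l$has_proj <- l$stride != 1 || l$in_c != l$out_c
        if (l$has_proj) {
          l$p_in_c <- l$in_c; l$p_out_c <- l$out_c; l$p_k <- 1L
          l$p_stride <- l$stride; l$p_pad <- 0L
          l$p_in_h <- h; l$p_in_w <- w; l$p_out_h <- oh; l$p_out_w <- ow
          l$Wp <- he_init(l$out_c, l$in_c, l$in_c)
          l$bp <- numeric(l$out_c)
        }
        h <- oh; w <- ow
      }
      layers <- c(layers, list(l))
    }
    layers
  })
}

prev_c <- function(layers, in_channels) {
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") return(l$out_c)
    if (l$type == "tconv") return(l$in_c)     # engine convention: in_c = tconv out_c
    if (l$type == "resblock") return(l$out_c)
    if (l$type == "gap") return(l$in_c)
    if (l$type == "bnorm") return(l$in_c)
  }
  in_channels
}

#' Training configuration
#'
#' @param loss `"cross_entropy"`, `"mse"` or `"bce"`; each `train_*` function
#'   fixes the loss matching its task.
#' @param epochs,batch_size,learning_rate optimizer settings (Adam). A scalar
#'   `learning_rate` expands into a step-decay schedule (full rate for the
#'   first two thirds of the epochs, then 0.3x, then 0.1x for the final
#'   twelfth); a vector gives explicit per-epoch rates.
#' @param weight_decay decoupled L2 weight decay applied to convolution and
#'   dense weights (not biases); 0 disables it.
#' @param seed seed controlling weight initialization and batch shuffling.
#' @export
train_config <- function(loss = NULL, epochs = 30, batch_size = 32,
                         learning_rate = 1e-3, weight_decay = 0, seed = 1) {
  structure(list(loss = loss, epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = seed),
            class = "train_config")
}

# Shared seeded training driver. `n_members > 1` trains a deep ensemble
# (identical architecture, independent initializations and batch orders) whose
# predictions are averaged at inference.
fit_network <- function(spec, X, Y, loss, cfg, task, normalizer = "minmax",
                        n_members = 1) {
  n <- ncol(X)
  if (n < 1) abort("empty training set")
  members <- lapply(seq_len(n_members), function(mem) {
    seed <- child_seed(cfg$seed, (mem - 1) * 7017881L)
    layers <- build_network(spec, seed = seed)
    perm <- with_seed(child_seed(seed, 7919),
                      vapply(seq_len(cfg$epochs), function(e) sample.int(n),
                             integer(n))) - 1L
    storage.mode(perm) <- "integer"
    lr <- lr_schedule(cfg$learning_rate, cfg$epochs)
    cpp_nn_train(layers, X, Y, loss, cfg$epochs,
                 as.integer(cfg$batch_size), lr,
                 matrix(perm, nrow = n),
                 weight_decay = cfg$weight_decay %||% 0,
                 rng_seed = child_seed(seed, 104729))
  })
  history <- tibble::tibble(
    epoch = rep(seq_len(cfg$epochs), n_members),
    member = rep(seq_len(n_members), each = cfg$epochs),
    loss = unlist(lapply(members, function(m) as.numeric(m$history))))
  structure(list(spec = spec, layers = members[[1]]$layers,
                 members = lapply(members, `[[`, "layers"),
                 history = history,
                 loss = loss, config = cfg, task = task, n_train = n,
                 normalizer = normalizer),
            class = c(paste0("cs3d_", task), "cs3d_model"))
}

#' Train the depth-classification network
#'
#' Learns to assign a blurred single-layer acquisition to one of 20 depth
#' bins (50 to 1950 micrometers in 100 micrometer steps).
#'
#' @param data a depth dataset from [build_depth_dataset()] (its `train`
#'   element), or any list of samples with `view` and `depth_class`.
#' @param cfg a [train_config()].
#' @param n_members ensemble size: members differ only in initialization and
#'   batch order; their class probabilities are averaged at inference.
#'   Ensembling stabilizes the depth estimate noticeably in the small-data
#'   regime.
#' @return A fitted `cs3d_depth` model with a per-epoch loss history.
#' @export
train_depth_classifier <- function(data, cfg = train_config(),
                                   n_members = 1) {
  samples <- dataset_samples(data)
  if (!length(samples)) abort("empty training set")
  classes <- vapply(samples, `[[`, numeric(1), "depth_class")
  if (length(unique(classes)) < 2) abort("need at least 2 depth classes")
  X <- views_to_matrix(samples, "mean_relative")
  Y <- matrix(0, 20, length(samples))
  Y[cbind(classes + 1, seq_along(samples))] <- 1
  fit_network(depth_classifier_spec(), X, Y, "cross_entropy", cfg, "depth",
              normalizer = "mean_relative", n_members = n_members)
}

#' Train the deblurring network
#'
#' Encoder-decoder regression from the blurred acquisition to the unblurred
#' phantom, both min-max normalized to \[0, 1\].
#'
#' @param data output of [build_deblur_dataset()].
#' @param cfg a [train_config()].
#' @export
train_deblur_net <- function(data, cfg = train_config()) {
  samples <- dataset_samples(data)
  if (!length(samples)) abort("empty training set")
  X <- views_to_matrix(samples)
  Y <- vapply(samples, function(s) as.numeric(normalize_view(s$target)),
              numeric(length(samples[[1]]$target)))
  fit_network(encoder_decoder_spec(1, 1, channels = c(24, 48, 96)),
              X, Y, "mse", cfg, "deblur")
}

#' Train the two-layer depth-map network
#'
#' Encoder-decoder regression from a two-layer composite acquisition to a
#' per-pixel normalized depth map (0 on background).
#'
#' @param data output of [build_nonoverlap_dataset()].
#' @param cfg a [train_config()].
#' @export
train_depth_mapper <- function(data, cfg = train_config()) {
  samples <- dataset_samples(data)
  if (!length(samples)) abort("empty training set")
  X <- views_to_matrix(samples)
  Y <- vapply(samples, function(s) as.numeric(s$depth_map),
              numeric(length(samples[[1]]$depth_map)))
  fit_network(encoder_decoder_spec(1, 1, channels = c(24, 48, 96)),
              X, Y, "mse", cfg, "depthmap")
}

#' Train a multi-layer cell detector
#'
#' Maps one (single-sensor) or two (dual-sensor) acquisitions to four
#' per-pixel cell-presence probability planes, one per layer ordered by
#' distance from sensor A. Trained with per-pixel binary cross-entropy.
#'
#' @param data output of [build_overlap_dataset()].
#' @param spec an [encoder_decoder_spec()] (default) or
#'   [resnet_detector_spec()]; input channels must match the dataset.
#' @param cfg a [train_config()].
#' @export
train_detector <- function(data, spec = NULL, cfg = train_config()) {
  samples <- dataset_samples(data)
  if (!length(samples)) abort("empty training set")
  n_ch <- if (!is.null(samples[[1]]$view_b)) 2L else 1L
  if (is.null(spec)) spec <- encoder_decoder_spec(n_ch, 4)
  if (spec$in_channels != n_ch)
    abort(sprintf("spec expects %d input channel(s), dataset provides %d",
                  spec$in_channels, n_ch), class = "config_error")
  X <- views_to_matrix(samples)
  Y <- vapply(samples, function(s)
    as.numeric(unlist(s$label_planes, use.names = FALSE)),
    numeric(4 * length(samples[[1]]$label_planes[[1]])))
  fit_network(spec, X, Y, "bce", cfg, "detector")
}

dataset_samples <- function(data) {
  if (!is.null(data$samples)) data$samples else data
}

# A scalar learning rate expands into the default step-decay schedule:
# full rate for the first two thirds of training, 0.3x until eleven twelfths,
# 0.1x for the tail. An explicit vector is recycled as given.
lr_schedule <- function(learning_rate, epochs) {
  if (length(learning_rate) > 1) return(rep_len(learning_rate, epochs))
  e1 <- floor(2 * epochs / 3)
  e2 <- floor(11 * epochs / 12)
  learning_rate * c(rep(1, e1), rep(0.3, e2 - e1), rep(0.1, epochs - e2))
}

# Stack per-sample normalized views into the engine's (features x N) matrix.
# "minmax" maps each view to [0, 1] (dense prediction tasks); "mean_relative"
# divides by the view mean (depth classification, where absolute contrast is
# the physical depth cue and min-max scaling would discard it).
views_to_matrix <- function(samples, normalizer = "minmax") {
  norm1 <- if (normalizer == "mean_relative") mean_relative_view else normalize_view
  one <- function(s) {
    v <- as.numeric(norm1(s$view))
    if (!is.null(s$view_b)) v <- c(v, as.numeric(norm1(s$view_b)))
    v
  }
  vapply(samples, one, numeric(length(one(samples[[1]]))))
}

#' Predict from a fitted model
#'
#' Pure seeded inference. Depth models return a tibble of class predictions;
#' deblurring returns non-negative images; detectors return four probability
#' planes per sample (values in \[0, 1\]).
#'
#' @param object a fitted `cs3d_model`.
#' @param newdata a dataset or list of samples as used in training.
#' @param ... unused.
#' @export
predict.cs3d_model <- function(object, newdata, ...) {
  samples <- dataset_samples(newdata)
  X <- views_to_matrix(samples, object$normalizer %||% "minmax")
  exp_in <- prod(object$spec$input_shape) * object$spec$in_channels
  if (nrow(X) != exp_in)
    abort(sprintf("input has %d features, model expects %d", nrow(X), exp_in))
  members <- object$members %||% list(object$layers)
  h <- object$spec$input_shape[1]; w <- object$spec$input_shape[2]
  if (object$task == "depth") {
    P <- 0
    for (layers in members) {
      O <- cpp_nn_forward(layers, X, 64L)
      P <- P + apply(O, 2, function(z) { z <- exp(z - max(z)); z / sum(z) })
    }
    cls <- apply(P, 2, which.max) - 1L
    return(tibble::tibble(sample = seq_along(cls), depth_class = cls,
                          depth_um = 50 + 100 * cls))
  }
  O <- cpp_nn_forward(object$layers, X, 64L)
  switch(object$task,
    deblur = lapply(seq_len(ncol(O)), function(j)
      matrix(pmax(O[, j], 0), h, w)),
    depthmap = lapply(seq_len(ncol(O)), function(j)
      matrix(pmin(pmax(O[, j], 0), 1), h, w)),
    detector = lapply(seq_len(ncol(O)), function(j) {
      p <- 1 / (1 + exp(-O[, j]))
      lapply(0:3, function(k) matrix(p[(k * h * w + 1):((k + 1) * h * w)], h, w))
    }))
}

#' @export
print.cs3d_model <- function(x, ...) {
  cat(sprintf("<cs3d_model task=%s | %d layers | n_train=%d | final loss %.4g>\n",
              x$task, length(x$layers), x$n_train,
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Broom-style accessors for fitted models
#'
#' `tidy()` returns the per-epoch training-loss table; `glance()` a one-row
#' model summary.
#'
#' @param x a fitted `cs3d_model`.
#' @param ... unused.
#' @export
tidy.cs3d_model <- function(x, ...) x$history

#' @rdname tidy.cs3d_model
#' @export
glance.cs3d_model <- function(x, ...) {
  tibble::tibble(task = x$task, n_train = x$n_train,
                 epochs = max(x$history$epoch),
                 final_loss = utils::tail(x$history$loss, 1),
                 loss = x$loss)
}

#' @rdname tidy.cs3d_model
#' @param object a fitted `cs3d_model` (for `autoplot`).
#' @export
autoplot.cs3d_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = paste0("training loss (", object$loss, ")"))
}

#' @importFrom ggplot2 .data
NULL
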