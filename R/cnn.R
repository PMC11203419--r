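# VGG-style CNN classifier over channel combinations, following the classic
# R modelling idiom: ifc_cnn() fits and returns a classed object with
# predict/print/summary/plot methods.

#' CNN model specification
#'
#' @param channel_combo One of the seven combination names (see
#'   [ifc_channel_combos()]) or a character vector of channel ids drawn
#'   from Ch01/Ch06/Ch07.
#' @param input_size Square network input side in pixels (at most 150;
#'   must be divisible by `2^conv_blocks`).
#' @param conv_blocks Number of conv+maxpool blocks.
#' @param filters Filter counts per block (length `conv_blocks`).
#' @param convs_per_block Convolutions per block.
#' @param dense_width Width of the dense layer.
#' @param learning_rate,batch_size,max_epochs Adam optimiser settings.
#' @param patience,min_delta Early stopping: training stops once validation
#'   accuracy has improved by less than `min_delta` for `patience` epochs;
#'   the best-validation-epoch weights are retained.
#' @param seed Seed for weight initialisation and data order.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(channel_combo = "BF+DNA",
                     input_size = 32L,
                     conv_blocks = 3L,
                     filters = c(8L, 16L, 32L),
                     convs_per_block = 1L,
                     dense_width = 64L,
                     learning_rate = 1e-3,
                     batch_size = 32L,
                     max_epochs = 30L,
                     patience = 5L,
                     min_delta = 0.002,
                     seed = 1L) {
  combos <- ifc_channel_combos()
  if (length(channel_combo) == 1 && channel_combo %in% names(combos)) {
    combo_name <- channel_combo
    channels <- combos[[channel_combo]]
  } else {
    channels <- intersect(c("Ch01", "Ch06", "Ch07"), channel_combo)
    if (length(channels) == 0 || !setequal(channels, channel_combo))
      stop("channel_combo must be a non-empty subset of Ch01/Ch06/Ch07 ",
           "or one of: ", paste(names(combos), collapse = ", "),
           call. = FALSE)
    ic <- ifc_image_channels()
    combo_name <- paste(names(ic)[ic %in% channels], collapse = "+")
  }
  if (input_size > 150)
    stop("input_size must be at most 150 pixels", call. = FALSE)
  if (input_size %% 2^conv_blocks != 0)
    stop("input_size must be divisible by 2^conv_blocks", call. = FALSE)
  if (length(filters) != conv_blocks)
    stop("filters must have one entry per block", call. = FALSE)
  structure(list(
    combo_name = combo_name,
    channels = channels,
    input_size = as.integer(input_size),
    conv_blocks = as.integer(conv_blocks),
    filters = as.integer(filters),
    convs_per_block = as.integer(convs_per_block),
    dense_width = as.integer(dense_width),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    patience = as.integer(patience),
    min_delta = min_delta,
    seed = as.integer(seed)
  ), class = "cnn_spec")
}

#' Prepare one event's normalised network input
#'
#' Stacks the requested channels (fixed Ch01, Ch06, Ch07 subset order),
#' centres the image on the cell-mask centroid, crops or zero-pads
#' symmetrically to `input_size` and divides by `adc_max` so pixel values
#' lie in `[0, 1]`.
#'
#' @param event An `ifc_event`.
#' @param channels Channel ids to stack.
#' @param input_size Output side (pixels).
#' @param centroid Optional (row, col) cell centroid; computed from the
#'   brightfield mask when missing (frame centre for empty masks).
#' @return Numeric array `input_size x input_size x length(channels)`.
#' @export
prepare_input <- function(event, channels, input_size, centroid = NULL) {
  missing_ch <- setdiff(channels, names(event$channels))
  if (length(missing_ch))
    stop("event lacks channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  channels <- intersect(c("Ch01", "Ch06", "Ch07"), channels)
  if (is.null(centroid)) {
    cm <- cell_mask(event$channels[["Ch01"]])
    centroid <- if (cm$empty)
      c(nrow(cm$mask), ncol(cm$mask)) / 2
    else colMeans(which(cm$mask, arr.ind = TRUE))
  }
  ctr <- round(centroid)
  out <- array(0, dim = c(input_size, input_size, length(channels)))
  half <- input_size / 2
  for (k in seq_along(channels)) {
    x <- event$channels[[channels[k]]]
    # output pixel (i,j) reads input (i - half + ctr, j - half + ctr)
    rows_out <- seq_len(input_size)
    cols_out <- seq_len(input_size)
    rows_in <- rows_out - half + ctr[1]
    cols_in <- cols_out - half + ctr[2]
    vr <- rows_in >= 1 & rows_in <= nrow(x)
    vc <- cols_in >= 1 & cols_in <= ncol(x)
    out[rows_out[vr], cols_out[vc], k] <-
      x[rows_in[vr], cols_in[vc]] / event$adc_max
  }
  out
}

#' Prepare a batch of network inputs from a store
#'
#' @param store An `ifc_store`.
#' @param event_ids Events to include (default all), in this order.
#' @param channels Channel ids to stack.
#' @param input_size Output side (pixels).
#' @return Numeric array `input_size x input_size x C x N`.
#' @export
prepare_inputs <- function(store, event_ids = NULL, channels = c("Ch01"),
                           input_size = 32L) {
  ids <- vapply(store$events, `[[`, "", "event_id")
  if (is.null(event_ids)) event_ids <- ids
  pos <- match(event_ids, ids)
  if (anyNA(pos)) stop("unknown event id(s)", call. = FALSE)
  channels <- intersect(c("Ch01", "Ch06", "Ch07"), channels)
  n <- length(pos)
  out <- array(0, dim = c(input_size, input_size, length(channels), n))
  for (i in seq_len(n))
    out[, , , i] <- prepare_input(store$events[[pos[i]]], channels,
                                  input_size)
  out
}

#' Fit a CNN HSC/LSC classifier
#'
#' Trains the specified VGG-style network on prepared image stacks using
#' Adam and cross-entropy, with seeded initialisation and data order,
#' per-epoch train/validation accuracy curves, early stopping and
#' best-validation-epoch weight retention.
#'
#' @param x_train,x_val Arrays `H x W x C x N` as from [prepare_inputs()].
#' @param y_train,y_val Labels (`"HSC"`/`"LSC"`, or a factor).
#' @param spec A [cnn_spec()]; its `input_size` and channel count must
#'   match the arrays.
#' @return An `ifc_cnn` model object.
#' @export
ifc_cnn <- function(x_train, y_train, x_val, y_val, spec = cnn_spec()) {
  d <- dim(x_train)
  if (length(d) != 4) stop("x_train must be a 4-d array", call. = FALSE)
  if (d[1] != spec$input_size || d[2] != spec$input_size)
    stop("input array size does not match spec$input_size", call. = FALSE)
  if (d[3] != length(spec$channels))
    stop("channel count does not match the spec", call. = FALSE)
  if (length(y_train) != d[4] || length(y_val) != dim(x_val)[4])
    stop("label length does not match array", call. = FALSE)
  classes <- c("HSC", "LSC")
  yt <- match(as.character(y_train), classes) - 1L
  yv <- match(as.character(y_val), classes) - 1L
  if (anyNA(yt) || anyNA(yv))
    stop("labels must be HSC or LSC", call. = FALSE)
  fit <- .cnn_train_cpp(as.numeric(x_train), yt, as.numeric(x_val), yv,
                        dims = c(spec$input_size, spec$input_size, d[3]),
                        filters = spec$filters,
                        convs_per_block = spec$convs_per_block,
                        dense_width = spec$dense_width,
                        lr = spec$learning_rate,
                        batch_size = spec$batch_size,
                        max_epochs = spec$max_epochs,
                        patience = spec$patience,
                        min_delta = spec$min_delta,
                        seed = spec$seed)
  structure(list(
    spec = spec,
    weights = fit$weights,
    accuracy_curves = data.frame(epoch = seq_along(fit$train_acc),
                                 train = fit$train_acc,
                                 val = fit$val_acc),
    stopped_epoch = fit$stopped_epoch,
    best_epoch = fit$best_epoch,
    best_val_acc = fit$best_val_acc,
    classes = classes
  ), class = "ifc_cnn")
}

#' @export
print.ifc_cnn <- function(x, ...) {
  cat("IFC CNN classifier —", x$spec$combo_name, "model\n")
  cat(sprintf("  input %dx%dx%d | blocks %s | dense %d\n",
              x$spec$input_size, x$spec$input_size,
              length(x$spec$channels),
              paste(x$spec$filters, collapse = "/"), x$spec$dense_width))
  cat(sprintf("  stopped at epoch %d (best epoch %d, val accuracy %.4f)\n",
              x$stopped_epoch, x$best_epoch, x$best_val_acc))
  invisible(x)
}

#' @export
summary.ifc_cnn <- function(object, ...) {
  print(object)
  cat("Accuracy curves (last 5 epochs):\n")
  print(utils::tail(object$accuracy_curves, 5), row.names = FALSE)
  invisible(object)
}

#' Plot CNN accuracy curves
#' @param x An `ifc_cnn` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ifc_cnn <- function(x, ...) {
  ac <- x$accuracy_curves
  graphics::matplot(ac$epoch, cbind(ac$train, ac$val), type = "l",
                    lty = 1:2, col = c("black", "red3"),
                    xlab = "epoch", ylab = "accuracy",
                    main = paste(x$spec$combo_name, "model"), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("bottomright", c("train", "validation"),
                   lty = 1:2, col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Predict HSC/LSC labels
#'
#' @param object An `ifc_cnn` model.
#' @param newdata Array `H x W x C x N` as from [prepare_inputs()] (must
#'   match the model's channels), or an `ifc_store` from which inputs are
#'   prepared.
#' @param type `"class"` for labels with probabilities attached, `"prob"`
#'   for the probability matrix.
#' @param ... Unused.
#' @return Character labels with a `prob` attribute, or an `N x 2`
#'   probability matrix (rows sum to 1).
#' @export
predict.ifc_cnn <- function(object, newdata, type = c("class", "prob"),
                            ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ifc_store"))
    newdata <- prepare_inputs(newdata, channels = object$spec$channels,
                              input_size = object$spec$input_size)
  d <- dim(newdata)
  if (length(d) != 4 || d[1] != object$spec$input_size ||
      d[3] != length(object$spec$channels))
    stop("newdata does not match the model's input geometry/channels",
         call. = FALSE)
  probs <- .cnn_predict_cpp(object$weights, as.numeric(newdata),
                            dims = d[1:3],
                            convs_per_block = object$spec$convs_per_block)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  lab <- object$classes[(probs[, 2] > 0.5) + 1L]
  attr(lab, "prob") <- probs
  lab
}
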