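#' Sequence-model architecture configuration
#'
#' The default is the bilayer bidirectional LSTM with 200 hidden units per
#' layer and direction, a dropout layer of probability 0.40 between the two
#' recurrent layers, and a fully connected regression head: per time step
#' (4 outputs x 200 steps) for the curve head, or 4 scalars from the final
#' hidden states for the peak head.
#'
#' @param n_layers number of recurrent layers (default 2).
#' @param bidirectional logical (default TRUE).
#' @param hidden_units hidden units per layer and direction (default 200).
#' @param dropout_p dropout probability between recurrent layers, in `[0, 1)`.
#' @param head `"curve"` or `"peak"`.
#' @return list of class `model_config`.
#' @export
model_config <- function(n_layers = 2, bidirectional = TRUE,
                         hidden_units = 200, dropout_p = 0.40,
                         head = c("curve", "peak")) {
  head <- match.arg(head)
  assert_that(dropout_p >= 0 && dropout_p < 1, "dropout_p must be in [0, 1)")
  assert_that(hidden_units >= 1, "hidden_units must be >= 1")
  assert_that(n_layers >= 1, "n_layers must be >= 1")
  structure(list(n_layers = as.integer(n_layers),
                 bidirectional = isTRUE(bidirectional),
                 hidden_units = as.integer(hidden_units),
                 dropout_p = dropout_p, head = head),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with initial learning rate 0.002,
#' batch size 64, at most 40 epochs (to limit overfitting), mean-squared
#' error on min-max-normalized targets. The returned model uses the weights
#' from the epoch with minimum validation loss.
#'
#' @param learning_rate initial Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param seed integer seed for weight initialization, shuffling and dropout.
#' @return list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.002, batch_size = 64,
                            max_epochs = 40, seed = 1L) {
  assert_that(learning_rate > 0 && batch_size > 0 && max_epochs > 0,
              "all training parameters must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "training_config")
}

# internal: Glorot-uniform matrix
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained predictor
#'
#' Initializes all weights (Glorot-uniform, forget-gate biases at 1) for the
#' layer sequence BiLSTM -> dropout -> BiLSTM -> fully connected regression
#' head.
#'
#' @param config a [model_config()].
#' @param n_input_channels input rows, i.e. 6 x number of nodes.
#' @param n_outputs output channels (4 limbs).
#' @param seed integer seed for initialization.
#' @return list of class `grfz_predictor` with `params`, `config`,
#'   `n_input_channels`.
#' @export
build_network <- function(config, n_input_channels, n_outputs = 4, seed = 1L) {
  H <- config$hidden_units
  D <- if (config$bidirectional) 2L else 1L
  dirs <- if (config$bidirectional) c("f", "b") else "f"
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    for (l in seq_len(config$n_layers)) {
      I_l <- if (l == 1) n_input_channels else D * H
      for (d in dirs) {
        key <- function(w) sprintf("l%d%s_%s", l, d, w)
        p[[key("Wx")]] <- glorot(4 * H, I_l)
        p[[key("Wh")]] <- glorot(4 * H, H)
        b <- numeric(4 * H)
        b[(H + 1):(2 * H)] <- 1  # forget-gate bias
        p[[key("b")]] <- b
      }
    }
    p[["fc_W"]] <- glorot(n_outputs, D * H)
    p[["fc_b"]] <- numeric(n_outputs)
    p
  })
  structure(list(params = params, config = config,
                 n_input_channels = as.integer(n_input_channels),
                 n_outputs = as.integer(n_outputs)),
            class = "grfz_predictor")
}

#' Number of trainable parameters
#'
#' @param predictor a `grfz_predictor`.
#' @return integer parameter count.
#' @export
n_params <- function(predictor) {
  sum(vapply(predictor$params, length, numeric(1)))
}

# internal: forward pass on a (C x n x T) array, chunked to bound memory
net_forward <- function(predictor, X, masks = list()) {
  cfg <- predictor$config
  if (cfg$head == "curve") {
    res <- cpp_lstm_forward(X, predictor$params, masks, cfg$n_layers,
                            cfg$bidirectional, cfg$head)
    res$pred
  } else {
    cpp_lstm_forward(X, predictor$params, masks, cfg$n_layers,
                     cfg$bidirectional, cfg$head)$pred
  }
}

# internal: dropout masks (inverted scaling), one per between-layer gap
make_masks <- function(cfg, n, Tn) {
  if (cfg$dropout_p <= 0 || cfg$n_layers < 2) return(list())
  DH <- cfg$hidden_units * (if (cfg$bidirectional) 2 else 1)
  keep <- 1 - cfg$dropout_p
  lapply(seq_len(cfg$n_layers - 1), function(l) {
    array((stats::runif(DH * n * Tn) < keep) / keep, c(DH, n, Tn))
  })
}

#' Train a predictor on a normalized dataset bundle
#'
#' Minimizes mean-squared error on the normalized targets with Adam,
#' recording training and validation loss per epoch and returning the weights
#' from the epoch with minimum validation loss (within the epoch budget).
#'
#' @param predictor an untrained `grfz_predictor` (or NULL to build one from
#'   `config`).
#' @param bundle a finalized `dataset_bundle`.
#' @param tconfig a [training_config()].
#' @param config used when `predictor` is NULL.
#' @param verbose print per-epoch losses.
#' @return a trained `grfz_predictor` with `history`, `bounds`, `best_epoch`.
#' @export
train_predictor <- function(predictor = NULL, bundle, tconfig = training_config(),
                            config = model_config(), verbose = FALSE) {
  assert_that(length(bundle$train) > 0, "empty training set")
  tr <- samples_to_arrays(bundle$train, bundle$bounds)
  va <- if (length(bundle$val) > 0) samples_to_arrays(bundle$val, bundle$bounds)
  cfg <- if (is.null(predictor)) config else predictor$config
  C <- dim(tr$X)[1]; n <- dim(tr$X)[2]; Tn <- dim(tr$X)[3]
  if (is.null(predictor)) {
    predictor <- build_network(cfg, C, seed = tconfig$seed)
  }
  assert_that(C == predictor$n_input_channels,
              "channel-count mismatch: data %d vs network %d", C,
              predictor$n_input_channels)
  target <- function(arr, idx) {
    if (cfg$head == "curve") arr$curve[, idx, , drop = FALSE]
    else arr$peak[, idx, drop = FALSE]
  }

  adam_m <- lapply(predictor$params, function(p) p * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = predictor$params, epoch = 0L)

  eval_loss <- function(arr) {
    ntot <- dim(arr$X)[2]; tot <- 0; cnt <- 0
    for (ix in split(seq_len(ntot), ceiling(seq_len(ntot) / 256))) {
      P <- net_forward(predictor, arr$X[, ix, , drop = FALSE])
      Yv <- target(arr, ix)
      tot <- tot + sum((P - Yv)^2); cnt <- cnt + length(Yv)
    }
    tot / cnt
  }

  withr::with_seed(tconfig$seed + 1L, {
    for (epoch in seq_len(tconfig$max_epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / tconfig$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        Xb <- tr$X[, bi, , drop = FALSE]
        Yb <- target(tr, bi)
        masks <- make_masks(cfg, length(bi), Tn)
        res <- cpp_lstm_loss_grad(Xb, Yb, predictor$params, masks,
                                  cfg$n_layers, cfg$bidirectional, cfg$head)
        if (!is.finite(res$loss)) {
          stopf("training diverged (loss is not finite) at epoch %d", epoch)
        }
        ep_loss <- ep_loss + res$loss * length(bi)
        step <- step + 1
        for (k in names(predictor$params)) {
          gk <- res$grads[[k]]
          adam_m[[k]] <- b1 * adam_m[[k]] + (1 - b1) * gk
          adam_v[[k]] <- b2 * adam_v[[k]] + (1 - b2) * gk^2
          mhat <- adam_m[[k]] / (1 - b1^step)
          vhat <- adam_v[[k]] / (1 - b2^step)
          predictor$params[[k]] <- predictor$params[[k]] -
            tconfig$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      vl <- if (!is.null(va)) eval_loss(va) else ep_loss / n
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / n,
                                           val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = predictor$params,
                                       epoch = epoch)
      if (verbose) {
        message(sprintf("epoch %2d  train %.5f  val %.5f", epoch,
                        ep_loss / n, vl))
      }
    }
  })
  predictor$params <- best$params
  predictor$best_epoch <- best$epoch
  predictor$history <- history
  predictor$bounds <- bundle$bounds
  predictor$tconfig <- tconfig
  predictor
}

#' Predict GRFz curves or peaks for stride samples
#'
#' Inputs are normalized with the predictor's stored training bounds and
#' outputs denormalized back to N/kg. Swing-phase predictions are reported
#' raw: outputs are never clipped or zeroed.
#'
#' @param predictor a trained `grfz_predictor` (with `bounds`).
#' @param samples list of (unnormalized) `stride_sample`s, or a pre-built
#'   array list from [samples_to_arrays()] already normalized.
#' @return curve head: array (4 x n x 200) in N/kg; peak head: 4 x n matrix.
#' @export
predict_grfz <- function(predictor, samples) {
  assert_that(!is.null(predictor$bounds),
              "predictor has no normalization bounds (untrained?)")
  arr <- if (is.list(samples) && !is.null(samples$X)) samples
         else samples_to_arrays(samples, predictor$bounds)
  assert_that(dim(arr$X)[1] == predictor$n_input_channels,
              "channel-count mismatch: data %d vs network %d", dim(arr$X)[1],
              predictor$n_input_channels)
  n <- dim(arr$X)[2]
  cfg <- predictor$config
  bounds <- if (cfg$head == "curve") predictor$bounds$curve
            else predictor$bounds$peak
  span <- bounds[, "max"] - bounds[, "min"]
  span[span == 0] <- 1
  if (cfg$head == "curve") {
    out <- array(0, c(4, n, dim(arr$X)[3]))
    for (ix in split(seq_len(n), ceiling(seq_len(n) / 256))) {
      out[, ix, ] <- net_forward(predictor, arr$X[, ix, , drop = FALSE])
    }
    sweep(sweep(out, 1, span, "*"), 1, bounds[, "min"], "+")
  } else {
    out <- matrix(0, 4, n)
    for (ix in split(seq_len(n), ceiling(seq_len(n) / 256))) {
      out[, ix] <- net_forward(predictor, arr$X[, ix, , drop = FALSE])
    }
    out * span + bounds[, "min"]
  }
}

#' Repeat the train/evaluate experiment with re-drawn horse splits
#'
#' Each repeat re-draws the horse split (and shuffling) with its own seed,
#' trains a predictor and evaluates it on that repeat's held-out test horses;
#' metric means and standard deviations are reported across repeats.
#'
#' @param samples list of `stride_sample`s (one gait, one node set).
#' @param counts train/val/test horse counts.
#' @param config,tconfig model and training configuration.
#' @param n_repeats number of repeats (study default 10).
#' @param seeds optional vector of split seeds (length `n_repeats`).
#' @return list with `repeats` (per-repeat evaluation), `summary` (mean/sd of
#'   median RMSE and rho across repeats).
#' @export
repeat_experiment <- function(samples, counts, config = model_config(),
                              tconfig = training_config(), n_repeats = 10,
                              seeds = NULL) {
  seeds <- seeds %||% (tconfig$seed + seq_len(n_repeats) * 1000L)
  assert_that(length(seeds) >= n_repeats, "need >= n_repeats seeds")
  reps <- lapply(seq_len(n_repeats), function(i) {
    bundle <- finalize_bundle(split_by_horse(samples, counts, seed = seeds[i]))
    tc <- tconfig; tc$seed <- as.integer(seeds[i])
    pred <- train_predictor(NULL, bundle, tc, config)
    if (config$head == "curve") {
      ev <- evaluate_curve_predictions(pred, bundle$test)
      list(seed = seeds[i], bundle_horses = bundle$horses, predictor = pred,
           eval = ev,
           median_rmse = stats::median(ev$rmse),
           median_rho = stats::median(ev$rho, na.rm = TRUE))
    } else {
      pk <- predict_grfz(pred, bundle$test)
      ref <- vapply(bundle$test, function(s) s$peak, numeric(4))
      list(seed = seeds[i], bundle_horses = bundle$horses, predictor = pred,
           eval = NULL,
           median_rmse = stats::median(abs(pk - ref)),
           median_rho = NA_real_)
    }
  })
  mr <- vapply(reps, `[[`, numeric(1), "median_rmse")
  rr <- vapply(reps, `[[`, numeric(1), "median_rho")
  list(repeats = reps,
       summary = data.frame(metric = c("median_rmse", "median_rho"),
                            mean = c(mean(mr), mean(rr)),
                            sd = c(stats::sd(mr), stats::sd(rr))))
}
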