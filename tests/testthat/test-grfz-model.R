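test_that("backpropagation matches numerical gradients", {
  withr::with_seed(2, {
    for (head in c("curve", "peak")) {
      cfg <- model_config(n_layers = 2, hidden_units = 3, dropout_p = 0.3,
                          head = head)
      net <- build_network(cfg, n_input_channels = 4, seed = 7)
      B <- 2; Tn <- 5
      X <- array(rnorm(4 * B * Tn), c(4, B, Tn))
      Y <- if (head == "curve") array(rnorm(4 * B * Tn), c(4, B, Tn))
           else matrix(rnorm(4 * B), 4, B)
      mask <- list(array((runif(6 * B * Tn) < 0.7) / 0.7, c(6, B, Tn)))
      f <- function(par) {
        equigrf:::cpp_lstm_loss_grad(X, Y, par, mask, 2L, TRUE, head)$loss
      }
      res <- equigrf:::cpp_lstm_loss_grad(X, Y, net$params, mask, 2L, TRUE,
                                          head)
      for (k in names(net$params)) {
        for (ii in sample(length(net$params[[k]]),
                          min(4, length(net$params[[k]])))) {
          eps <- 1e-6
          p1 <- net$params; p1[[k]][ii] <- p1[[k]][ii] + eps
          p2 <- net$params; p2[[k]][ii] <- p2[[k]][ii] - eps
          num <- (f(p1) - f(p2)) / (2 * eps)
          got <- res$grads[[k]][ii]
          expect_lt(abs(num - got) / max(1e-6, abs(num) + abs(got)), 1e-3)
        }
      }
    }
  })
})

test_that("network shapes follow the node set and head", {
  net <- build_network(model_config(hidden_units = 8, head = "curve"), 42)
  X <- array(0, c(42, 3, 200))
  out <- equigrf:::cpp_lstm_forward(X, net$params, list(), 2L, TRUE, "curve")
  expect_equal(dim(out$pred), c(4, 3, 200))
  netp <- build_network(model_config(hidden_units = 8, head = "peak"), 6)
  Xp <- array(0, c(6, 3, 200))
  outp <- equigrf:::cpp_lstm_forward(Xp, netp$params, list(), 2L, TRUE, "peak")
  expect_equal(dim(outp$pred), c(4, 3))
})

test_that("parameter count matches the closed form for the BiLSTM stack", {
  H <- 8; C <- 42; O <- 4
  net <- build_network(model_config(hidden_units = H), C)
  expected <- 2 * 4 * H * (C + H + 1) +      # layer 1, both directions
    2 * 4 * H * (2 * H + H + 1) +            # layer 2 takes 2H inputs
    O * 2 * H + O                            # fully connected head
  expect_equal(n_params(net), expected)
})

test_that("a zero-dropout forward pass is deterministic", {
  net <- build_network(model_config(hidden_units = 6, dropout_p = 0), 6,
                       seed = 3)
  X <- array(rnorm(6 * 2 * 50), c(6, 2, 50))
  o1 <- equigrf:::cpp_lstm_forward(X, net$params, list(), 2L, TRUE, "curve")
  o2 <- equigrf:::cpp_lstm_forward(X, net$params, list(), 2L, TRUE, "curve")
  expect_identical(o1$pred, o2$pred)
})

test_that("training learns a linear input-to-curve map", {
  samples <- make_linear_samples(n = 60, C = 6, Tn = 60)
  bundle <- finalize_bundle(split_by_horse(samples, c(4, 1, 1), seed = 2))
  fit <- train_predictor(NULL, bundle,
                         training_config(max_epochs = 60, batch_size = 16,
                                         seed = 11),
                         model_config(hidden_units = 16, dropout_p = 0.1,
                                      head = "curve"))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.10 * h$train_loss[1])
  # learnability floor: held-out RMSE under 5% of the target range
  pred <- predict_grfz(fit, bundle$test)
  ref <- vapply(bundle$test, function(s) s$curve, bundle$test[[1]]$curve)
  rng <- max(fit$bounds$curve[, "max"] - fit$bounds$curve[, "min"])
  rmse <- sqrt(mean((aperm(pred, c(1, 3, 2)) - ref)^2))
  expect_lt(rmse, 0.05 * rng)
})

test_that("a single-sample dataset is memorized", {
  samples <- make_linear_samples(n = 8, C = 4, Tn = 40)
  bundle <- list(train = samples[1], val = samples[1], test = samples[1],
                 horses = list())
  class(bundle) <- "dataset_bundle"
  bundle <- finalize_bundle(bundle)
  fit <- train_predictor(NULL, bundle,
                         training_config(max_epochs = 80, batch_size = 1,
                                         seed = 5),
                         model_config(hidden_units = 16, dropout_p = 0,
                                      head = "curve"))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.01 * h$train_loss[1])
})

test_that("training is reproducible under a fixed seed", {
  samples <- make_linear_samples(n = 12, C = 4, Tn = 30)
  bundle <- finalize_bundle(split_by_horse(samples, c(4, 1, 1), seed = 2))
  tc <- training_config(max_epochs = 3, batch_size = 8, seed = 21)
  cfg <- model_config(hidden_units = 8, head = "curve")
  f1 <- train_predictor(NULL, bundle, tc, cfg)
  f2 <- train_predictor(NULL, bundle, tc, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("training rejects empty training sets and channel mismatches", {
  samples <- make_linear_samples(n = 12, C = 4, Tn = 30)
  bundle <- finalize_bundle(split_by_horse(samples, c(4, 1, 1), seed = 2))
  empty <- bundle; empty$train <- list()
  expect_error(train_predictor(NULL, empty, training_config()), "empty")
  net <- build_network(model_config(hidden_units = 4), 7)
  expect_error(train_predictor(net, bundle, training_config()),
               "channel-count mismatch")
})

test_that("repeat experiments re-draw disjoint splits and report spread", {
  samples <- make_linear_samples(n = 30, C = 4, Tn = 30)
  ex <- repeat_experiment(samples, c(4, 1, 1),
                          model_config(hidden_units = 8, head = "curve"),
                          training_config(max_epochs = 4, batch_size = 8,
                                          seed = 1),
                          n_repeats = 2, seeds = c(11L, 57L))
  expect_length(ex$repeats, 2)
  expect_named(ex$summary, c("metric", "mean", "sd"))
  expect_true(all(is.finite(ex$summary$sd)))
  expect_gt(ex$summary$sd[1], 0)  # stochastic training varies across seeds
  for (r in ex$repeats) {
    expect_length(intersect(r$bundle_horses$train, r$bundle_horses$test), 0)
  }
})

test_that("predictions keep raw swing values and exceed training bounds when
           warranted", {
  run <- headline_run("walk")
  pred <- predict_grfz(run$fit, run$bundle$test)
  expect_equal(dim(pred), c(4, length(run$bundle$test), 200))
  s <- run$bundle$test[[1]]
  swing <- !(seq(0, 1, length.out = 200) >= s$stance_frac[1, 1] &
               seq(0, 1, length.out = 200) <= s$stance_frac[1, 2])
  expect_true(any(pred[1, 1, swing] != 0))   # swing output is not zeroed
  expect_true(any(pred < 0))                 # and negatives are not clipped
})

test_that("more informative node sets do not predict worse (median over
           paired repeats)", {
  ord <- ordering_run()
  med <- vapply(ord, stats::median, numeric(1))
  expect_lte(med[["All"]], med[["UB"]])
  expect_lte(med[["UB"]], med[["Sac"]])
  expect_lte(med[["All"]], med[["Limbs"]])
})

test_that("predictors round-trip through JSON", {
  samples <- make_linear_samples(n = 12, C = 4, Tn = 30)
  bundle <- finalize_bundle(split_by_horse(samples, c(4, 1, 1), seed = 2))
  fit <- train_predictor(NULL, bundle,
                         training_config(max_epochs = 2, batch_size = 8,
                                         seed = 3),
                         model_config(hidden_units = 6, head = "curve"))
  f <- tempfile(fileext = ".json")
  write_predictor(fit, f)
  fit2 <- read_predictor(f)
  p1 <- predict_grfz(fit, bundle$test)
  p2 <- predict_grfz(fit2, bundle$test)
  expect_equal(p1, p2, tolerance = 1e-12)
  unlink(f)
})
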