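# Training regimes: plateau scheduling, reproducibility, checkpoints,
# update-direction sanity for the adversarial pair.

test_that("plateau_scheduler follows the decay-0.5 / patience-5 regime", {
  cfg <- train_config(plateau_decay = 0.5, plateau_patience = 5)
  # improving sequence: unchanged
  expect_identical(plateau_scheduler(c(1, 0.9, 0.8, 0.7, 0.6, 0.5), 0.001, cfg),
                   0.001)
  # five consecutive non-improving epochs after the best: halved
  expect_identical(plateau_scheduler(c(0.5, 0.6, 0.6, 0.6, 0.6, 0.6), 0.001, cfg),
                   0.0005)
  # not enough history: unchanged
  expect_identical(plateau_scheduler(c(0.6, 0.6, 0.6), 0.001, cfg), 0.001)
  expect_error(plateau_scheduler(c(1, 2), 0, cfg),
               class = "ribclear_argument_error")
})

test_that("plateau decisions match a literal specification oracle on random sequences", {
  cfg <- train_config(plateau_decay = 0.5, plateau_patience = 3)
  oracle <- function(losses, lr) {
    p <- 3
    n <- length(losses)
    if (n < p + 1) return(lr)
    if (min(losses[(n - p + 1):n]) >= min(losses[seq_len(n - p)])) lr * 0.5 else lr
  }
  for (sd in 1:100) {
    losses <- withr::with_seed(sd, round(runif(sample(2:9, 1)), 2))
    expect_identical(plateau_scheduler(losses, 0.01, cfg), oracle(losses, 0.01))
  }
})

test_that("zero-epoch training returns the model unchanged with empty history", {
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 1, size = 32), 6)
  m <- build_cdae(model_spec("cdae", 32, depth = 2, base_filters = 3,
                             input_channels = 1), seed = 1)
  fit <- train_supervised(m, pairs, loss = "L1",
                          cfg = train_config(epochs = 0))
  expect_identical(nn_params(fit$model), nn_params(m))
  expect_identical(nrow(fit$history), 0L)
  g <- build_generator(model_spec("gan_generator", 32, depth = 2,
                                  base_filters = 3, input_channels = 1), seed = 2)
  cr <- build_critic(model_spec("gan_critic", 32, depth = 2, base_filters = 3,
                                input_channels = 1), seed = 3)
  p11 <- lapply(pairs, pair_normalize, to = c(-1, 1))
  gfit <- train_adversarial(g, cr, p11,
                            weights = composite_weights(beta_perc = 0,
                                                        gamma_sobel = 0),
                            cfg = train_config(epochs = 0,
                                               normalization = c(-1, 1)))
  expect_identical(nn_params(gfit$gen), nn_params(g))
  expect_identical(nrow(gfit$history), 0L)
})

test_that("the learning rate halves after exactly patience non-improving epochs", {
  # a vanishing step size freezes the parameters, so after the first epoch
  # the validation loss can never improve and the decay must fire at epoch
  # patience + 1
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 2, size = 32), 8)
  m <- build_cdae(model_spec("cdae", 32, depth = 2, base_filters = 3,
                             input_channels = 1), seed = 4)
  fit <- train_supervised(m, pairs[1:6], val_pairs = pairs[7:8], loss = "L1",
                          cfg = train_config(epochs = 7, batch_size = 4,
                                             learning_rate = 1e-12,
                                             plateau_patience = 5, seed = 5))
  lrs <- fit$history$lr
  expect_equal(lrs[1:5], rep(1e-12, 5))
  expect_equal(lrs[6], 5e-13)
  # invariant: non-increasing, changes only by the decay factor
  steps <- lrs[-1] / lrs[-length(lrs)]
  expect_true(all(abs(steps - 1) < 1e-12 | abs(steps - 0.5) < 1e-12))
})

test_that("training histories are reproducible from the seeds", {
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 3, size = 32), 10)
  spec <- model_spec("cdae", 32, depth = 2, base_filters = 3, input_channels = 1)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 11)
  f1 <- train_supervised(build_cdae(spec, seed = 6), pairs, loss = "L1", cfg = cfg)
  f2 <- train_supervised(build_cdae(spec, seed = 6), pairs, loss = "L1", cfg = cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(nn_params(f1$model), nn_params(f2$model))
})

test_that("data range mismatches are rejected before training", {
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 4, size = 32), 4)
  m <- build_cdae(model_spec("cdae", 32, depth = 2, base_filters = 3,
                             input_channels = 1), seed = 1)
  expect_error(train_supervised(m, pairs, loss = "L1",
                                cfg = train_config(normalization = c(-1, 1))),
               class = "ribclear_config_error")
  g <- build_generator(model_spec("gan_generator", 32, depth = 2,
                                  base_filters = 3, input_channels = 1), seed = 1)
  cr <- build_critic(model_spec("gan_critic", 32, depth = 2, base_filters = 3,
                                input_channels = 1), seed = 1)
  expect_error(train_adversarial(g, cr, pairs,
                                 weights = composite_weights(beta_perc = 10),
                                 cfg = train_config(normalization = c(-1, 1))),
               class = "ribclear_config_error")
})

test_that("a short supervised run reduces the training loss", {
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 5, size = 32), 20)
  m <- build_cdae(model_spec("cdae", 32, depth = 2, base_filters = 4,
                             input_channels = 1), seed = 7)
  fit <- train_supervised(m, pairs, loss = "L1",
                          cfg = train_config(epochs = 5, batch_size = 4,
                                             seed = 8))
  expect_lt(utils::tail(fit$history$train_loss, 1),
            fit$history$train_loss[1])
})

test_that("one critic update decreases the critic loss on a fixed batch", {
  rc <- rcns
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 6, size = 32), 8)
  p11 <- lapply(pairs, pair_normalize, to = c(-1, 1))
  g <- build_generator(model_spec("gan_generator", 32, depth = 2,
                                  base_filters = 4, input_channels = 1), seed = 9)
  cr <- build_critic(model_spec("gan_critic", 32, depth = 2, base_filters = 4,
                                input_channels = 1), seed = 10)
  d <- rc$.pairs_to_xy(p11, 1L)
  yhat <- rc$.net_forward(g, d$x, train = TRUE)$out
  real_in <- rc$.concat_ch(d$x, d$y)
  fake_in <- rc$.concat_ch(d$x, yhat)
  eval_cl <- function(critic) {
    sr <- rc$.net_forward(critic, real_in, train = TRUE)$out
    sf <- rc$.net_forward(critic, fake_in, train = TRUE)$out
    critic_loss(sr, sf)
  }
  before <- eval_cl(cr)
  n <- dim(real_in)[4]
  fr <- rc$.net_forward(cr, real_in, train = TRUE)
  ff <- rc$.net_forward(cr, fake_in, train = TRUE)
  grads <- rc$grads_add(
    rc$.net_backward(cr, fr$cache, matrix(-1 / n, 1, n))$grads,
    rc$.net_backward(cr, ff$cache, matrix(1 / n, 1, n))$grads)
  par <- nn_params(cr)
  st <- rc$adam_update(par, grads, rc$adam_init(par), lr = 1e-3)
  after <- eval_cl(nn_set_params(cr, st$params))
  expect_lt(after, before)
})

test_that("a pure-adversarial generator update raises the mean critic score", {
  rc <- rcns
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 7, size = 32), 8)
  p11 <- lapply(pairs, pair_normalize, to = c(-1, 1))
  g <- build_generator(model_spec("gan_generator", 32, depth = 2,
                                  base_filters = 4, input_channels = 1), seed = 11)
  cr <- build_critic(model_spec("gan_critic", 32, depth = 2, base_filters = 4,
                                input_channels = 1), seed = 12)
  d <- rc$.pairs_to_xy(p11, 1L)
  n <- dim(d$x)[4]
  mean_score <- function(gen) {
    yh <- rc$.net_forward(gen, d$x, train = TRUE)$out
    mean(rc$.net_forward(cr, rc$.concat_ch(d$x, yh), train = TRUE)$out)
  }
  before <- mean_score(g)
  fg <- rc$.net_forward(g, d$x, train = TRUE)
  fc <- rc$.net_forward(cr, rc$.concat_ch(d$x, fg$out), train = TRUE)
  dyhat <- rc$.net_backward(cr, fc$cache,
                            matrix(-1 / n, 1, n))$dx[, , 2, , drop = FALSE]
  gbk <- rc$.net_backward(g, fg$cache, dyhat)
  par <- nn_params(g)
  st <- rc$adam_update(par, gbk$grads, rc$adam_init(par), lr = 1e-3)
  expect_gt(mean_score(nn_set_params(g, st$params)), before)
})

test_that("checkpoints round-trip forward outputs and histories bit-identically", {
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 8, size = 32), 10)
  spec <- model_spec("unet", 32, depth = 2, base_filters = 3, input_channels = 1)
  fit <- train_supervised(build_unet(spec, seed = 13), pairs, loss = "L1",
                          cfg = train_config(epochs = 2, batch_size = 4,
                                             seed = 14))
  probe <- seeded_image(32, seed = 15)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  ck <- load_checkpoint(path)
  expect_identical(nn_forward(ck$model, probe), nn_forward(fit$model, probe))
  expect_identical(ck$history, fit$history)
  expect_identical(load_checkpoint(path, spec = spec)$model$spec$family, "unet")
  other <- model_spec("unet", 32, depth = 2, base_filters = 5, input_channels = 1)
  expect_error(load_checkpoint(path, spec = other),
               class = "ribclear_spec_mismatch_error")
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds")),
               class = "ribclear_io_error")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(nonsense = 1), bad)
  expect_error(load_checkpoint(bad), class = "ribclear_io_error")
})
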