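# Training objectives: reductions, component oracles, gradients, and the
# adversarial pieces.

test_that("pixel losses match their closed forms", {
  x <- seeded_image(8, seed = 1)
  expect_identical(pixel_loss(x, x, "L1"), 0)
  expect_identical(pixel_loss(x, x, "L2"), 0)
  expect_equal(pixel_loss(x + 0.5, x, "L1"), 0.5)
  expect_equal(pixel_loss(x + 0.5, x, "L2"), 0.25)
  expect_error(pixel_loss(x, x[1:4, 1:4]), class = "ribclear_dimension_error")
})

test_that("msssim_loss is definitional on ms_ssim and matches the pyramid oracle", {
  p <- ssim_params(window_size = 7, scales = 3)
  x <- seeded_image(64, seed = 3)
  y <- seeded_image(64, seed = 4)
  expect_identical(msssim_loss(x, x, p), 0)
  expect_identical(msssim_loss(x, y, p), 1 - ms_ssim(x, y, p))
  expect_lt(abs(msssim_loss(x, y, p) - (1 - oracle_msssim(x, y, p))), 1e-6)
})

test_that("mixed_loss reduces to its pure components and composes linearly", {
  p <- ssim_params(window_size = 7, scales = 2)
  x <- seeded_image(32, seed = 5)
  y <- seeded_image(32, seed = 6)
  cfg0 <- mixed_loss_config(alpha_mix = 0, pixel_kind = "L1", ssim_params = p)
  cfg1 <- mixed_loss_config(alpha_mix = 1, pixel_kind = "L1", ssim_params = p)
  expect_identical(mixed_loss(x, y, cfg0), pixel_loss(x, y, "L1"))
  expect_identical(mixed_loss(x, y, cfg1), msssim_loss(x, y, p))
  cfg <- mixed_loss_config(alpha_mix = 0.84, pixel_kind = "L1", ssim_params = p)
  target_val <- 0.84 * (1 - oracle_msssim(x, y, p)) + 0.16 * mean(abs(x - y))
  expect_lt(abs(mixed_loss(x, y, cfg) - target_val), 1e-9)
  expect_error(mixed_loss_config(alpha_mix = 1.2),
               class = "ribclear_argument_error")
})

test_that("sobel_loss matches a literal stencil convolution oracle", {
  x <- seeded_image(12, seed = 7)
  expect_identical(sobel_loss(x, x), 0)
  expect_identical(sobel_loss(matrix(0.2, 8, 8), matrix(0.7, 8, 8)), 0)
  # step edges one column apart
  pred <- matrix(0, 10, 10); pred[, 5:10] <- 1
  tgt <- matrix(0, 10, 10); tgt[, 6:10] <- 1
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gd <- function(m, k) oracle_conv_valid(oracle_pad_reflect(m, 1), k)
  oracle <- (sum(abs(gd(pred, kx) - gd(tgt, kx))) +
             sum(abs(gd(pred, t(kx)) - gd(tgt, t(kx))))) / (2 * 100)
  expect_lt(abs(sobel_loss(pred, tgt) - oracle), 1e-9)
  expect_error(sobel_loss(matrix(0, 2, 2), matrix(0, 2, 2)),
               class = "ribclear_dimension_error")
})

test_that("perceptual_loss vanishes at identity and matches a manual forward pass", {
  ex <- make_random_extractor(stages = 3, base_filters = 4, in_ch = 1, seed = 11)
  x <- seeded_image(16, seed = 8)
  y <- seeded_image(16, seed = 9)
  expect_identical(perceptual_loss(x, x, ex), 0)
  expect_identical(perceptual_loss(x, y, identity_extractor(1)),
                   pixel_loss(x, y, "L2"))
  # manual forward: naive conv + leaky relu + 2x2 max pool per stage
  man_forward <- function(m) {
    feats <- list()
    planes <- list(m)
    for (s in 1:3) {
      conv <- ex$layers[[paste0("s", s, ".conv")]]
      outs <- list()
      for (co in seq_len(dim(conv$w)[4])) {
        acc <- matrix(conv$b[co], nrow(planes[[1]]), ncol(planes[[1]]))
        for (ci in seq_along(planes)) {
          padded <- matrix(0, nrow(planes[[ci]]) + 2, ncol(planes[[ci]]) + 2)
          padded[2:(nrow(planes[[ci]]) + 1), 2:(ncol(planes[[ci]]) + 1)] <-
            planes[[ci]]
          acc <- acc + oracle_conv_valid(padded, conv$w[, , ci, co])
        }
        outs[[co]] <- ifelse(acc > 0, acc, 0.2 * acc)
      }
      feats[[s]] <- outs
      if (s < 3) {
        planes <- lapply(outs, function(p) {
          h <- nrow(p) %/% 2; w <- ncol(p) %/% 2
          q <- matrix(0, h, w)
          for (i in seq_len(h)) for (j in seq_len(w))
            q[i, j] <- max(p[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
          q
        })
      } else planes <- outs
    }
    feats
  }
  fx <- man_forward(x); fy <- man_forward(y)
  oracle <- mean(vapply(1:3, function(s) {
    mean(unlist(Map(function(a, b) (a - b)^2, fx[[s]], fy[[s]])))
  }, numeric(1)))
  expect_lt(abs(perceptual_loss(x, y, ex) - oracle), 1e-6)
})

test_that("critic_loss is the score-mean difference and antisymmetric", {
  expect_identical(critic_loss(c(1, 1), c(0, 0)), -1)
  expect_identical(critic_loss(c(0.3, 0.7), c(0.3, 0.7)), 0)
  for (sd in 1:5) {
    dr <- withr::with_seed(sd, rnorm(6))
    df <- withr::with_seed(sd + 50, rnorm(6))
    expect_equal(critic_loss(dr, df), -critic_loss(df, dr))
  }
  expect_error(critic_loss(numeric(0), 1), class = "ribclear_argument_error")
})

test_that("gradient_penalty matches its closed forms", {
  # sum-critic: one stride-2 4x4 window covering the whole padded 2x2 input
  spec <- model_spec("gan_critic", input_size = 2, depth = 1, base_filters = 1,
                     input_channels = 1, normalization = "none")
  cr <- build_critic(spec, seed = 1)
  par <- nn_params(cr)
  par[["c1.conv.w"]][] <- 1
  par[["c1.conv.b"]][] <- 0
  par[["head.dense.w"]][] <- 1
  par[["head.dense.b"]][] <- 0
  cr <- nn_set_params(cr, par)
  real <- array(withr::with_seed(2, runif(2 * 2 * 2 * 4, 0.1, 1)), c(2, 2, 2, 4))
  fake <- array(withr::with_seed(3, runif(2 * 2 * 2 * 4, 0.1, 1)), c(2, 2, 2, 4))
  # D(x) = sum(x): gradient norm is sqrt(N) with N = 8 input elements
  expect_equal(gradient_penalty(cr, real, fake, seed = 4),
               (sqrt(8) - 1)^2, tolerance = 1e-10)
  # constant critic: zero gradient, penalty (0 - 1)^2 = 1
  par0 <- lapply(par, function(p) p * 0)
  cr0 <- nn_set_params(cr, par0)
  expect_equal(gradient_penalty(cr0, real, fake, seed = 4), 1, tolerance = 1e-12)
})

test_that("gradient_penalty parameter gradients match finite differences", {
  spec <- model_spec("gan_critic", input_size = 8, depth = 2, base_filters = 3,
                     input_channels = 1, normalization = "none")
  cr <- build_critic(spec, seed = 3)
  real <- array(withr::with_seed(5, runif(8 * 8 * 2 * 3)), c(8, 8, 2, 3))
  fake <- array(withr::with_seed(6, runif(8 * 8 * 2 * 3)), c(8, 8, 2, 3))
  g <- gradient_penalty(cr, real, fake, seed = 7, param_grads = TRUE)
  par <- nn_params(cr)
  idx <- withr::with_seed(8, lapply(1:8, function(i) {
    nm <- sample(names(par), 1)
    list(nm = nm, i = sample(length(par[[nm]]), 1))
  }))
  for (ix in idx) {
    f <- function(v) {
      p2 <- par; p2[[ix$nm]][ix$i] <- v
      gradient_penalty(nn_set_params(cr, p2), real, fake, seed = 7)
    }
    eps <- 1e-5
    fdv <- (f(par[[ix$nm]][ix$i] + eps) - f(par[[ix$nm]][ix$i] - eps)) / (2 * eps)
    an <- g$grads[[ix$nm]]
    an <- if (is.null(an)) 0 else an[ix$i]
    expect_lt(abs(fdv - an) / max(1e-2, abs(fdv)), 1e-4)
  }
})

test_that("generator_loss reduces to its printed special cases", {
  x <- seeded_image(16, seed = 20)
  y <- seeded_image(16, seed = 21)
  d_fake <- withr::with_seed(22, rnorm(4))
  gl0 <- generator_loss(d_fake, y, y,
                        composite_weights(beta_perc = 0, gamma_sobel = 0))
  expect_equal(gl0$total - gl0$adversarial, 0)
  expect_equal(generator_loss(0, y, y, composite_weights(beta_perc = 0,
                                                         gamma_sobel = 0))$total, 0)
  w10 <- composite_weights(delta = 1, alpha_pix = 1, beta_perc = 0,
                           gamma_sobel = 0, pixel_kind = "L1")
  expect_equal(generator_loss(d_fake, x, y, w10)$total,
               -mean(d_fake) + mae(x, y), tolerance = 1e-12)
  expect_error(generator_loss(d_fake, x, y, composite_weights()),
               class = "ribclear_config_error")
})

test_that("generator_loss combines weighted components exactly and is affine in each", {
  x <- seeded_image(16, seed = 23)
  y <- seeded_image(16, seed = 24)
  d_fake <- withr::with_seed(25, rnorm(4))
  ex <- make_random_extractor(stages = 2, base_filters = 4, in_ch = 1, seed = 26)
  w <- composite_weights(pixel_kind = "L1")  # defaults 10000 / 1 / 10 / 10
  gl <- generator_loss(d_fake, x, y, w, extractor = ex)
  manual <- -mean(d_fake) + 10000 * (1 * mae(x, y) +
                                     10 * perceptual_loss(x, y, ex) +
                                     10 * sobel_loss(x, y))
  expect_lt(abs(gl$total - manual) / abs(manual), 1e-6)
  # doubling one weight shifts the total by exactly that component
  for (fld in c("alpha_pix", "beta_perc", "gamma_sobel")) {
    w2 <- w; w2[[fld]] <- 2 * w[[fld]]
    comp <- switch(fld, alpha_pix = "pixel", beta_perc = "perceptual",
                   gamma_sobel = "sobel")
    gl2 <- generator_loss(d_fake, x, y, w2, extractor = ex)
    expect_equal(gl2$total - gl$total, w$delta * w[[fld]] * gl[[comp]],
                 tolerance = 1e-9)
  }
})

test_that("loss_config parses the field shorthand", {
  expect_identical(loss_config("MixL1")$objective, "mixed")
  expect_identical(loss_config("L2")$pixel_kind, "L2")
  wl <- loss_config("WL")
  expect_identical(wl$kind, "adversarial")
  expect_identical(wl$weights$alpha_pix, 0)
  w1 <- loss_config("WL1PS")$weights
  expect_identical(c(w1$delta, w1$alpha_pix, w1$beta_perc, w1$gamma_sobel),
                   c(10000, 1, 10, 10))
  expect_identical(w1$pixel_kind, "L1")
  expect_error(loss_config("bogus"), class = "ribclear_config_error")
})

test_that("analytic gradients match central finite differences on 8x8 inputs", {
  x <- seeded_image(8, seed = 31)
  y <- seeded_image(8, seed = 32)
  p <- ssim_params(window_size = 3, scales = 2)
  ex <- make_random_extractor(stages = 2, base_filters = 3, in_ch = 1, seed = 33)
  cases <- list(
    list(f = function(z) pixel_loss(z, y, "L2"),
         g = pixel_loss(x, y, "L2", grad = TRUE)$grad),
    list(f = function(z) pixel_loss(z, y, "L1"),
         g = pixel_loss(x, y, "L1", grad = TRUE)$grad),
    list(f = function(z) msssim_loss(z, y, p),
         g = msssim_loss(x, y, p, grad = TRUE)$grad),
    list(f = function(z) sobel_loss(z, y),
         g = sobel_loss(x, y, grad = TRUE)$grad),
    list(f = function(z) perceptual_loss(z, y, ex),
         g = perceptual_loss(x, y, ex, grad = TRUE)$grad),
    list(f = function(z) mixed_loss(z, y, mixed_loss_config(0.5, "L1", p)),
         g = mixed_loss(x, y, mixed_loss_config(0.5, "L1", p), grad = TRUE)$grad))
  for (cs in cases) expect_fd_match(cs$f, x, cs$g, n = 6, tol = 1e-4)
})

test_that("reconstruction losses are minimized at pred = target", {
  y <- seeded_image(16, seed = 41)
  p <- ssim_params(window_size = 5, scales = 2)
  ex <- make_random_extractor(stages = 2, base_filters = 3, in_ch = 1, seed = 42)
  for (sd in 1:5) {
    x <- seeded_image(16, seed = sd + 60)
    expect_gte(pixel_loss(x, y, "L1"), 0)
    expect_gte(msssim_loss(x, y, p), msssim_loss(y, y, p))
    expect_gte(sobel_loss(x, y), 0)
    expect_gte(perceptual_loss(x, y, ex), 0)
  }
})
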