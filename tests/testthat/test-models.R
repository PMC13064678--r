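# Architecture contracts: shape preservation, determinism, parameter
# schedules, critic structure, backbone seam.

test_that("model_spec enforces its invariants", {
  expect_error(model_spec("cdae", input_size = 30, depth = 2),
               class = "ribclear_spec_error")
  expect_error(model_spec("cdae", base_filters = 0),
               class = "ribclear_spec_error")
  expect_error(model_spec("gan_critic", output_activation = "sigmoid"),
               class = "ribclear_spec_error")
  expect_error(model_spec("cdae", input_channels = 2),
               class = "ribclear_spec_error")
  expect_identical(model_spec("gan_generator")$output_activation, "tanh")
  expect_identical(model_spec("unet")$output_activation, "sigmoid")
  expect_identical(model_spec("gan_critic")$normalization, "batch")
})

test_that("generator-family networks preserve input shape and output range", {
  for (size in c(32L, 64L)) {
    for (fam in c("cdae", "unet", "gan_generator")) {
      spec <- model_spec(fam, input_size = size, depth = 3, base_filters = 4,
                         input_channels = 1)
      h <- switch(fam, cdae = build_cdae(spec, seed = 2),
                  unet = build_unet(spec, seed = 2),
                  gan_generator = build_generator(spec, seed = 2))
      x <- array(withr::with_seed(size, runif(size * size * 2)),
                 c(size, size, 1, 2))
      out <- nn_forward(h, x)
      expect_identical(dim(out), dim(x))
      rng <- if (fam == "gan_generator") c(-1, 1) else c(0, 1)
      expect_true(all(out >= rng[1] & out <= rng[2]))
    }
  }
})

test_that("identical spec and seed give bit-identical parameters and outputs", {
  spec <- model_spec("unet", input_size = 32, depth = 2, base_filters = 4,
                     input_channels = 1)
  a <- build_unet(spec, seed = 9)
  b <- build_unet(spec, seed = 9)
  expect_identical(nn_params(a), nn_params(b))
  x <- array(withr::with_seed(1, runif(32 * 32)), c(32, 32, 1, 1))
  expect_identical(nn_forward(a, x), nn_forward(b, x))
  expect_false(identical(nn_params(a), nn_params(build_unet(spec, seed = 10))))
})

test_that("sampled outputs respect the declared activation range over seeds", {
  spec <- model_spec("gan_generator", input_size = 32, depth = 2,
                     base_filters = 4, input_channels = 1)
  for (sd in 1:10) {
    g <- build_generator(spec, seed = sd)
    x <- array(withr::with_seed(sd + 100, runif(32 * 32, -1, 1)), c(32, 32, 1, 1))
    out <- nn_forward(g, x)
    expect_true(all(out >= -1 & out <= 1))
  }
})

test_that("cdae parameter count matches the layer-by-layer closed form", {
  spec <- model_spec("cdae", input_size = 32, depth = 2, base_filters = 4,
                     input_channels = 1)
  h <- build_cdae(spec, seed = 1)
  # filter schedule 4, 8 (encoder), 16 (bottleneck), 8, 4 (decoder), 1 (head);
  # 3x3 kernels: 40 + 296 + 1168 + 1160 + 292 + 37 = 2993
  expect_identical(h$n_params, 2993L)
  expect_identical(sum(vapply(nn_params(h), length, integer(1))), 2993L)
})

test_that("cdae output shape survives depth-3 encode/decode", {
  spec <- model_spec("cdae", input_size = 64, depth = 3, base_filters = 4,
                     input_channels = 1)
  h <- build_cdae(spec, seed = 3)
  out <- nn_forward(h, matrix(0.5, 64, 64))
  expect_identical(dim(out), c(64L, 64L, 1L, 1L))
})

test_that("u-net skip connections are live and channels follow the schedule", {
  spec <- model_spec("unet", input_size = 32, depth = 3, base_filters = 4,
                     input_channels = 1)
  h <- build_unet(spec, seed = 4)
  x <- array(withr::with_seed(2, runif(32 * 32)), c(32, 32, 1, 1))
  base_out <- nn_forward(h, x)
  # zero the decoder weights that multiply the level-1 skip channels
  par <- nn_params(h)
  w <- par[["dec1.conv.w"]]
  f1 <- h$layers[["dec1.upconv"]]$out_ch
  w[, , (f1 + 1):dim(w)[3], ] <- 0
  par[["dec1.conv.w"]] <- w
  expect_false(identical(nn_forward(nn_set_params(h, par), x), base_out))
  # decoder input channels = upsampled channels + skip channels per level
  for (l in 1:3) {
    dec <- h$layers[[paste0("dec", l, ".conv")]]
    up <- h$layers[[paste0("dec", l, ".upconv")]]
    skip <- h$layers[[paste0("enc", l, ".conv")]]
    expect_identical(dec$in_ch, up$out_ch + skip$out_ch)
  }
})

test_that("generator spatial sizes double from the bottleneck to the input size", {
  spec <- model_spec("gan_generator", input_size = 64, depth = 4,
                     base_filters = 4, input_channels = 3)
  g <- build_generator(spec, seed = 5)
  tr <- nn_shape_trace(g)
  dec <- tr[grepl("^dec", tr$stage) | tr$stage == "mid", ]
  expect_identical(dec$h, c(4L, 8L, 16L, 32L, 64L))
  expect_identical(tr$h[tr$stage == "head"], 64L)
  out <- nn_forward(g, array(0.1, c(64, 64, 3, 1)))
  expect_identical(dim(out), c(64L, 64L, 3L, 1L))
})

test_that("critic yields one linear score per image and halves resolution per stage", {
  spec <- model_spec("gan_critic", input_size = 64, depth = 3, base_filters = 4,
                     input_channels = 1)
  cr <- build_critic(spec, seed = 6)
  x <- array(withr::with_seed(3, runif(64 * 64 * 2 * 8, -1, 1)), c(64, 64, 2, 8))
  scores <- nn_forward(cr, x)
  expect_identical(dim(scores), c(1L, 8L))
  tr <- nn_shape_trace(cr)
  conv_rows <- tr[grepl("\\.conv$", tr$stage), ]
  expect_identical(conv_rows$h, c(32L, 16L, 8L))
  # batch norm after every convolution except the first
  expect_false("c1.bn" %in% names(cr$layers))
  expect_true(all(c("c2.bn", "c3.bn") %in% names(cr$layers)))
  expect_identical(cr$order[1:2], c("c1.conv", "c1.act"))
})

test_that("the backbone seam validates levels and produces working U-Nets", {
  bb <- random_backbone(depth = 3, base_filters = 4, in_ch = 1, seed = 7)
  expect_error(model_spec("unet", input_size = 32, depth = 2, base_filters = 4,
                          input_channels = 1, backbone = bb) |> build_unet(),
               class = "ribclear_interface_error")
  spec <- model_spec("unet", input_size = 32, depth = 3, base_filters = 4,
                     input_channels = 1, backbone = bb)
  h <- build_unet(spec, seed = 8)
  out <- nn_forward(h, matrix(0.3, 32, 32))
  expect_identical(dim(out), c(32L, 32L, 1L, 1L))
  # deterministic backbone: same input, same features
  expect_identical(nn_forward(h, matrix(0.3, 32, 32)), out)
})
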