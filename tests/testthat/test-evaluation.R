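# Region-wise evaluation: alignment, bone-mask derivation, the MAE
# conservation identity, residual uniformity, model comparison.

test_that("alignment is the identity on matching shapes and idempotent", {
  m <- seeded_image(16, seed = 1)
  expect_identical(align_to_reference(m, c(16, 16)), m)
  up <- align_to_reference(m, c(24, 24))
  expect_identical(align_to_reference(up, c(24, 24)), up)
  expect_error(align_to_reference(array(0, c(2, 2, 2)), c(4, 4)),
               class = "ribclear_dimension_error")
})

test_that("bilinear alignment preserves constants and matches a manual oracle", {
  cst <- matrix(0.37, 8, 8)
  down <- align_to_reference(cst, c(4, 4))
  expect_equal(align_to_reference(down, c(8, 8)), cst, tolerance = 1e-12)
  # 4x4 checkerboard upsampled to 8x8, against a literal center-aligned
  # bilinear interpolation loop
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  got <- align_to_reference(cb, c(8, 8))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    sr <- (i - 0.5) * 4 / 8 + 0.5
    sc <- (j - 0.5) * 4 / 8 + 0.5
    r0 <- min(max(floor(sr), 1), 4); r1 <- min(r0 + 1, 4)
    c0 <- min(max(floor(sc), 1), 4); c1 <- min(c0 + 1, 4)
    fr <- min(max(sr - r0, 0), 1); fc <- min(max(sc - c0, 0), 1)
    oracle[i, j] <- cb[r0, c0] * (1 - fr) * (1 - fc) +
      cb[r0, c1] * (1 - fr) * fc + cb[r1, c0] * fr * (1 - fc) +
      cb[r1, c1] * fr * fc
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("bone masks behave at the degenerate and constructed extremes", {
  t0 <- seeded_image(32, seed = 2)
  bm0 <- bone_mask_from_difference(t0, t0)
  expect_true(bm0$no_bone_signal)
  expect_identical(sum(bm0$mask), 0L)
  # overlay of amplitude 0.3 with a fixed 0.2 threshold recovers the
  # support exactly
  support <- matrix(FALSE, 32, 32); support[10:20, 5:25] <- TRUE
  orig <- t0 * 0.5 + support * 0.3
  bm <- bone_mask_from_difference(orig, t0 * 0.5, method = "fixed", value = 0.2)
  expect_identical(bm$mask, support)
  expect_identical(bm$threshold, 0.2)
  # raising a fixed threshold never grows the mask
  d <- abs(seeded_image(32, seed = 3))
  masks <- lapply(c(0.2, 0.4, 0.6), function(t)
    bone_mask_from_difference(d, d * 0, method = "fixed", value = t)$mask)
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
})

test_that("otsu masks overlap the ground-truth rib masks", {
  ious <- vapply(1:5, function(sd) {
    pr <- generate_phantom_pair(tiny_phantom_cfg(seed = sd))
    bm <- bone_mask_from_difference(pr$source, pr$target)
    sum(bm$mask & pr$rib_mask) / sum(bm$mask | pr$rib_mask)
  }, numeric(1))
  expect_true(all(ious >= 0.5))
})

test_that("region_analysis satisfies the weighted MAE conservation identity", {
  for (sd in 1:10) {
    orig <- seeded_image(24, seed = sd)
    tgt <- seeded_image(24, seed = sd + 30)
    pred <- seeded_image(24, seed = sd + 60)
    rr <- region_analysis(orig, tgt, pred)
    lhs <- rr$n_bone * rr$mae_bone + rr$n_nonbone * rr$mae_nonbone
    expect_lt(abs(lhs - (rr$n_bone + rr$n_nonbone) * rr$mae_total), 1e-9)
    expect_gte(rr$mae_bone, 0); expect_gte(rr$mae_nonbone, 0)
    expect_identical(rr$n_bone + rr$n_nonbone, length(tgt))
  }
})

test_that("perfect predictions and do-nothing baselines behave as computed", {
  pr <- generate_phantom_pair(tiny_phantom_cfg(seed = 12))
  perfect <- region_analysis(pr$source, pr$target, pr$target)
  expect_identical(perfect$mae_total, 0)
  expect_identical(perfect$edge_error_bone, 0)
  naive <- region_analysis(pr$source, pr$target, pr$source)
  d <- abs(pr$source - pr$target)
  expect_equal(naive$mae_bone, mean(d[naive$mask]), tolerance = 1e-12)
  expect_gt(naive$mae_bone, naive$mae_nonbone)
  # degenerate input: empty mask is flagged, not an error
  flat <- region_analysis(pr$target, pr$target, pr$target)
  expect_true(flat$no_bone_signal)
  expect_true(is.na(flat$mae_bone))
  td <- tidy(naive)
  expect_identical(td$region, c("bone", "nonbone", "total"))
})

test_that("predictions at another resolution are aligned before scoring", {
  pr <- generate_phantom_pair(tiny_phantom_cfg(seed = 13, size = 32))
  half <- align_to_reference(pr$target, c(16, 16))
  rr <- region_analysis(pr$source, pr$target, half)
  expect_identical(dim(rr$mask), dim(pr$target))
  expect_gte(rr$mae_total, 0)
})

test_that("residual_uniformity measures the bone/non-bone MAE ratio", {
  tgt <- seeded_image(16, seed = 14)
  mask <- matrix(FALSE, 16, 16); mask[1:8, ] <- TRUE
  expect_equal(residual_uniformity(tgt + 0.1, tgt, mask), 1, tolerance = 1e-12)
  conc <- tgt; conc[mask] <- conc[mask] + 0.5
  expect_gt(residual_uniformity(conc, tgt, mask), 10)
  expect_identical(residual_uniformity(conc, tgt, mask), Inf)
  resid <- seeded_image(16, seed = 15, lo = -0.1, hi = 0.1)
  got <- residual_uniformity(tgt + resid, tgt, mask)
  expect_equal(got, mean(abs(resid)[mask]) / mean(abs(resid)[!mask]),
               tolerance = 1e-12)
})

test_that("compare_models flags winners and recomputes column means", {
  pairs <- generate_dataset(tiny_phantom_cfg(seed = 16, size = 32), 3)
  good <- lapply(pairs, `[[`, "target")
  bad <- lapply(pairs, `[[`, "source")
  mid <- lapply(pairs, function(p) 0.5 * p$target + 0.5 * p$source)
  reports <- list(perfect = metric_report(pairs, good),
                  baseline = metric_report(pairs, bad),
                  halfway = metric_report(pairs, mid))
  tab <- compare_models(reports)
  expect_identical(nrow(tab), 3L)
  expect_match(tab$best[tab$model == "perfect"], "ms_ssim")
  expect_identical(tab$ms_ssim,
                   vapply(reports, function(r) mean(tidy(r)$ms_ssim),
                          numeric(1), USE.NAMES = FALSE))
  single <- compare_models(reports["halfway"])
  expect_match(single$best, "ms_ssim")
  expect_error(compare_models(setNames(reports[1:2], c("a", "a"))),
               class = "ribclear_argument_error")
  two <- compare_models(reports[c("halfway", "baseline")])
  expect_match(two$best[two$model == "halfway"], "ms_ssim")
})
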