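test_that("dice and pixel accuracy follow their confusion-count definitions", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(dice(a, b), 0)
  # TP = 3, FP = 1, FN = 1 -> 6/8
  pred <- matrix(0, 3, 3); truth <- matrix(0, 3, 3)
  pred[c(1, 2, 3, 4)] <- 1
  truth[c(1, 2, 3, 5)] <- 1
  expect_equal(dice(pred, truth), 0.75)
  expect_equal(dice(matrix(0, 2, 2), matrix(0, 2, 2)), 1)  # both empty
  expect_equal(dice(pred, truth), dice(truth, pred))       # symmetric
  expect_equal(pixel_accuracy(a, a), 1)
  expect_equal(pixel_accuracy(a, 1 - a), 0)
  expect_equal(pixel_accuracy(pred, truth), 7 / 9)
  expect_equal(pixel_accuracy(pred, truth), pixel_accuracy(truth, pred))
  expect_error(dice(a, matrix(0, 2, 2)), "shapes")
  expect_error(pixel_accuracy(a * 0.5, a), "binary")
})

test_that("the gate requires one 8-connected component above the area threshold", {
  disc <- function(S, cy, cx, r) {
    y <- matrix(seq_len(S), S, S); x <- t(y)
    ((y - cy)^2 + (x - cx)^2 <= r^2) + 0
  }
  one <- disc(500, 250, 250, 62)   # ~12,000 px
  expect_gt(sum(one), 10000)
  r1 <- qc_gate(one)
  expect_true(r1$pass)
  expect_equal(r1$n_components, 1)
  two <- disc(500, 150, 150, 44) + disc(500, 370, 370, 44)  # ~6000 px each
  expect_gt(sum(two), 10000)
  r2 <- qc_gate(two)
  expect_false(r2$pass)
  expect_equal(r2$n_components, 2)
  # absolute threshold override
  expect_false(qc_gate(disc(500, 250, 250, 40), min_area = 10000)$pass)
  expect_true(qc_gate(disc(500, 250, 250, 60), min_area = 10000)$pass)
  # fraction rule transfers across sizes: 4% of 64^2 = 163.84 px
  small <- disc(64, 32, 32, 8)    # ~201 px
  expect_true(qc_gate(small)$pass)
  expect_false(qc_gate(disc(64, 32, 32, 6))$pass)  # ~113 px
  expect_error(qc_gate(one * 0.5), "binary")
})

test_that("component counting agrees with a flood-fill oracle", {
  set.seed(7)
  for (i in 1:200) {
    m <- random_mask(32, p = runif(1, 0.15, 0.5))
    expect_equal(count_components(m), flood_count(m), info = paste("case", i))
  }
  # diagonal adjacency joins components (8-connectivity)
  d <- matrix(0, 4, 4); d[1, 1] <- 1; d[2, 2] <- 1
  expect_equal(count_components(d), 1)
})

test_that("growing a passing component never flips the gate to fail", {
  set.seed(11)
  S <- 64
  m <- matrix(0, S, S); m[20:44, 20:44] <- 1  # 625 px, passes at 4%
  expect_true(qc_gate(m)$pass)
  for (step in 1:30) {
    lab <- which(m == 1)
    # add a random border pixel 4-adjacent to the component
    cand <- setdiff(unique(c(lab - 1, lab + 1, lab - S, lab + S)), lab)
    cand <- cand[cand >= 1 & cand <= S * S]
    m[sample(cand, 1)] <- 1
    rep <- qc_gate(m)
    expect_true(rep$pass)
    expect_equal(rep$n_components, 1)
  }
})

test_that("area fractions print like the study table in both modes", {
  expect_equal(area_fraction_pct(10932, 500, "truncate"), 4.3)
  expect_equal(area_fraction_pct(10932, 500, "round"), 4.4)
  expect_equal(area_fraction_pct(19481, 500, "truncate"), 7.7)
  expect_equal(area_fraction_pct(19481, 500, "round"), 7.8)
  expect_equal(area_fraction_pct(10000, 500, "truncate"), 4.0)
  expect_equal(area_fraction_pct(10000, 500, "round"), 4.0)
  expect_error(area_fraction_pct(300000, 500), "exceeds")
})

test_that("pass rates print to one decimal in both modes", {
  reports <- data.frame(pass = rep(c(TRUE, FALSE), c(253, 654 - 253)))
  expect_equal(pass_rate(reports), 38.6)            # truncate (38.685)
  expect_equal(pass_rate(reports, "round"), 38.7)
  expect_equal(pass_rate(data.frame(pass = rep(TRUE, 5))), 100)
  expect_equal(pass_rate(data.frame(pass = c(TRUE, FALSE, FALSE))), 33.3)
  expect_error(pass_rate(list()), "no reports")
})

test_that("the segmenter improves with training and is seed-reproducible", {
  p <- quiet_params(32, seed = 1, noise_sd = 0.02)
  pairs <- lapply(1:12, function(i) {
    s <- generate_phantom_slice(p, seed = 100 + i)
    list(image = s$image, mask = s$mask)
  })
  cfg <- seg_config(steps = 250L, checkpoint_steps = c(25L, 250L), seed = 4)
  m1 <- train_segmenter(pairs, cfg)
  expect_equal(nrow(m1$checkpoints), 2)
  expect_gte(m1$checkpoints$dice[2], m1$checkpoints$dice[1])
  m2 <- train_segmenter(pairs, cfg)
  expect_identical(m1$checkpoints, m2$checkpoints)
  # prediction is deterministic and robust to degenerate input
  pm <- predict_mask(m1, pairs[[1]]$image)
  expect_identical(pm, predict_mask(m1, pairs[[1]]$image))
  expect_true(all(pm %in% c(0, 1)))
  zero <- predict_mask(m1, matrix(0, 32, 32))
  expect_true(is.numeric(sum(zero)))
  expect_error(predict_mask(m1, matrix(0, 16, 16)), "shape")
  expect_error(train_segmenter(list(), cfg), "non-empty")
  expect_error(train_segmenter(pairs[1], cfg), "batch_size")
})

test_that("a single pair is overfit to near-perfect Dice", {
  p <- quiet_params(32, seed = 1, noise_sd = 0.02)
  s <- generate_phantom_slice(p, seed = 9)
  cfg <- seg_config(batch_size = 1L, steps = 1600L, checkpoint_steps = 1600L,
                    seed = 5)
  m <- train_segmenter(list(list(image = s$image, mask = s$mask)), cfg)
  expect_gt(m$checkpoints$dice[1], 0.95)
})
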