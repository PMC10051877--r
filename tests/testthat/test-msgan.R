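# Brute-force oracle: enumerate pyramid sizes coarse_min * (1/ratio)^k that
# stay strictly below the finest min dimension, plus the finest scale itself.
enum_scales <- function(height, width, ratio = 0.75, coarse_min = 25,
                        cap = 250) {
  fh <- height; fw <- width
  if (max(fh, fw) > cap) {
    sc <- cap / max(fh, fw)
    fh <- max(round(fh * sc), coarse_min)
    fw <- max(round(fw * sc), coarse_min)
  }
  fmin <- min(fh, fw)
  k <- 0
  count <- 0
  while (coarse_min * (1 / ratio)^k < fmin) {
    count <- count + 1
    k <- k + 1
  }
  count + 1
}

test_that("a 500x500 image yields a 10-scale pyramid under defaults", {
  sched <- build_scale_schedule(500, 500)
  expect_equal(length(sched), 10)
  expect_equal(unname(sched$sizes[10, ]), c(250, 250))  # finest capped
  expect_equal(unname(sched$sizes[1, ]), c(25, 25))     # coarsest floor
})

test_that("scale schedules agree with brute-force enumeration and are monotone", {
  sides <- c(25, 33, 64, 100, 128, 250, 333, 500, 600)
  for (h in sides) for (w in c(h, min(h + 37, 600))) {
    for (ratio in c(0.6, 0.75)) {
      sched <- build_scale_schedule(h, w, ratio = ratio)
      expect_equal(length(sched), enum_scales(h, w, ratio = ratio),
                   info = paste(h, w, ratio))
      s <- sched$sizes
      if (nrow(s) > 1) {
        expect_true(all(diff(s[, 1]) > 0) && all(diff(s[, 2]) > 0))
        expect_gte(min(s[1, ]), 25)
        expect_lt(min(s[1, ]), 25 / ratio)
      }
      expect_lte(max(s[nrow(s), ]), 250)
    }
  }
  expect_equal(length(build_scale_schedule(25, 25)), 1)
  expect_error(build_scale_schedule(20, 300), "smaller")
  expect_equal(length(build_scale_schedule(128, 128)), enum_scales(128, 128))
})

# One tiny trained stack shared by the remaining blocks.
tiny_stack <- local({
  p <- quiet_params(32, seed = 1)
  img <- generate_phantom_slice(p, seed = 5)$image
  cfg <- singan_config("desk", channels = 4L, iters_per_scale = 30L, seed = 21)
  list(img = img, cfg = cfg, stack = train_single_image_gan(img, cfg))
})

test_that("training reduces reconstruction error at every scale", {
  log <- tiny_stack$stack$scale_log
  expect_true(all(log$mse_end < log$mse_start))
  expect_equal(tiny_stack$stack$sigmas[1], 1)
  expect_true(all(tiny_stack$stack$sigmas >= 0))
  expect_true(all(tiny_stack$stack$sigmas[-1] > 0))
})

test_that("training and sampling are seed-reproducible", {
  st2 <- train_single_image_gan(tiny_stack$img, tiny_stack$cfg)
  s1 <- singan_sample(tiny_stack$stack, length(tiny_stack$stack$schedule), 2,
                      seed = 7)
  s2 <- singan_sample(st2, length(st2$schedule), 2, seed = 7)
  expect_identical(s1, s2)
  expect_identical(s1, singan_sample(tiny_stack$stack,
                                     length(tiny_stack$stack$schedule), 2,
                                     seed = 7))
})

test_that("samples are clamped, diverse and distinct from the training image", {
  st <- tiny_stack$stack
  nsc <- length(st$schedule)
  smp <- singan_sample(st, nsc, 20, seed = 3)
  expect_true(all(vapply(smp, function(m) min(m) >= 0 && max(m) <= 1,
                         logical(1))))
  pixvar <- apply(simplify2array(smp), c(1, 2), var)
  expect_gt(max(pixvar), 0)
  mad_to_train <- vapply(smp, function(m) mean(abs(m - tiny_stack$img)),
                         numeric(1))
  expect_true(all(mad_to_train > 0))
  # the reconstruction path is closer to the training image than random draws
  rec <- singan_sample(st, nsc, 1, reconstruction = TRUE)[[1]]
  expect_lt(mean(abs(rec - tiny_stack$img)), min(mad_to_train))
  # resizing to an explicit output size
  big <- singan_sample(st, nsc, 1, seed = 2, output_size = 64)[[1]]
  expect_equal(dim(big), c(64, 64))
  expect_error(singan_sample(st, nsc + 1, 1, seed = 1), "scale_index")
})

test_that("coarsest-scale reconstruction sampling reproduces the stored reconstruction", {
  st <- tiny_stack$stack
  rec1 <- singan_sample(st, 1, 1, reconstruction = TRUE)[[1]]
  stored <- pmin(pmax((st$recons[[1]][, , 1] + 1) / 2, 0), 1)
  expect_identical(rec1, stored)
})

test_that("generate_pool records complete provenance and is deterministic", {
  p <- quiet_params(32, seed = 1)
  imgs <- lapply(1:2, function(i) generate_phantom_slice(p, seed = i)$image)
  cfg <- singan_config("desk", channels = 4L, iters_per_scale = 10L, seed = 31)
  pool <- generate_pool(imgs, per_image = 3, config = cfg)
  expect_equal(nrow(pool$manifest), 6)
  expect_true(all(pool$manifest$status == "ok"))
  expect_equal(sort(unique(pool$manifest$source_id)), c("src001", "src002"))
  nsc <- length(build_scale_schedule(32, 32, ratio = cfg$ratio))
  expect_true(all(pool$manifest$scale %in% seq(max(1, nsc - 2), nsc)))
  pool2 <- generate_pool(imgs, per_image = 3, config = cfg)
  expect_identical(pool$manifest, pool2$manifest)
  expect_identical(pool$samples, pool2$samples)
  # a failing image is recorded without aborting the pool
  bad <- list(imgs[[1]], matrix(0.5, 10, 10))
  pool3 <- generate_pool(bad, per_image = 1, config = cfg)
  expect_true(any(grepl("error", pool3$manifest$status)))
  expect_true(any(pool3$manifest$status == "ok"))
})

test_that("stacks serialize and reload to identical samplers", {
  dir <- tempfile("stack")
  save_singan(tiny_stack$stack, dir)
  st2 <- load_singan(dir)
  nsc <- length(tiny_stack$stack$schedule)
  expect_identical(singan_sample(tiny_stack$stack, nsc, 2, seed = 4),
                   singan_sample(st2, nsc, 2, seed = 4))
})
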