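test_that("stratified splits reproduce the published counts", {
  sp <- split_train_test(list(conventional = seq_len(790),
                              synthetic = seq_len(237)),
                         test_fraction = 0.25, seed = 1)
  expect_equal(sp$counts$test, c(198, 59))
  expect_equal(sp$counts$train, c(592, 178))
  tiny <- split_train_test(list(a = 1:4), 0.25, seed = 2)
  expect_equal(tiny$counts$test, 1)
  expect_equal(tiny$counts$train, 3)
  expect_error(split_train_test(list(a = 1:4), 1.5), "test_fraction")
  expect_error(split_train_test(list(a = integer(0)), 0.25), "non-empty")
})

test_that("split counts obey the round-half-up contract (integer oracle)", {
  fracs <- list(c(1L, 10L), c(1L, 5L), c(1L, 4L), c(1L, 2L))
  for (pq in fracs) {
    f <- pq[1] / pq[2]
    for (n in seq.int(1L, 1000L, by = 13L)) {
      sp <- split_train_test(list(x = seq_len(n)), f, seed = n)
      oracle <- (2L * n * pq[1] + pq[2]) %/% (2L * pq[2])  # floor(nf + 1/2)
      expect_equal(sp$counts$test, oracle, info = paste(n, f))
      expect_equal(sp$counts$train + sp$counts$test, n)
      expect_setequal(c(sp$train$x, sp$test$x), seq_len(n))
    }
  }
  # reproducibility
  s1 <- split_train_test(list(x = 1:100), 0.25, seed = 7)
  s2 <- split_train_test(list(x = 1:100), 0.25, seed = 7)
  expect_identical(s1, s2)
})

test_that("the CNN separates lesioned from normal phantoms", {
  train_x <- c(lesion_batch(20, TRUE, seed_base = 0),
               lesion_batch(20, FALSE, seed_base = 500))
  train_y <- rep(c(1, 0), each = 20)
  test_x <- c(lesion_batch(10, TRUE, seed_base = 900),
              lesion_batch(10, FALSE, seed_base = 1300))
  test_y <- rep(c(1, 0), each = 10)
  cfg <- cnn_config(channels = c(4L, 8L, 8L), seed = 3)
  m <- train_binary_cnn(train_x, train_y, cfg)
  expect_lt(m$loss[length(m$loss)], m$loss[1])
  acc <- evaluate_accuracy(m, test_x, test_y)
  expect_gte(acc, 90)
  # same seed, same metrics
  m2 <- train_binary_cnn(train_x, train_y, cfg)
  expect_equal(evaluate_accuracy(m2, test_x, test_y), acc)
  expect_error(train_binary_cnn(train_x, rep(1, 40), cfg), "both classes")
})

test_that("shuffled labels give chance-level held-out accuracy", {
  train_x <- c(lesion_batch(16, TRUE, seed_base = 0),
               lesion_batch(16, FALSE, seed_base = 500))
  set.seed(10)
  train_y <- sample(rep(c(1, 0), each = 16))  # labels decoupled from images
  test_x <- c(lesion_batch(12, TRUE, seed_base = 900),
              lesion_batch(12, FALSE, seed_base = 1300))
  test_y <- rep(c(1, 0), each = 12)
  cfg <- cnn_config(channels = c(4L, 8L, 8L), epochs = 8L, seed = 4)
  m <- train_binary_cnn(train_x, train_y, cfg)
  acc <- evaluate_accuracy(m, test_x, test_y)
  se3 <- 3 * 100 * sqrt(0.25 / length(test_y))
  expect_lt(abs(acc - 50), se3 + 1)
})

test_that("accuracy is monotone in lesion contrast", {
  accs <- sapply(c(0.1, 0.2, 0.4), function(contrast) {
    mean(sapply(1:5, function(seed) {
      tx <- c(lesion_batch(12, TRUE, contrast = contrast,
                           seed_base = 2000 * seed),
              lesion_batch(12, FALSE, contrast = contrast,
                           seed_base = 2000 * seed + 700))
      ty <- rep(c(1, 0), each = 12)
      ex <- c(lesion_batch(8, TRUE, contrast = contrast,
                           seed_base = 2000 * seed + 1400),
              lesion_batch(8, FALSE, contrast = contrast,
                           seed_base = 2000 * seed + 1700))
      ey <- rep(c(1, 0), each = 8)
      cfg <- cnn_config(channels = c(4L, 8L, 8L), epochs = 12L, seed = seed)
      evaluate_accuracy(train_binary_cnn(tx, ty, cfg), ex, ey)
    }))
  })
  expect_true(all(diff(accs) >= 0))
})

test_that("evaluate_accuracy equals hand-computed bookkeeping", {
  train_x <- c(lesion_batch(10, TRUE, seed_base = 0),
               lesion_batch(10, FALSE, seed_base = 500))
  m <- train_binary_cnn(train_x, rep(c(1, 0), each = 10),
                        cnn_config(channels = c(4L, 8L, 8L), epochs = 4L,
                                   seed = 5))
  test_x <- c(lesion_batch(10, TRUE, seed_base = 900),
              lesion_batch(10, FALSE, seed_base = 1300))
  test_y <- rep(c(1, 0), each = 10)
  probs <- predict(m, test_x)
  byhand <- 100 * sum((probs >= 0.5) == (test_y == 1)) / length(test_y)
  expect_equal(evaluate_accuracy(m, test_x, test_y), byhand)
  # a constant-output model scores 50 on a balanced test set
  const <- m
  const$net$fc$W[] <- 0
  const$net$fc$b <- 10       # sigmoid ~ 1: always calls the positive class
  expect_equal(evaluate_accuracy(const, test_x, test_y), 50)
  expect_error(evaluate_accuracy(m, list(), numeric(0)), "empty")
})

test_that("the anomaly screen reports rates by source and is deterministic", {
  train_x <- c(lesion_batch(20, TRUE, seed_base = 0),
               lesion_batch(20, FALSE, seed_base = 500))
  m <- train_binary_cnn(train_x, rep(c(1, 0), each = 20),
                        cnn_config(channels = c(4L, 8L, 8L), seed = 3))
  pos <- lesion_batch(10, TRUE, seed_base = 3000)
  neg <- lesion_batch(10, FALSE, seed_base = 4000)
  scr <- anomaly_screen(m, c(pos, neg), source = rep(c("a", "b"), each = 10))
  expect_named(scr$rate_by_source, c("a", "b"))
  expect_gte(scr$rate_by_source[["a"]], 80)  # lesioned batch detected
  expect_lte(scr$rate_by_source[["b"]], 20)  # lesion-free batch mostly clear
  scr2 <- anomaly_screen(m, c(pos, neg), source = rep(c("a", "b"), each = 10))
  expect_identical(scr$calls, scr2$calls)
  expect_error(anomaly_screen(list(), pos), "binary_cnn")
})
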