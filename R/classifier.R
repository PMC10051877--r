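# Validation harness: class-stratified train/test splitting with round-half-
# up test counts, a small convolutional binary classifier, and the anomaly
# (lesion) screen comparing detection rates between conventional phantoms
# and GAN samples.

#' Stratified train/test split
#'
#' Per class, the test size is `round_half_up(n * test_fraction)` items
#' drawn uniformly without replacement; the remainder trains.  This
#' rounding reproduces both published splits: 790 at 25% -> 198 test / 592
#' train and 237 at 25% -> 59 test / 178 train.
#'
#' @param class_items named list mapping class label to a vector (or list)
#'   of items.
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` (named lists of items per class) and
#'   `counts` (data frame: class, total, train, test).
#' @export
split_train_test <- function(class_items, test_fraction = 0.25, seed = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (length(class_items) == 0 || any(lengths(class_items) == 0))
    stop("every class must be non-empty")
  if (is.null(names(class_items)))
    names(class_items) <- paste0("class", seq_along(class_items))
  with_seed(seed, {
    train <- list()
    test <- list()
    counts <- list()
    for (cl in names(class_items)) {
      items <- class_items[[cl]]
      n <- length(items)
      n_test <- round_half_up(n * test_fraction)
      idx <- sample.int(n, n_test)
      test[[cl]] <- items[idx]
      train[[cl]] <- items[setdiff(seq_len(n), idx)]
      counts[[cl]] <- data.frame(class = cl, total = n, train = n - n_test,
                                 test = n_test, stringsAsFactors = FALSE)
    }
    list(train = train, test = test, counts = do.call(rbind, counts))
  })
}

#' Classifier configuration
#'
#' Three conv blocks (3x3 convolution, leaky rectifier, 2x2 max pooling)
#' followed by a dense sigmoid head; adaptive-moment updates.
#'
#' @param channels channel count per conv block (length 3).
#' @param epochs training epochs.
#' @param learning_rate adaptive-moment step size.
#' @param batch_size images per update.
#' @param seed integer seed.
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(channels = c(8L, 16L, 16L), epochs = 25L,
                       learning_rate = 3e-3, batch_size = 4L, seed = 1L) {
  stopifnot(length(channels) == 3, learning_rate > 0, epochs >= 1,
            batch_size >= 1)
  structure(list(channels = as.integer(channels), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "cnn_config")
}

cnn_init <- function(cfg, side) {
  ch <- cfg$channels
  nf <- (side / 8)^2 * ch[3]
  list(c1 = conv_layer(1, ch[1]), c2 = conv_layer(ch[1], ch[2]),
       c3 = conv_layer(ch[2], ch[3]),
       fc = list(W = matrix(stats::rnorm(nf, sd = 1 / sqrt(nf)), nf, 1),
                 b = 0))
}

cnn_fwd <- function(net, img) {
  x <- as_t3(img)
  a1 <- lrelu_f(cpp_conv_fwd(x, net$c1$W, net$c1$b))
  p1 <- cpp_maxpool2(a1$y)
  a2 <- lrelu_f(cpp_conv_fwd(p1$y, net$c2$W, net$c2$b))
  p2 <- cpp_maxpool2(a2$y)
  a3 <- lrelu_f(cpp_conv_fwd(p2$y, net$c3$W, net$c3$b))
  p3 <- cpp_maxpool2(a3$y)
  f <- as.numeric(p3$y)
  z <- sum(f * net$fc$W) + net$fc$b
  prob <- 1 / (1 + exp(-z))
  list(prob = prob,
       cache = list(x = x, a1 = a1, p1 = p1, a2 = a2, p2 = p2, a3 = a3,
                    p3 = p3, f = f))
}

cnn_bwd <- function(net, cache, gz) {
  g <- list(fc = list(W = matrix(gz * cache$f, ncol = 1), b = gz))
  gp3 <- array(gz * as.numeric(net$fc$W), dim = dim(cache$p3$y))
  ga3 <- cpp_maxpool2_back(gp3, cache$p3$idx, dim(cache$a3$y)) * cache$a3$m
  bk <- cpp_conv_gradw(cache$p2$y, ga3, 3L)
  g$c3 <- list(W = bk$gw, b = bk$gb)
  gp2 <- cpp_conv_gradx(ga3, net$c3$W)
  ga2 <- cpp_maxpool2_back(gp2, cache$p2$idx, dim(cache$a2$y)) * cache$a2$m
  bk <- cpp_conv_gradw(cache$p1$y, ga2, 3L)
  g$c2 <- list(W = bk$gw, b = bk$gb)
  gp1 <- cpp_conv_gradx(ga2, net$c2$W)
  ga1 <- cpp_maxpool2_back(gp1, cache$p1$idx, dim(cache$a1$y)) * cache$a1$m
  bk <- cpp_conv_gradw(cache$x, ga1, 3L)
  g$c1 <- list(W = bk$gw, b = bk$gb)
  g
}

#' Train a small binary image classifier
#'
#' Three conv/pool blocks and a dense sigmoid head trained on binary
#' cross-entropy with adaptive-moment updates; seed-reproducible.
#'
#' @param images list of square matrices (side divisible by 8), values in
#'   `[0, 1]`.
#' @param labels 0/1 vector (or two-level factor), one per image; both
#'   classes must be present.
#' @param config a [cnn_config()] object.
#' @return an object of class `binary_cnn` with the trained `net`, the
#'   `config`, the class `levels` and an epoch `loss` trace.
#' @export
train_binary_cnn <- function(images, labels, config = cnn_config()) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must have exactly two levels")
    labels <- as.integer(as.character(labels) == lv[2])
  } else lv <- c("0", "1")
  labels <- as.numeric(labels)
  if (length(images) != length(labels)) stop("images/labels length mismatch")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  side <- nrow(images[[1]])
  if (side %% 8 != 0) stop("image side must be divisible by 8")
  set.seed(config$seed)
  net <- cnn_init(config, side)
  # Adam state over the 4 parameter groups
  st <- lapply(net, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                     mb = l$b * 0, vb = l$b * 0))
  t <- 0
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(images))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      grads <- NULL
      for (i in idx) {
        fw <- cnn_fwd(net, images[[i]])
        p <- min(max(fw$prob, 1e-7), 1 - 1e-7)
        ep_loss <- ep_loss - (labels[i] * log(p) + (1 - labels[i]) * log(1 - p))
        gi <- cnn_bwd(net, fw$cache, fw$prob - labels[i])
        grads <- if (is.null(grads)) gi else
          mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                 grads, gi, SIMPLIFY = FALSE)
      }
      t <- t + 1
      for (nm in names(net)) {
        for (pn in c("W", "b")) {
          gv <- grads[[nm]][[pn]] / length(idx)
          mk <- paste0("m", pn); vk <- paste0("v", pn)
          st[[nm]][[mk]] <- 0.9 * st[[nm]][[mk]] + 0.1 * gv
          st[[nm]][[vk]] <- 0.999 * st[[nm]][[vk]] + 0.001 * gv^2
          mh <- st[[nm]][[mk]] / (1 - 0.9^t)
          vh <- st[[nm]][[vk]] / (1 - 0.999^t)
          net[[nm]][[pn]] <- net[[nm]][[pn]] -
            config$learning_rate * mh / (sqrt(vh) + 1e-8)
        }
      }
    }
    losses[ep] <- ep_loss / length(images)
    if (!is.finite(losses[ep])) stop("non-finite loss at epoch ", ep)
  }
  structure(list(net = net, config = config, levels = lv, side = side,
                 loss = losses),
            class = "binary_cnn")
}

#' @export
print.binary_cnn <- function(x, ...) {
  cat("Binary CNN (", x$side, "x", x$side, " input, classes: ",
      paste(x$levels, collapse = " vs "), ")\n", sep = "")
  cat("  epoch loss: ", signif(x$loss[1], 3), " -> ",
      signif(x$loss[length(x$loss)], 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn train_binary_cnn `predict()` method: probability of the
#'   second class level for each image.
#' @param object a `binary_cnn`; `newdata` a list of image matrices.
#' @param newdata,... see above.
#' @export
predict.binary_cnn <- function(object, newdata, ...) {
  vapply(newdata, function(im) cnn_fwd(object$net, im)$prob, numeric(1))
}

#' Classification accuracy on a labelled test set
#'
#' `100 * correct / total` at probability threshold 0.5.
#'
#' @param model a trained `binary_cnn`.
#' @param images list of image matrices.
#' @param labels 0/1 vector or factor with the model's levels.
#' @return percent accuracy.
#' @export
evaluate_accuracy <- function(model, images, labels) {
  if (length(images) == 0) stop("empty test set")
  if (is.factor(labels) || is.character(labels))
    labels <- as.integer(as.character(labels) == model$levels[2])
  pred <- as.integer(predict(model, images) >= 0.5)
  100 * mean(pred == as.numeric(labels))
}

#' Anomaly screen: lesion detection rates by image source
#'
#' Applies a tumor-vs-normal classifier to a batch and reports the per-image
#' anomaly probability, the binary call at threshold 0.5 and the detection
#' rate separately per image source (e.g. conventional phantoms vs GAN
#' samples), so parity between sources can be checked as
#' `|rate_synthetic - rate_conventional|`.
#'
#' @param model a trained `binary_cnn` (positive class = tumor).
#' @param images list of image matrices.
#' @param source optional character vector of image sources.
#' @return list with `calls` (data frame: source, prob, call) and
#'   `rate_by_source` (percent of positive calls per source).
#' @export
anomaly_screen <- function(model, images, source = NULL) {
  if (!inherits(model, "binary_cnn")) stop("model must be a trained binary_cnn")
  if (length(images) == 0) stop("no images to screen")
  if (is.null(source)) source <- rep("all", length(images))
  prob <- predict(model, images)
  calls <- data.frame(source = source, prob = prob, call = prob >= 0.5,
                      stringsAsFactors = FALSE)
  rate <- vapply(split(calls$call, calls$source),
                 function(z) 100 * mean(z), numeric(1))
  list(calls = calls, rate_by_source = rate)
}
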