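# Shared fixtures, all generated in code at test time.

quiet_params <- function(size = 64, ...) {
  args <- list(image_size = size, noise_sd = 0, bias_field_amplitude = 0,
               lesion_probability = 0)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(phantom_params, args)
}

# A blob-free random binary mask for component-counting property tests.
random_mask <- function(n = 32, p = 0.3) {
  matrix(as.numeric(stats::runif(n * n) < p), n, n)
}

# Independent flood-fill component counter (8-connectivity), queue-based,
# written without reference to the package's C++ labeling.
flood_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0
  for (j0 in seq_len(w)) for (i0 in seq_len(h)) {
    if (mask[i0, j0] == 0 || seen[i0, j0]) next
    count <- count + 1
    queue <- list(c(i0, j0))
    seen[i0, j0] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > h || qj < 1 || qj > w) next
        if (mask[qi, qj] == 1 && !seen[qi, qj]) {
          seen[qi, qj] <- TRUE
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  count
}

# Lesion/normal phantom sets for the classifier tests.
lesion_batch <- function(n, lesion, size = 48, contrast = 0.4, noise = 0.02,
                         seed_base = 0) {
  p <- phantom_params(image_size = size,
                      lesion_probability = if (lesion) 1 else 0,
                      lesion_contrast = contrast, noise_sd = noise)
  lapply(seq_len(n), function(i)
    generate_phantom_slice(p, seed = seed_base + i)$image)
}
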