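# Shared small helpers: rounding conventions, seed substreams, validation.

#' Round half up
#'
#' Rounds `x` to `digits` decimals with halves rounded away from zero upward
#' (the convention behind the printed study tables), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

truncate_decimal <- function(x, digits = 0) {
  f <- 10^digits
  trunc(x * f + 1e-9) / f
}

# Derives a reproducible per-component seed from one global seed, so the
# phantom, GAN, segmenter and rater streams are independently reproducible.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 2654435 + h * 97) %% 2147483647)
}

# Runs `expr` under a temporary RNG seed and restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

is_binary_mask <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}

stop_if_not_mask <- function(m, what = "mask") {
  if (!is_binary_mask(m)) stop(what, " must be a strictly binary matrix", call. = FALSE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
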