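# Blinded rater-study scoring and the associated statistics: percent
# correct, false positives (conventional called synthetic), false negatives
# (synthetic called conventional), pairwise concordance, chi-square
# association, Wilcoxon signed-rank and two-sample t tests, plus the
# random-without-replacement study designer.

as_study_table <- function(table) {
  need <- c("rater_id", "group", "image_id", "true_class", "answer")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("study table needs columns ", paste(need, collapse = ", "))
  raters <- unique(table$rater_id)
  images <- unique(table$image_id)
  counts <- table(table$rater_id, table$image_id)
  if (any(counts != 1)) {
    gaps <- which(counts != 1, arr.ind = TRUE)
    stop("every rater must answer every image exactly once; problems: ",
         paste(utils::head(paste(rownames(counts)[gaps[, 1]],
                                 colnames(counts)[gaps[, 2]], sep = "/"), 5),
               collapse = ", "))
  }
  table
}

#' Score a blinded rater study
#'
#' Per experience group: percent correct over all answers; percent false
#' positives (conventional images answered synthetic, out of all answers to
#' conventional images); percent false negatives (synthetic images answered
#' conventional, out of all answers to synthetic images); and pairwise
#' concordance for groups with at least two raters.  Percentages are
#' rounded half-up to integers, matching the study-table presentation.
#'
#' @param table a study table (see [simulate_raters()]) with columns
#'   `rater_id`, `group`, `image_id`, `true_class`, `answer`.
#' @return data frame with one row per group: `group`, `n_raters`,
#'   `pct_correct`, `pct_fp`, `pct_fn`, `pct_concordance`.
#' @export
score_study <- function(table) {
  table <- as_study_table(table)
  groups <- unique(table$group)
  rows <- lapply(groups, function(g) {
    tg <- table[table$group == g, ]
    conv <- tg$true_class == "conventional"
    data.frame(group = g, n_raters = length(unique(tg$rater_id)),
               pct_correct = round_half_up(100 * mean(tg$answer == tg$true_class)),
               pct_fp = round_half_up(100 * mean(tg$answer[conv] == "synthetic")),
               pct_fn = round_half_up(100 * mean(tg$answer[!conv] == "conventional")),
               pct_concordance = if (length(unique(tg$rater_id)) >= 2)
                 concordance(table, g) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise rater concordance
#'
#' Mean over all rater pairs in a group of the fraction of images the two
#' raters answered identically, as a percent rounded half-up to an integer.
#'
#' @param table a study table.
#' @param group group label to score.
#' @return percent in `[0, 100]`.
#' @export
concordance <- function(table, group) {
  table <- as_study_table(table)
  tg <- table[table$group == group, ]
  raters <- unique(tg$rater_id)
  if (length(raters) < 2) stop("concordance needs at least 2 raters")
  imgs <- sort(unique(tg$image_id))
  amat <- vapply(raters, function(r) {
    tr <- tg[tg$rater_id == r, ]
    tr$answer[match(imgs, tr$image_id)]
  }, character(length(imgs)))
  pairs <- utils::combn(length(raters), 2)
  agree <- apply(pairs, 2, function(p) mean(amat[, p[1]] == amat[, p[2]]))
  round_half_up(100 * mean(agree))
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction; p-value from the
#' chi-square upper tail.
#'
#' @param contingency matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column marginal")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(ht$expected <= 0)) stop("all expected counts must be positive")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped and tied ranks averaged.  The exact
#' distribution is used for n <= 25 untied differences, the normal
#' approximation (without continuity correction) otherwise.
#'
#' @param paired_a,paired_b paired numeric vectors.
#' @return list with `statistic` (V), `n` (nonzero differences), `p`,
#'   `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) stop("paired vectors differ in length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences are zero: test undefined")
  ties <- any(duplicated(abs(d)))
  use_exact <- length(d) <= 25 && !ties
  ht <- suppressWarnings(stats::wilcox.test(d, exact = use_exact,
                                            correct = FALSE))
  list(statistic = unname(ht$statistic), n = length(d),
       p = unname(ht$p.value), exact = use_exact)
}

#' Two-sample t test
#'
#' Two-sided; the classical `student` variant pools variances, `welch` does
#' not.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param variant `"student"` or `"welch"`.
#' @return list with `statistic`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0,
                                        df = length(a) + length(b) - 2, p = 1))
    stop("degenerate variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = variant == "student")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Design a blinded study by random sampling without replacement
#'
#' Draws `n_conventional` and `n_synthetic` image ids uniformly without
#' replacement from a QC-passed pool, reproducibly by seed.
#'
#' @param pool data frame with columns `image_id` and `class`
#'   (`"conventional"`/`"synthetic"`).
#' @param n_conventional,n_synthetic counts to draw (>= 1).
#' @param seed integer seed.
#' @param exposure_seconds seconds each image is shown (metadata; default 5).
#' @return object of class `study_design`: the selection data frame plus the
#'   design parameters.
#' @export
design_study <- function(pool, n_conventional, n_synthetic, seed = NULL,
                         exposure_seconds = 5) {
  stopifnot(is.data.frame(pool), all(c("image_id", "class") %in% names(pool)))
  if (n_conventional < 1 || n_synthetic < 1) stop("counts must be >= 1")
  conv <- pool$image_id[pool$class == "conventional"]
  syn <- pool$image_id[pool$class == "synthetic"]
  if (length(conv) < n_conventional || length(syn) < n_synthetic)
    stop("pool too small: have ", length(conv), " conventional and ",
         length(syn), " synthetic")
  with_seed(seed, {
    sel_c <- if (length(conv) == n_conventional) conv
             else sample(conv, n_conventional)
    sel_s <- if (length(syn) == n_synthetic) syn
             else sample(syn, n_synthetic)
    selection <- data.frame(
      image_id = c(sel_c, sel_s),
      true_class = rep(c("conventional", "synthetic"),
                       c(n_conventional, n_synthetic)),
      stringsAsFactors = FALSE)
    structure(list(selection = selection,
                   n_conventional = n_conventional,
                   n_synthetic = n_synthetic,
                   exposure_seconds = exposure_seconds,
                   selection_mode = "random_without_replacement",
                   seed = seed),
              class = "study_design")
  })
}

#' @export
print.study_design <- function(x, ...) {
  cat("Blinded study design:", x$n_conventional, "conventional +",
      x$n_synthetic, "synthetic images,", x$exposure_seconds,
      "s exposure,", x$selection_mode, "\n")
  invisible(x)
}
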