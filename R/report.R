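#' Summarise one image's oyster measurements
#'
#' Count, arithmetic means and sample (n-1) standard deviations of length
#' and width. An empty measurement list yields count 0 with missing (`NA`)
#' means rather than zeros; a single oyster reports sd 0 with a
#' degenerate-sample flag.
#'
#' @param measurements data.frame with `length_mm` and `width_mm` columns
#'   (e.g. the output of [refine()]).
#' @param image_id identifier carried into the report.
#' @return An `image_report` list: `image`, `count`, `mean_length_mm`,
#'   `mean_width_mm`, `sd_length_mm`, `sd_width_mm`, `degenerate` (TRUE when
#'   count < 2) and `oysters` (the per-oyster rows).
#' @export
summarize_image <- function(measurements, image_id = NA_character_) {
  n <- nrow(measurements)
  if (n == 0L) {
    rep <- list(image = image_id, count = 0L,
                mean_length_mm = NA_real_, mean_width_mm = NA_real_,
                sd_length_mm = NA_real_, sd_width_mm = NA_real_,
                degenerate = TRUE, oysters = measurements)
  } else {
    rep <- list(
      image = image_id, count = n,
      mean_length_mm = mean(measurements$length_mm),
      mean_width_mm = mean(measurements$width_mm),
      sd_length_mm = if (n > 1L) stats::sd(measurements$length_mm) else 0,
      sd_width_mm = if (n > 1L) stats::sd(measurements$width_mm) else 0,
      degenerate = n < 2L, oysters = measurements)
  }
  structure(rep, class = "image_report")
}

#' @export
print.image_report <- function(x, ...) {
  cat(sprintf(
    "<image_report %s: %d oysters, length %.1f +/- %.1f mm, width %.1f +/- %.1f mm%s>\n",
    x$image, x$count, x$mean_length_mm, x$sd_length_mm, x$mean_width_mm,
    x$sd_width_mm, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Write an image report as JSON
#'
#' Schema: `{image, count, mean_length_mm, mean_width_mm, sd_length_mm,
#' sd_width_mm, oysters: [...]}`.
#'
#' @param report an `image_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "image_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(path)
}

#' Combine image reports into a batch table
#'
#' @param reports list of `image_report`.
#' @return A data.frame with one row per image.
#' @export
batch_report <- function(reports) {
  out <- do.call(rbind, lapply(reports, function(r)
    data.frame(image = r$image, count = r$count,
               mean_length_mm = r$mean_length_mm,
               mean_width_mm = r$mean_width_mm,
               sd_length_mm = r$sd_length_mm,
               sd_width_mm = r$sd_width_mm)))
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test with the normal approximation
#'
#' Computes the signed-rank test on paired samples the way the classic
#' statistical packages report it: differences `a - b` are taken, zero
#' differences are dropped as ties, absolute differences are ranked with
#' mid-ranks for equal values, and the large-sample Z statistic is formed
#' from the rank sums without continuity correction,
#' \deqn{Z = (W - n(n+1)/4) / \sqrt{n(n+1)(2n+1)/24 - \sum(t^3 - t)/48}}
#' where the tie term sums over groups of equal absolute differences.
#'
#' Two Z statistics are reported. `z` follows the reporting convention of
#' the classic packages, using the *smaller* of the two rank sums as W (so
#' `z <= 0` always); `z_signed` uses the sum of positive ranks, so it is
#' antisymmetric in the two samples (`z_signed(a, b) = -z_signed(b, a)`).
#' Both have the same magnitude, and the two-tailed p-value is computed from
#' it.
#'
#' @param a,b numeric vectors of equal length (>= 2); `a` is conventionally
#'   the system measurement and `b` the manual one.
#' @return A `wilcoxon_result` with `n_negative`, `n_positive`, `n_ties`,
#'   `sum_negative_ranks`, `sum_positive_ranks`, `mean_negative_rank`,
#'   `mean_positive_rank`, `z`, `z_signed`, `p_two_tailed` and
#'   `all_ties` (TRUE when every pair is tied; then z and p are `NA`).
#' @export
wilcoxon_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  n_ties <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(
      n_negative = 0L, n_positive = 0L, n_ties = n_ties,
      sum_negative_ranks = 0, sum_positive_ranks = 0,
      mean_negative_rank = NA_real_, mean_positive_rank = NA_real_,
      z = NA_real_, z_signed = NA_real_, p_two_tailed = NA_real_,
      all_ties = TRUE), class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  pos <- d > 0
  w_pos <- sum(r[pos]); w_neg <- sum(r[!pos])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z_signed <- (w_pos - mu) / sqrt(sigma2)
  structure(list(
    n_negative = sum(!pos), n_positive = sum(pos), n_ties = n_ties,
    sum_negative_ranks = w_neg, sum_positive_ranks = w_pos,
    mean_negative_rank = if (any(!pos)) w_neg / sum(!pos) else NA_real_,
    mean_positive_rank = if (any(pos)) w_pos / sum(pos) else NA_real_,
    z = -abs(z_signed),                 # smaller-rank-sum convention
    z_signed = z_signed,
    p_two_tailed = 2 * stats::pnorm(-abs(z_signed)),
    all_ties = FALSE), class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$all_ties) {
    cat("<wilcoxon_result: all pairs tied, Z undefined>\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("<wilcoxon_result: %d negative (sum %.2f, mean %.2f), ",
           "%d positive (sum %.2f, mean %.2f), %d ties, Z = %.2f, ",
           "p = %.3f>\n"),
    x$n_negative, x$sum_negative_ranks, x$mean_negative_rank,
    x$n_positive, x$sum_positive_ranks, x$mean_positive_rank,
    x$n_ties, x$z, x$p_two_tailed))
  invisible(x)
}

#' Construct paired samples with a prescribed signed-rank structure
#'
#' Builds vectors `a`, `b` whose paired differences have exactly the given
#' negative ranks, positive ranks and number of zero ties: all absolute
#' differences are distinct integers, so the rank of each difference equals
#' its magnitude. Useful for reproducing a published rank table.
#'
#' @param negative_ranks integer ranks of the pairs where `a < b`.
#' @param positive_ranks integer ranks of the pairs where `a > b`.
#' @param n_ties number of exactly tied pairs.
#' @param baseline value of `b` (default 100, arbitrary).
#' @return List with components `a` and `b`.
#' @export
pairs_from_rank_structure <- function(negative_ranks, positive_ranks,
                                      n_ties = 0L, baseline = 100) {
  ranks <- sort(c(negative_ranks, positive_ranks))
  if (!identical(as.integer(ranks), seq_along(ranks)))
    stop("negative_ranks and positive_ranks must partition 1..n")
  d <- c(positive_ranks, -negative_ranks, rep(0, n_ties))
  list(a = baseline + d, b = rep(baseline, length(d)))
}
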