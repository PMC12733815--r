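test_that("image summaries use sample sd and flag degenerate counts", {
  m <- data.frame(length_mm = c(50, 60, 70), width_mm = c(25, 30, 35))
  rep <- summarize_image(m, "img1")
  expect_equal(rep$count, 3L)
  expect_equal(rep$mean_length_mm, 60)
  expect_equal(rep$sd_length_mm, 10)          # sample sd of 50,60,70
  expect_false(rep$degenerate)

  one <- summarize_image(data.frame(length_mm = 60, width_mm = 30), "img2")
  expect_equal(one$sd_length_mm, 0)
  expect_true(one$degenerate)

  none <- summarize_image(data.frame(length_mm = numeric(),
                                     width_mm = numeric()), "img3")
  expect_equal(none$count, 0L)
  expect_true(is.na(none$mean_length_mm))     # missing, not zero
})

test_that("report JSON and batch tables carry the summary fields", {
  m <- data.frame(length_mm = c(60, 70), width_mm = c(30, 35))
  rep <- summarize_image(m, "a")
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$count, 2L)
  expect_equal(back$mean_length_mm, 65)
  expect_length(back$oysters, 2L)

  tab <- batch_report(list(rep, summarize_image(m * 2, "b")))
  expect_equal(tab$image, c("a", "b"))
  expect_equal(tab$mean_width_mm, c(32.5, 65))
})

test_that("signed-rank machinery matches hand-computed rank structure", {
  # 4 pairs: differences -3, +1, -2, 0 -> ranks of |d|: 3, 1, 2
  w <- wilcoxon_paired(c(7, 11, 8, 5), c(10, 10, 10, 5))
  expect_equal(w$n_ties, 1L)
  expect_equal(w$n_negative, 2L)
  expect_equal(w$n_positive, 1L)
  expect_equal(w$sum_negative_ranks, 5)
  expect_equal(w$sum_positive_ranks, 1)
  expect_equal(w$mean_negative_rank, 2.5)
})

test_that("rank sums always partition n(n+1)/2", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- round(rnorm(n, 50, 10), 1)
    b <- round(rnorm(n, 50, 10), 1)
    w <- wilcoxon_paired(a, b)
    nn <- w$n_negative + w$n_positive
    expect_equal(w$sum_negative_ranks + w$sum_positive_ranks,
                 nn * (nn + 1) / 2)
  }
})

test_that("z_signed is antisymmetric and |z| matches it", {
  set.seed(8)
  a <- rnorm(25, 60, 8); b <- rnorm(25, 58, 8)
  w1 <- wilcoxon_paired(a, b)
  w2 <- wilcoxon_paired(b, a)
  expect_equal(w1$z_signed, -w2$z_signed)
  expect_equal(w1$z, w2$z)                    # reporting convention: <= 0
  expect_equal(w1$z, -abs(w1$z_signed))
})

test_that("p-values agree with the reference implementation", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    a <- round(rnorm(n, 50, 5))               # integers force ties
    b <- round(rnorm(n, 50, 5))
    if (all(a == b)) next
    w <- wilcoxon_paired(a, b)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                         correct = FALSE))
    expect_equal(w$p_two_tailed, ref$p.value, tolerance = 1e-10)
    expect_equal(w$sum_positive_ranks, unname(ref$statistic))
  }
})

test_that("identical samples are flagged as all ties", {
  w <- wilcoxon_paired(c(1, 2, 3), c(1, 2, 3))
  expect_true(w$all_ties)
  expect_true(is.na(w$z))
})

test_that("under the null the |Z| > 1.96 rate is near 5 percent", {
  set.seed(99)
  hits <- replicate(1000, {
    a <- rnorm(20); b <- rnorm(20)
    abs(wilcoxon_paired(a, b)$z_signed) > 1.96
  })
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("rank structures can be rebuilt into paired samples", {
  pos <- c(2, 5, 11, 12, 14)
  neg <- setdiff(1:20, pos)
  p <- pairs_from_rank_structure(neg, pos, n_ties = 1)
  w <- wilcoxon_paired(p$a, p$b)
  expect_equal(w$n_negative, 15L)
  expect_equal(w$n_positive, 5L)
  expect_equal(w$n_ties, 1L)
  expect_equal(w$sum_negative_ranks, 166)
  expect_equal(w$sum_positive_ranks, 44)
  expect_error(pairs_from_rank_structure(c(1, 3), c(4)), "partition")
})
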