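test_that("unique sequence scores 1 and a clean duplication scores 0.5", {
  g <- random_seq(3000, 55)
  tr <- alignability_track(c(chr1 = g), 50L)
  expect_true(all(tr$scores$chr1 == 1))
  block <- random_seq(600, 56)
  g2 <- paste0(random_seq(400, 57), block, random_seq(400, 58), block,
               random_seq(400, 59))
  tr2 <- alignability_track(c(chr1 = g2), 50L)
  # interior positions of both copies are duplicated k-mers
  expect_true(all(tr2$scores$chr1[401:900] == 0.5))
  expect_true(all(tr2$scores$chr1[1401:1900] == 0.5))
  expect_true(all(tr2$scores$chr1[100:300] == 1))
})

test_that("occurrence counts equal a naive substring scan", {
  g <- random_seq(5000, 60)
  k <- 25L
  tr <- alignability_track(c(chr1 = g), k)
  withr::with_seed(3, picks <- sample(5000 - k, 40L))
  for (p in picks) {
    km <- substr(g, p, p + k - 1L)
    expect_equal(1 / tr$scores$chr1[p], naive_occ(g, km))
  }
})

test_that("long-window (k > 31) occurrence counting agrees with the packed path", {
  block <- random_seq(500, 61)
  g <- paste0(random_seq(300, 62), block, random_seq(300, 63), block,
              random_seq(300, 64))
  t31 <- alignability_track(c(chr1 = g), 31L)
  t40 <- alignability_track(c(chr1 = g), 40L)
  # interior duplicated windows are 0.5 under both window lengths
  expect_true(all(t40$scores$chr1[301:760] == 0.5))
  expect_true(all(t31$scores$chr1[301:769] == 0.5))
  expect_true(all(t40$scores$chr1[1:250] == 1))
})

test_that("welch comparison matches a direct t-distribution computation", {
  withr::with_seed(11, {
    a <- rnorm(100, 0, 1)
    b <- rnorm(100, 1, 1)
  })
  # oracle: hand-computed Welch statistic and one-sided p via pt()
  sa <- var(a) / 100; sb <- var(b) / 100
  t_hand <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df_hand <- (sa + sb)^2 / (sa^2 / 99 + sb^2 / 99)
  p_hand <- pt(t_hand, df_hand)
  fake_track <- structure(list(scores = list(chr1 = c(a, b)), k = 1L),
                          class = "alignability_track")
  res <- compare_alignability(
    data.frame(contig = "chr1", pos = 1:100),
    data.frame(contig = "chr1", pos = 101:200), fake_track)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
  expect_lt(res$p, 1e-8)
  # identical samples: one-sided p near 0.5
  res0 <- compare_alignability(
    data.frame(contig = "chr1", pos = 1:100),
    data.frame(contig = "chr1", pos = 1:100), fake_track)
  expect_equal(res0$p, 0.5, tolerance = 1e-6)
})

test_that("degenerate zero-variance comparisons are signalled", {
  fake <- structure(list(scores = list(chr1 = rep(0.5, 50)), k = 1L),
                    class = "alignability_track")
  expect_error(compare_alignability(
    data.frame(contig = "chr1", pos = 1:10),
    data.frame(contig = "chr1", pos = 11:20), fake), "degenerate")
})

test_that("random site sampling is uniform, deterministic and respects masks", {
  sc <- mini_scenario(5L)
  tg <- sc$reference$targets
  n_avail <- sum(tg$end - tg$start + 1L)
  all_sites <- sample_random_sites(sc$reference, n_avail, seed = 1L)
  expect_equal(nrow(all_sites), n_avail)
  expect_equal(anyDuplicated(all_sites$pos), 0L)
  s1 <- sample_random_sites(sc$reference, 500L, seed = 7L)
  s2 <- sample_random_sites(sc$reference, 500L, seed = 7L)
  expect_identical(s1, s2)
  mask <- s1[1:100, ]
  s3 <- sample_random_sites(sc$reference, 200L, seed = 8L, exclude = mask)
  expect_equal(length(intersect(paste(s3$contig, s3$pos),
                                paste(mask$contig, mask$pos))), 0L)
  expect_error(sample_random_sites(sc$reference, n_avail + 1L), "exceeds")
  # uniformity: chi-square over 10 equal bins of the first target
  draws <- sample_random_sites(sc$reference, 10000L, seed = 3L)
  w <- draws$pos[draws$pos >= tg$start[1] & draws$pos <= tg$end[1]]
  bins <- cut(w, breaks = seq(tg$start[1] - 1L, tg$end[1],
                              length.out = 11L))
  counts <- as.numeric(table(bins))
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_gt(pchisq(chi, df = 9, lower.tail = FALSE), 0.001)
})

test_that("alignability drops at ledger difference-site neighbourhoods and recovers with k", {
  sc <- mini_scenario(6L)
  d <- sc$ledger$diffs
  cp <- sc$ledger$copies
  tr_small <- alignability_track(sc$reference, 30L)
  # windows fully inside a copy that cross no difference site are shared
  offs <- sort(d$offset)
  gaps <- data.frame(lo = offs[-length(offs)], hi = offs[-1])
  gaps <- gaps[gaps$hi - gaps$lo > 40, ][1:5, ]
  for (i in seq_len(nrow(gaps))) {
    p <- cp$start[1] + gaps$lo[i] + 3L
    expect_equal(tr_small$scores$chr1[p], 0.5)
  }
  # a window crossing a difference site is unique at either copy
  p_at <- cp$start[1] + offs[5] - 15L
  expect_equal(tr_small$scores$chr1[p_at], 1)
})

test_that("bedgraph-style export round-trips the run-length structure", {
  block <- random_seq(200, 65)
  g <- paste0(random_seq(150, 66), block, random_seq(150, 67), block,
              random_seq(150, 68))
  tr <- alignability_track(c(chr1 = g), 40L)
  p <- tempfile(fileext = ".tsv")
  write_track(tr, p)
  bed <- read.table(p, header = TRUE)
  expect_true(all(bed$end0 > bed$start0))
  expect_equal(sum(bed$end0 - bed$start0), length(tr$scores$chr1))
  scores <- rep(bed$score, bed$end0 - bed$start0)
  expect_equal(scores, tr$scores$chr1)
})
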