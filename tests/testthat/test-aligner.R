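test_that("k-mer index lookups agree with a naive scan", {
  g <- random_seq(5000, 31)
  idx <- build_index(c(chr1 = g), 12L)
  withr::with_seed(5, {
    for (i in 1:25) {
      p <- sample.int(4989, 1)
      km <- substr(g, p, p + 11L)
      hits <- index_lookup(idx, km)
      naive <- which(vapply(seq_len(4989), function(q)
        substr(g, q, q + 11L) == km, TRUE))
      expect_equal(sort(hits$pos), naive)
    }
  })
})

test_that("a tandem duplication doubles interior k-mer hit counts", {
  block <- random_seq(1000, 8)
  g <- paste0(random_seq(500, 9), block, block, random_seq(500, 10))
  idx <- build_index(c(chr1 = g), 15L)
  km <- substr(block, 400, 414)
  expect_equal(nrow(index_lookup(idx, km)), 2L)
  km_flank <- substr(g, 100, 114)
  expect_equal(nrow(index_lookup(idx, km_flank)), 1L)
})

test_that("an error-free read from a unique region maps to its origin at MAPQ 60", {
  g <- random_seq(8000, 42)
  idx <- build_index(c(chr1 = g), 20L)
  read <- substr(g, 3001, 3120)
  m <- map_read(read, idx)
  expect_true(m$mapped)
  expect_equal(m$pos, 3001L)
  expect_equal(m$mm, 0L)
  expect_equal(m$tie_count, 1L)
  expect_equal(m$mapq, 60L)
  expect_equal(m$strand, "+")
  # its reverse complement maps to the same place on the minus strand
  mr <- map_read(revcomp(read), idx)
  expect_equal(mr$pos, 3001L)
  expect_equal(mr$strand, "-")
})

test_that("best-score placements match the exhaustive Hamming oracle", {
  g <- paste0(random_seq(4000, 1), substr(random_seq(4000, 1), 1001, 3000),
              random_seq(2000, 2))  # 10 kb with an internal 2 kb duplication
  ref <- toy_ref(c(chr1 = g))
  idx <- build_index(ref, 15L)
  withr::with_seed(99, {
    reads <- vapply(1:500, function(i) {
      if (i %% 5 == 0) random_seq(60, 10000 + i)  # mostly unmappable
      else {
        p <- sample.int(nchar(g) - 60L, 1)
        r <- substr(g, p, p + 59L)
        if (i %% 3 == 0) r <- revcomp(r)
        # sprinkle up to 2 errors
        nerr <- sample(0:2, 1)
        if (nerr > 0) {
          s <- strsplit(r, "")[[1]]
          at <- sample.int(60, nerr)
          for (a in at) s[a] <- sample(setdiff(c("A","C","G","T"), s[a]), 1)
          r <- paste(s, collapse = "")
        }
        r
      }
    }, "")
  })
  max_mm <- 4L
  m <- rfpsim:::cpp_map_single(idx$ptr, idx$genome, reads, idx$contig_start0,
                      idx$contig_end0, max_mm, 1, 0)
  for (i in seq_along(reads)) {
    oracle <- brute_best(g, reads[i], max_mm)
    if (nrow(oracle) == 0L) {
      expect_false(m$mapped[i])
    } else {
      expect_true(m$mapped[i])
      expect_equal(m$mm[i], oracle$mm[1])
      expect_equal(m$tie_count[i], nrow(oracle))
      strand <- ifelse(m$strand[i] == 1L, "-", "+")
      expect_true(any(oracle$pos0 == m$pos0[i] & oracle$strand == strand))
    }
  }
})

test_that("tie-breaking across paralog copies is uniform (chi-square)", {
  sc <- mini_scenario(1L)
  cp <- sc$ledger$copies
  diffs <- sc$ledger$diffs
  # find a 120 bp window inside copy 1 that overlaps no difference site
  offs <- sort(diffs$offset)
  gap <- which(diff(offs) > 140)[1]
  start_off <- offs[gap] + 5L
  read <- substr(sc$reference$contigs[["chr1"]],
                 cp$start[1] + start_off, cp$start[1] + start_off + 119L)
  idx <- build_index(sc$reference, 20L)
  n <- 2000L
  m <- rfpsim:::cpp_map_single(idx$ptr, idx$genome, rep(read, n), idx$contig_start0,
                      idx$contig_end0, 8L, 123, 0)
  expect_true(all(m$tie_count == 2L))
  expect_true(all(m$mapq == 0L))
  counts <- table(m$pos0)
  expect_length(counts, 2L)
  chi <- sum((as.numeric(counts) - n / 2)^2 / (n / 2))
  expect_gt(pchisq(chi, df = 1, lower.tail = FALSE), 0.001)
})

test_that("jointly tied pairs move between copies as a unit", {
  # constructed duplication: two identical 800 bp copies except one
  # difference site at copy offset 30, far from the sampled fragment
  copy1 <- random_seq(800, 71)
  copy2 <- copy1
  substr(copy2, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                   substr(copy1, 30, 30))[1]
  g <- paste0(random_seq(600, 72), copy1, random_seq(700, 73), copy2,
              random_seq(600, 74))
  ref <- toy_ref(c(chr1 = g))
  frag <- substr(copy1, 200, 699)  # inside both copies, no difference site
  s1 <- substr(frag, 1, 120)
  s2 <- revcomp(substr(frag, 381, 500))
  idx <- build_index(ref, 20L)
  res <- lapply(1:50, function(i) map_pair(s1, s2, idx, seed = i))
  for (r in res) {
    expect_true(all(r$mapq == 0L))
    expect_true(all(r$proper))
    # both mates on the same copy: offset difference preserved
    expect_equal(r$pos[2] - r$pos[1], 380L)
  }
  placed <- vapply(res, function(r) r$pos[1], 0L)
  expect_length(unique(placed), 2L)  # both copies actually used
})

test_that("mates that cannot pair properly are flagged and MAPQ-0", {
  g1 <- random_seq(3000, 61); g2 <- random_seq(3000, 62)
  ref <- toy_ref(c(c1 = g1, c2 = g2))
  idx <- build_index(ref, 20L)
  r <- map_pair(substr(g1, 1001, 1120), revcomp(substr(g2, 2001, 2120)), idx)
  expect_true(all(!r$proper))
  expect_true(all(r$mapq == 0L))
  expect_equal(r$contig, c("c1", "c2"))
})

test_that("alignment output is deterministic per seed", {
  sc <- mini_scenario(2L)
  rd <- sample_reads(sc$individual, sampler_config(n_pairs = 300L), seed = 3L)
  idx <- build_index(sc$reference, 20L)
  a <- align_reads(rd, idx, sc$aligner_cfg, seed = 3L, round = 1L)
  b <- align_reads(rd, idx, sc$aligner_cfg, seed = 3L, round = 1L)
  expect_identical(a$alignments, b$alignments)
  p1 <- tempfile(); p2 <- tempfile()
  write_sam(a, sc$reference, p1); write_sam(b, sc$reference, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("misassignment of error-free reads requires difference-site coverage", {
  sc <- mini_scenario(1L)
  cp <- sc$ledger$copies
  diffs <- sc$ledger$diffs
  idx <- build_index(sc$reference, 20L)
  g <- sc$reference$contigs[["chr1"]]
  # reads overlapping at least one difference site never switch copies
  d <- diffs$offset[10]
  read <- substr(g, cp$start[1] + d - 60L, cp$start[1] + d + 59L)
  m <- rfpsim:::cpp_map_single(idx$ptr, idx$genome, rep(read, 200L), idx$contig_start0,
                      idx$contig_end0, 8L, 77, 0)
  expect_true(all(m$tie_count == 1L))
  expect_true(all(m$pos0 == cp$start[1] + d - 61L))
})
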