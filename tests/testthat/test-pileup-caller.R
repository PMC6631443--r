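make_aln_set <- function(df, read_length = 120L) {
  structure(list(alignments = df, read_length = read_length,
                 max_mismatch = 8L, paired = TRUE, base_quality = 25L),
            class = "alignment_set")
}

test_that("duplicate pairs collapse to one before piling (rmdup)", {
  g <- random_seq(1000, 17)
  ref <- toy_ref(c(chr1 = g))
  one_pair <- function(id) {
    data.frame(id = id, mate = 1:2, contig = "chr1", pos = c(101L, 381L),
               strand = c("+", "-"), mm = 0L, mapq = 60L, tie_count = 1L,
               mapped = TRUE, proper = TRUE,
               seq = c(substr(g, 101, 220), revcomp(substr(g, 381, 500))),
               pos0 = c(100L, 380L), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, lapply(sprintf("rd%02d", 1:10), one_pair))
  pu <- build_pileup(make_aln_set(df), ref)
  expect_true(all(pu$sites$depth == 1L))
  pu2 <- build_pileup(make_aln_set(df), ref, rmdup = FALSE)
  expect_true(all(pu2$sites$depth == 10L))
  # shifting one pair breaks the duplicate signature
  df$pos[3] <- 102L; df$pos0[3] <- 101L
  df$seq[3] <- substr(g, 102, 221)
  pu3 <- build_pileup(make_aln_set(df), ref)
  expect_equal(max(pu3$sites$depth), 2L)
})

test_that("pileup allele counts equal a brute-force recount from the records", {
  sc <- mini_scenario(3L, n_snvs = 10L)
  rd <- sample_reads(sc$individual, sampler_config(n_pairs = 150L), seed = 6L)
  idx <- build_index(sc$reference, 20L)
  aln <- align_reads(rd, idx, sc$aligner_cfg)
  pu <- build_pileup(aln, sc$reference, rmdup = FALSE)
  a <- aln$alignments[aln$alignments$mapped, ]
  # recount at 30 random covered sites
  withr::with_seed(8, picks <- sample(nrow(pu$sites), 30L))
  for (i in picks) {
    s <- pu$sites[i, ]
    cover <- a[a$pos <= s$pos & a$pos + 119L >= s$pos, ]
    bases <- vapply(seq_len(nrow(cover)), function(j) {
      sq <- if (cover$strand[j] == "-") revcomp(cover$seq[j]) else cover$seq[j]
      substr(sq, s$pos - cover$pos[j] + 1L, s$pos - cover$pos[j] + 1L)
    }, "")
    expect_equal(s$depth, length(bases))
    expect_equal(unname(s$A + 0L), sum(bases == "A"))
    expect_equal(unname(s$G + 0L), sum(bases == "G"))
  }
})

test_that("sites with no coverage are absent and deep alignments are bounded", {
  g <- random_seq(500, 19)
  ref <- toy_ref(c(chr1 = g))
  df <- data.frame(id = "r1", mate = 1L, contig = "chr1", pos = 1L,
                   strand = "+", mm = 0L, mapq = 60L, tie_count = 1L,
                   mapped = TRUE, proper = FALSE, seq = substr(g, 1, 120),
                   pos0 = 0L, stringsAsFactors = FALSE)
  pu <- build_pileup(make_aln_set(df), ref)
  expect_equal(nrow(pu$sites), 120L)
  df$pos <- 450L; df$pos0 <- 449L
  expect_error(build_pileup(make_aln_set(df), ref), "beyond")
})

test_that("threshold caller gates depth, count and fraction as specified", {
  expect_equal(nrow(call_a_threshold(toy_pileup(30L, 15L))), 1L)
  expect_equal(nrow(call_a_threshold(toy_pileup(30L, 2L))), 0L)
  expect_equal(nrow(call_a_threshold(toy_pileup(4L, 4L))), 0L)   # depth gate
  expect_equal(nrow(call_a_threshold(toy_pileup(30L, 5L))), 0L)  # fraction gate
  got <- call_a_threshold(toy_pileup(25L, 6L))
  expect_equal(got$qual, 6)
  expect_equal(got$alt, "G")
})

test_that("likelihood caller matches direct binomial computation", {
  # oracle: explicit genotype likelihood ratio
  lr <- function(n, k, e = 0.01) {
    max(dbinom(k, n, 0.5), dbinom(k, n, 1 - e)) / dbinom(k, n, e)
  }
  expect_gt(lr(30, 15), 10)   # clearly heterozygous-like
  expect_lt(lr(30, 1), 10)    # noise-compatible
  expect_equal(nrow(call_b_likelihood(toy_pileup(30L, 15L))), 1L)
  expect_equal(nrow(call_b_likelihood(toy_pileup(30L, 0L))), 0L)
  expect_equal(nrow(call_b_likelihood(toy_pileup(30L, 1L))), 0L)
  got <- call_b_likelihood(toy_pileup(30L, 15L))
  expect_equal(got$qual, round(10 * log10(lr(30, 15))))
  # threshold site: smallest k called matches the oracle for several depths
  for (n in c(10L, 20L, 30L, 50L)) {
    kstar_oracle <- min(which(vapply(1:n, function(k) lr(n, k) >= 10, TRUE)))
    called <- vapply(1:n, function(k)
      nrow(call_b_likelihood(toy_pileup(n, k))) == 1L, TRUE)
    expect_equal(min(which(called)), kstar_oracle)
  }
})

test_that("both callers recover planted homozygous variants in unique sequence", {
  spec <- genome_spec(genome_length = 100000L, n_paralog_families = 0L,
                      n_unique_targets = 6L, unique_target_length = 5000L,
                      rng_seed = 31L)
  fr <- build_reference(spec)
  ind <- derive_individual(fr$reference, fr$ledger, 200L, seed = 4L)
  rd <- sample_reads(ind, sampler_config(coverage = 30), seed = 10L)
  idx <- build_index(fr$reference, 20L)
  aln <- align_reads(rd, idx, align_config())
  pu <- build_pileup(aln, fr$reference)
  truth <- variant_key(ind$variants$contig, ind$variants$pos,
                       ind$variants$ref, ind$variants$alt)
  for (calls in list(call_a_threshold(pu), call_b_likelihood(pu))) {
    keys <- variant_key(calls$contig, calls$pos, calls$ref, calls$alt)
    expect_gte(mean(truth %in% keys), 0.99)
  }
})

test_that("the two callers agree on clear sites", {
  sc <- cached("mini_round", {
    sc <- mini_scenario(3L, n_snvs = 30L)
    rd <- sample_reads(sc$individual, sc$sampler_cfg, seed = 2L)
    idx <- build_index(sc$reference, 20L)
    aln <- align_reads(rd, idx, sc$aligner_cfg)
    sc$pileup <- build_pileup(aln, sc$reference)
    sc
  })
  pu <- sc$pileup
  a <- call_a_threshold(pu); b <- call_b_likelihood(pu)
  ka <- variant_key(a$contig, a$pos, a$ref, a$alt)
  kb <- variant_key(b$contig, b$pos, b$ref, b$alt)
  # clear sites: alt fraction >= 0.4 at depth >= 20 (caller A qual = alt count)
  depth_at <- pu$sites$depth[match(paste(a$contig, a$pos),
                                   paste(pu$sites$contig, pu$sites$pos))]
  sel <- depth_at >= 20 & a$qual / depth_at >= 0.4
  expect_gt(sum(sel), 20)
  expect_gte(mean(ka[sel] %in% kb), 0.99)
})
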