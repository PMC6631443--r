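test_that("a genome without duplications has an empty ledger and ACGT alphabet", {
  spec <- genome_spec(genome_length = 50000L, n_paralog_families = 0L,
                      n_unique_targets = 4L, unique_target_length = 2000L,
                      rng_seed = 3L)
  fr <- build_reference(spec)
  expect_equal(nrow(fr$ledger$diffs), 0L)
  expect_equal(nrow(fr$ledger$copies), 0L)
  expect_false(grepl("[^ACGT]", fr$reference$contigs[["chr1"]]))
  expect_equal(nchar(fr$reference$contigs[["chr1"]]), 50000L)
  expect_true(all(fr$reference$targets$end <= 50000L))
})

test_that("ledger difference sites equal a base-by-base diff of the emitted copies", {
  spec <- genome_spec(genome_length = 60000L, n_paralog_families = 1L,
                      copies_per_family = 2L, copy_length = 10000L,
                      paralog_identity = 0.99, n_unique_targets = 0L,
                      rng_seed = 11L)
  fr <- build_reference(spec)
  cp <- fr$ledger$copies
  g <- fr$reference$contigs[["chr1"]]
  s1 <- substr(g, cp$start[1], cp$end[1])
  s2 <- substr(g, cp$start[2], cp$end[2])
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  observed <- which(a != b)
  expect_equal(sort(fr$ledger$diffs$offset), observed)
  expect_equal(fr$ledger$diffs$base_i, a[fr$ledger$diffs$offset])
  expect_equal(fr$ledger$diffs$base_j, b[fr$ledger$diffs$offset])
  # realized identity within the binomial range around 0.99
  rid <- fr$ledger$identity$identity[1]
  expect_equal(rid, 1 - length(observed) / 10000)
  expect_gt(rid, 0.985)
  expect_lt(rid, 0.995)
})

test_that("divergence near the observed paralog regime (identity 0.98) is realised", {
  spec <- genome_spec(genome_length = 60000L, n_paralog_families = 1L,
                      copies_per_family = 2L, copy_length = 10000L,
                      paralog_identity = 0.981, n_unique_targets = 0L,
                      rng_seed = 5L)
  fr <- build_reference(spec)
  expect_equal(fr$ledger$identity$identity[1], 0.98, tolerance = 0.005)
})

test_that("specs that cannot fit or degenerate identities are rejected", {
  expect_error(genome_spec(genome_length = 10000L, n_paralog_families = 2L,
                           copy_length = 10000L), "fit")
  expect_error(genome_spec(paralog_identity = 1.0), "identity")
  expect_error(genome_spec(paralog_identity = 0.5), "identity")
  expect_error(genome_spec(copies_per_family = 1L), "copies_per_family")
})

test_that("identical spec and seed give byte-identical genomes", {
  spec <- genome_spec(genome_length = 50000L, n_paralog_families = 1L,
                      copy_length = 5000L, n_unique_targets = 2L,
                      unique_target_length = 2000L, rng_seed = 9L)
  f1 <- build_reference(spec); f2 <- build_reference(spec)
  expect_identical(f1$reference$contigs, f2$reference$contigs)
  expect_identical(f1$ledger$diffs, f2$ledger$diffs)
  p1 <- tempfile(fileext = ".fa"); p2 <- tempfile(fileext = ".fa")
  write_fasta(f1$reference, p1); write_fasta(f2$reference, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an individual with no variants equals its reference", {
  fr <- build_reference(genome_spec(genome_length = 30000L,
                                    n_paralog_families = 0L,
                                    n_unique_targets = 2L,
                                    unique_target_length = 2000L,
                                    rng_seed = 2L))
  ind <- derive_individual(fr$reference, fr$ledger, 0L, seed = 1L)
  expect_identical(ind$haplotypes[1], fr$reference$contigs[["chr1"]])
  expect_equal(nrow(ind$variants), 0L)
})

test_that("variant planting honours counts, paralog fraction and labels", {
  sc <- mini_scenario(4L, n_snvs = 0L)
  ind <- derive_individual(sc$reference, sc$ledger, 50L,
                           fraction_in_paralogs = 0.2, seed = 8L)
  expect_equal(nrow(ind$variants), 50L)
  expect_equal(sum(ind$variants$in_paralog), 10L)
  expect_true(all(ind$variants$ref != ind$variants$alt))
  # labels agree with the ledger intervals
  cp <- sc$ledger$copies
  inside <- vapply(ind$variants$pos, function(p)
    any(cp$start <= p & cp$end >= p & cp$target), TRUE)
  expect_equal(ind$variants$in_paralog, inside)
})

test_that("haplotype realisation round-trips the planted variants", {
  sc <- mini_scenario(6L, n_snvs = 30L)
  ind <- sc$individual
  g <- sc$reference$contigs[["chr1"]]
  v <- ind$variants
  expect_equal(substring(g, v$pos, v$pos), v$ref)
  for (t in 1:2) {
    h <- g
    for (i in seq_len(nrow(v))) substring(h, v$pos[i], v$pos[i]) <- v$alt[i]
    expect_identical(ind$haplotypes[t], h)  # all-hom individual
  }
  expect_false(anyDuplicated(v$pos) > 0)
})

test_that("independently seeded individuals draw near-independent positions", {
  sc <- mini_scenario(12L, n_snvs = 0L)
  inds <- lapply(1:6, function(s)
    derive_individual(sc$reference, sc$ledger, 40L, seed = 1000L + s))
  tg <- sc$reference$targets
  n_avail <- sum(tg$end - tg$start + 1L)
  overlaps <- vapply(2:6, function(i)
    length(intersect(inds[[1]]$variants$pos, inds[[i]]$variants$pos)), 0L)
  # expected overlap is hypergeometric: mean 40*40/n_avail
  expected <- 40 * 40 / n_avail
  expect_lt(mean(overlaps), expected + 3 * sqrt(expected))
})
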