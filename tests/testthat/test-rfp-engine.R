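test_that("identical master seeds reproduce the call matrix exactly", {
  sc <- mini_scenario(2L, n_snvs = 20L)
  cfg <- sampler_config(coverage = 15)
  m1 <- run_rounds(sc$individual, n_rounds = 3L, sampler_cfg = cfg,
                   aligner_cfg = sc$aligner_cfg, master_seed = 9L)
  m2 <- run_rounds(sc$individual, n_rounds = 3L, sampler_cfg = cfg,
                   aligner_cfg = sc$aligner_cfg, master_seed = 9L)
  expect_identical(m1$incidence, m2$incidence)
  m3 <- run_rounds(sc$individual, n_rounds = 3L, sampler_cfg = cfg,
                   aligner_cfg = sc$aligner_cfg, master_seed = 10L)
  expect_false(identical(m1$incidence, m3$incidence))
})

test_that("without errors or paralogs every round calls exactly the planted variants", {
  spec <- genome_spec(genome_length = 50000L, n_paralog_families = 0L,
                      n_unique_targets = 3L, unique_target_length = 4000L,
                      rng_seed = 13L)
  fr <- build_reference(spec)
  ind <- derive_individual(fr$reference, fr$ledger, 25L, seed = 2L)
  m <- run_rounds(ind, n_rounds = 4L,
                  sampler_cfg = sampler_config(coverage = 30, error_rate = 0),
                  master_seed = 3L)
  truth <- sort(variant_key(ind$variants$contig, ind$variants$pos,
                            ind$variants$ref, ind$variants$alt))
  expect_identical(m$keys, truth)
  expect_true(all(m$frequency == 1))
})

test_that("call frequencies classify on strict 5%/95% boundaries", {
  keys <- c("chr1:10:A>G", "chr1:20:C>T", "chr1:30:G>A", "chr1:40:T>C")
  rounds <- lapply(1:100, function(r) {
    k <- character(0)
    if (r <= 5) k <- c(k, keys[1])              # f = 0.05 -> sporadic
    if (r <= 50) k <- c(k, keys[2])             # f = 0.50 -> RFP
    if (r <= 95) k <- c(k, keys[3])             # f = 0.95 -> consistent
    c(k, keys[4])                               # f = 1.00 -> consistent
  })
  m <- build_call_matrix(rounds)
  catg <- classify_calls(m)
  expect_equal(catg$class[match(keys, catg$key)],
               c("sporadic", "RFP", "consistent", "consistent"))
  # just inside the open interval on both sides
  rounds2 <- lapply(1:100, function(r) {
    c(if (r <= 6) "chr1:1:A>C", if (r <= 94) "chr1:2:A>C")
  })
  catg2 <- classify_calls(build_call_matrix(rounds2))
  expect_equal(sort(unname(catg2$class)), c("RFP", "RFP"))
  expect_error(classify_calls(m, f_low = 0.5, f_high = 0.4), "thresholds")
})

test_that("a key called every round gives a flat accumulation curve", {
  rounds <- lapply(1:10, function(r) c("chr1:5:A>G",
                                       if (r %% 2 == 0) "chr1:9:C>T"))
  m <- build_call_matrix(rounds)
  curve <- accumulation(m)
  expect_true(all(diff(curve$cumulative) >= 0))
  expect_equal(curve$cumulative[10], 1L)  # only the intermittent key counts
  expect_equal(curve$increments, c(0L, 1L, rep(0L, 8L)))  # first seen round 2
  expect_equal(fraction_discovered(curve, 5L, 10L), 1)
})

test_that("independent per-key calling matches the closed-form accumulation", {
  V <- 500L; p <- 0.11; N <- 100L
  withr::with_seed(42, {
    inc <- matrix(runif(V * N) < p, nrow = V)
  })
  rounds <- lapply(seq_len(N), function(r)
    sprintf("chr1:%d:A>G", which(inc[, r])))
  m <- build_call_matrix(rounds)
  curve <- accumulation(m, f_low = 0, f_high = 1)
  for (n in c(5L, 10L, 50L, 100L)) {
    prob <- 1 - (1 - p)^n
    lo <- qbinom(0.005, V, prob); hi <- qbinom(0.995, V, prob)
    expect_gte(curve$cumulative[n], lo)
    expect_lte(curve$cumulative[n], hi)
  }
  # lambda is the increment mean by definition
  expect_equal(curve$lambda_hat, mean(curve$increments[-1]))
  # fraction discovered matches the closed-form ratio
  expected <- (1 - (1 - p)^10) / (1 - (1 - p)^100)
  expect_equal(fraction_discovered(curve, 10L, 100L), expected,
               tolerance = 0.05)
})

test_that("fraction_discovered signals an empty candidate universe", {
  rounds <- lapply(1:5, function(r) "chr1:5:A>G")  # consistent only
  curve <- accumulation(build_call_matrix(rounds))
  expect_equal(curve$cumulative, rep(0L, 5L))
  expect_error(fraction_discovered(curve, 2L, 5L), "undefined")
})

test_that("catalogue TSV round-trips with metadata sidecar", {
  rounds <- lapply(1:20, function(r) {
    c("chr1:100:A>G", if (r <= 10) "chr1:200:C>T", if (r == 1) "chr1:300:G>C")
  })
  m <- build_call_matrix(rounds, meta = list(caller_id = "A"))
  catg <- classify_calls(m)
  p <- tempfile(fileext = ".tsv")
  write_catalogue(catg, p)
  back <- read_catalogue(p)
  expect_equal(back$key, catg$key)
  expect_equal(back$class, catg$class)
  expect_equal(back$frequency, catg$frequency)
  expect_equal(attr(back, "meta")$caller_id, "A")
})

test_that("stage failures are reported with their round index", {
  sc <- mini_scenario(2L)
  bad_cfg <- sampler_config(n_pairs = 10L)
  bad_cfg$read_length <- 100000L  # longer than any interval
  expect_error(
    suppressWarnings(run_rounds(sc$individual, n_rounds = 2L,
                                sampler_cfg = bad_cfg, master_seed = 1L)),
    "round 1 failed")
})
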