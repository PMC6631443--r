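# Independent oracles and small fixtures, built in code.

# Exhaustive Hamming scan: every placement of `read` on both strands of a
# genome string. Returns all positions with their mismatch counts.
# Deliberately brute force and independent of the aligner's index/seeding.
brute_scan <- function(genome, read) {
  L <- nchar(read)
  G <- nchar(genome)
  gb <- charToRaw(genome)
  scan_one <- function(r, strand) {
    rb <- charToRaw(r)
    n <- G - L + 1L
    idx <- outer(seq_len(L), 0:(n - 1L), `+`)
    mm <- colSums(matrix(gb[idx], nrow = L) != rb)
    data.frame(pos0 = 0:(n - 1L), strand = strand, mm = mm)
  }
  rbind(scan_one(read, "+"), scan_one(rfpsim::revcomp(read), "-"))
}

brute_best <- function(genome, read, max_mm) {
  sc <- brute_scan(genome, read)
  best <- min(sc$mm)
  if (best > max_mm) return(sc[0, ])
  sc[sc$mm == best, ]
}

# Naive substring occurrence count (both strands) for mappability checks.
naive_occ <- function(genome, kmer) {
  cnt <- function(pat) {
    hits <- gregexpr(pat, genome, fixed = TRUE)[[1]]
    if (hits[1] == -1L) 0L else {
      # gregexpr misses overlapping matches; slide manually
      n <- 0L
      for (p in seq_len(nchar(genome) - nchar(pat) + 1L))
        if (substr(genome, p, p + nchar(pat) - 1L) == pat) n <- n + 1L
      n
    }
  }
  rc <- rfpsim::revcomp(kmer)
  cnt(kmer) + if (rc != kmer) cnt(rc) else 0L
}

random_seq <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# Wrap bare sequences into a ref_genome whose targets span each contig.
toy_ref <- function(seqs, pad = 0L) {
  structure(list(contigs = seqs,
                 targets = data.frame(contig = names(seqs), start = 1L,
                                      end = nchar(seqs), type = "unique",
                                      family = NA_integer_,
                                      copy = NA_integer_,
                                      stringsAsFactors = FALSE),
                 pad_length = as.integer(pad)),
            class = "ref_genome")
}

# Toy pileup for caller tests.
toy_pileup <- function(depth, alt, ref = "A", altb = "G", pos = 100L) {
  counts <- stats::setNames(c(0L, 0L, 0L, 0L), c("A", "C", "G", "T"))
  counts[ref] <- depth - alt
  counts[altb] <- alt
  structure(list(sites = data.frame(contig = "chr1", pos = pos, ref = ref,
                                    depth = depth, A = counts[["A"]],
                                    C = counts[["C"]], G = counts[["G"]],
                                    T = counts[["T"]], n_mapq0 = 0L,
                                    stringsAsFactors = FALSE),
                 min_mapq = 0L),
            class = "pileup")
}

# Small paralog scenario for fast integration tests: 60 kb genome, one
# 2-copy 6 kb family, strain-like individual.
mini_scenario <- function(seed = 1L, identity = 0.99, n_snvs = 40L) {
  spec <- genome_spec(genome_length = 60000L, n_paralog_families = 1L,
                      copies_per_family = 2L, copy_length = 6000L,
                      paralog_identity = identity, n_unique_targets = 2L,
                      unique_target_length = 3000L, rng_seed = seed)
  fr <- build_reference(spec)
  ind <- derive_individual(fr$reference, fr$ledger, n_private_snvs = n_snvs,
                           seed = derive_seed(seed, 101L))
  list(reference = fr$reference, ledger = fr$ledger, individual = ind,
       sampler_cfg = sampler_config(coverage = 30),
       aligner_cfg = align_config())
}

# Session-level cache so expensive runs are shared between test blocks.
.rfpsim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .rfpsim_cache))
    assign(key, force(expr), envir = .rfpsim_cache)
  get(key, envir = .rfpsim_cache)
}
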