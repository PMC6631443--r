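#' Configuration for the paired-end read sampler
#'
#' Emulates wgsim-style simulation: fragments drawn uniformly, with
#' replacement, from the exome-like sampling space (targets plus padding);
#' each base substituted independently at \code{error_rate} to a uniformly
#' chosen different base; no indels.  Insert lengths are
#' Normal(\code{insert_mean}, \code{insert_sd}) truncated to
#' \code{[2 * read_length, insert_max]}.
#'
#' @param read_length read length in bases (default 120).
#' @param error_rate per-base substitution probability (default 0.01).
#' @param n_pairs number of pairs; exactly one of \code{n_pairs} and
#'   \code{coverage} may be set.
#' @param coverage target mean depth over the sampling space; translated to
#'   \code{n_pairs = coverage * space / (2 * read_length)}.
#' @param insert_mean,insert_sd fragment length distribution (default 500/50).
#' @param insert_max upper truncation for fragment length.
#' @param base_quality constant Phred quality written to FASTQ (default 25).
#' @return an object of class \code{sampler_config}.
#' @export
sampler_config <- function(read_length = 120L, error_rate = 0.01,
                           n_pairs = NULL, coverage = NULL,
                           insert_mean = 500, insert_sd = 50,
                           insert_max = 2000L, base_quality = 25L) {
  if (!is.null(n_pairs) && !is.null(coverage))
    stop("set either n_pairs or coverage, not both")
  if (is.null(n_pairs) && is.null(coverage)) coverage <- 30
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (insert_mean < 2 * read_length)
    warning("insert_mean below twice the read length; mates will overlap")
  structure(list(read_length = as.integer(read_length),
                 error_rate = as.numeric(error_rate),
                 n_pairs = if (!is.null(n_pairs)) as.integer(n_pairs),
                 coverage = if (!is.null(coverage)) as.numeric(coverage),
                 insert_mean = as.numeric(insert_mean),
                 insert_sd = as.numeric(insert_sd),
                 insert_max = as.integer(insert_max),
                 base_quality = as.integer(base_quality)),
            class = "sampler_config")
}

#' Simulate paired-end reads from an individual genome
#'
#' Fragment start positions are uniform over the sampling space and drawn
#' with replacement ("redundant" sampling), so duplicate fragments can occur;
#' mate 2 is reverse-complemented, and which physical fragment end becomes
#' mate 1 is randomised.  For heterozygous individuals the source haplotype
#' is drawn per fragment.  Fully deterministic given \code{(seed, round)}.
#'
#' @param individual an \code{individual_genome}.
#' @param cfg a \code{\link{sampler_config}}.
#' @param seed master seed.
#' @param round round index (keys an independent random stream per round).
#' @return an object of class \code{read_set}: a \code{pairs} data.frame with
#'   ids, mate sequences and per-pair truth (global fragment start, length,
#'   source haplotype, error count), plus the configuration used.
#' @export
sample_reads <- function(individual, cfg = sampler_config(), seed = 1L,
                         round = 0L) {
  stopifnot(inherits(individual, "individual_genome"),
            inherits(cfg, "sampler_config"))
  ref <- individual$ref
  iv <- sampling_intervals(ref)
  iv_len <- iv$end - iv$start + 1L
  short <- iv_len < 2L * cfg$read_length
  if (any(short)) {
    warning(sum(short), " sampling interval(s) shorter than twice the read ",
            "length were skipped")
    iv <- iv[!short, , drop = FALSE]
    iv_len <- iv_len[!short]
  }
  if (nrow(iv) == 0L) stop("no sampling interval can accommodate the reads")
  start0 <- to_global0(ref, iv$contig, iv$start)
  space <- sum(iv_len)
  n_pairs <- cfg$n_pairs %||% as.integer(round(cfg$coverage * space /
                                                 (2 * cfg$read_length)))
  haps <- if (any(individual$variants$zygosity == "het"))
    individual$haplotypes else individual$haplotypes[1]
  res <- cpp_sample_pairs(haps, start0, iv_len, n_pairs,
                          cfg$read_length, cfg$insert_mean, cfg$insert_sd,
                          max(2L * cfg$read_length, cfg$read_length),
                          cfg$insert_max, cfg$error_rate,
                          as.double(seed), as.double(round))
  pairs <- data.frame(id = sprintf("rd%06d", seq_len(n_pairs)),
                      seq1 = res$seq1, seq2 = res$seq2,
                      frag_start0 = res$frag_start0,
                      frag_len = res$frag_len,
                      haplotype = res$haplotype,
                      flip = res$flip,
                      n_errors = res$n_errors,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, read_length = cfg$read_length,
                 base_quality = cfg$base_quality, config = cfg,
                 seed = seed, round = round),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", nrow(x$pairs), "pairs of", x$read_length, "bp\n")
  invisible(x)
}
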