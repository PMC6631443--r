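#' Standard study scenarios
#'
#' Two fixed scenario builders used throughout the package's validation: a
#' null genome without duplications and a paralog genome with three
#' near-identical families.  Both use a 200 kb contig with unique 5 kb
#' exon-like targets, 325 bp padding, exome-style sampling at 30x, 120 bp
#' paired reads and 1\% sequencing error.  The paralog scenario has eight
#' unique targets plus three 2-copy families of 10 kb at 99\% identity — the divergence regime where
#' inter-copy differences meet the error rate — with one family's second
#' copy demoted to a non-target pseudogene, and an individual carrying
#' private homozygous SNVs at about one per kilobase of target space,
#' placed proportionally (so roughly half fall inside paralog copies,
#' emulating strain variation in duplicated regions).
#'
#' @param seed integer seed controlling genome realisation and variant
#'   placement.
#' @param n_snvs number of private SNVs planted in the individual.
#' @return list with \code{reference}, \code{ledger}, \code{individual},
#'   and default \code{sampler_cfg} / \code{aligner_cfg}.
#' @export
paralog_scenario <- function(seed = 1L, n_snvs = 100L) {
  spec <- genome_spec(genome_length = 200000L, n_paralog_families = 3L,
                      copies_per_family = 2L, copy_length = 10000L,
                      paralog_identity = 0.99, pad_length = 325L,
                      gc_content = 0.42,
                      include_pseudogene = c(FALSE, FALSE, TRUE),
                      n_unique_targets = 8L, unique_target_length = 5000L,
                      rng_seed = seed)
  fr <- build_reference(spec)
  ind <- derive_individual(fr$reference, fr$ledger,
                           n_private_snvs = n_snvs,
                           fraction_in_paralogs = NULL,
                           zygosity_mode = "hom",
                           seed = derive_seed(seed, 101L))
  list(reference = fr$reference, ledger = fr$ledger, individual = ind,
       sampler_cfg = sampler_config(read_length = 120L, error_rate = 0.01,
                                    coverage = 30),
       aligner_cfg = align_config(k = 20L, paired = TRUE))
}

#' @rdname paralog_scenario
#' @export
sweep_scenario <- function(seed = 42L, n_snvs = 60L) {
  # compact paralog genome used for read-length sweeps and
  # individual-comparison studies, where many full runs are required:
  # 120 kb, two 2-copy 10 kb families at 99% identity, three unique targets
  spec <- genome_spec(genome_length = 120000L, n_paralog_families = 2L,
                      copies_per_family = 2L, copy_length = 10000L,
                      paralog_identity = 0.99, pad_length = 325L,
                      gc_content = 0.42, n_unique_targets = 3L,
                      unique_target_length = 4000L, rng_seed = seed)
  fr <- build_reference(spec)
  ind <- derive_individual(fr$reference, fr$ledger,
                           n_private_snvs = n_snvs,
                           zygosity_mode = "hom",
                           seed = derive_seed(seed, 101L))
  list(reference = fr$reference, ledger = fr$ledger, individual = ind,
       sampler_cfg = sampler_config(read_length = 120L, error_rate = 0.01,
                                    coverage = 30),
       aligner_cfg = align_config(k = 20L, paired = TRUE))
}

#' @rdname paralog_scenario
#' @export
null_scenario <- function(seed = 1L, n_snvs = 100L) {
  spec <- genome_spec(genome_length = 200000L, n_paralog_families = 0L,
                      copies_per_family = 2L, copy_length = 10000L,
                      paralog_identity = 0.99, pad_length = 325L,
                      gc_content = 0.42, n_unique_targets = 10L,
                      unique_target_length = 5000L, rng_seed = seed)
  fr <- build_reference(spec)
  ind <- derive_individual(fr$reference, fr$ledger,
                           n_private_snvs = n_snvs,
                           zygosity_mode = "hom",
                           seed = derive_seed(seed, 101L))
  list(reference = fr$reference, ledger = fr$ledger, individual = ind,
       sampler_cfg = sampler_config(read_length = 120L, error_rate = 0.01,
                                    coverage = 30),
       aligner_cfg = align_config(k = 20L, paired = TRUE))
}
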