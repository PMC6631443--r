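#' Aligner configuration
#'
#' The aligner is a seed-and-extend Hamming-distance mapper: three
#' non-overlapping k-mer seeds at fixed read offsets \{0, L/3, 2L/3\} gather
#' candidate placements on both strands, every candidate is scored by exact
#' mismatch count, and the minimal-mismatch placement wins.  When several
#' placements score equally the choice is uniform at random from the tie set
#' (one counter-based draw keyed on seed, round and read index) and MAPQ is
#' set to 0 — the random-assignment contract that produces recurrent
#' miscalls.  Otherwise MAPQ is \code{min(60, 10 * (second_best - best) + 20)}
#' (60 when no competing placement is found).
#'
#' @param k seed length in bases (default 20).
#' @param max_mismatch maximum mismatches for a valid placement;
#'   \code{NULL} chooses \code{ceiling(3 + 4 * error_rate * read_length)}
#'   at alignment time.
#' @param paired align mates jointly (default) or each independently.
#' @param insert_mean,insert_sd expected fragment-length distribution used
#'   for the proper-pair window \code{insert_mean +/- 4 * insert_sd}.
#' @return an object of class \code{align_config}.
#' @export
align_config <- function(k = 20L, max_mismatch = NULL, paired = TRUE,
                         insert_mean = 500, insert_sd = 50) {
  structure(list(k = as.integer(k),
                 max_mismatch = if (!is.null(max_mismatch)) as.integer(max_mismatch),
                 paired = isTRUE(paired),
                 insert_mean = as.numeric(insert_mean),
                 insert_sd = as.numeric(insert_sd)),
            class = "align_config")
}

default_max_mismatch <- function(error_rate, read_length) {
  as.integer(ceiling(3 + 4 * error_rate * read_length))
}

#' Build an exact k-mer index over a reference
#'
#' Every position of every contig contributes its k-mer; lookups return all
#' exact occurrences.  Both strands are represented by querying a read in
#' both orientations against the forward index.
#'
#' @param ref a \code{ref_genome} (or named character vector of contigs).
#' @param k k-mer length, 8..31.
#' @return an object of class \code{kmer_index}.
#' @export
build_index <- function(ref, k = 20L) {
  contigs <- if (inherits(ref, "ref_genome")) ref$contigs else ref
  if (k < 8L || k > 31L) stop("k must be in [8, 31]")
  if (k > min(nchar(contigs))) stop("k larger than the shortest contig")
  ref_obj <- if (inherits(ref, "ref_genome")) ref else
    structure(list(contigs = contigs,
                   targets = data.frame(contig = character(), start = integer(),
                                        end = integer()),
                   pad_length = 0L), class = "ref_genome")
  genome <- concat_genome(contigs)
  off <- contig_offsets(ref_obj)
  structure(list(ptr = cpp_build_index(genome, as.integer(k)),
                 genome = genome, k = as.integer(k), ref = ref_obj,
                 contig_start0 = off$start0, contig_end0 = off$end0,
                 contig = off$contig),
            class = "kmer_index")
}

#' Look up exact occurrences of a k-mer
#' @param index a \code{kmer_index}.
#' @param kmer string of length k.
#' @return data.frame(contig, pos) of 1-based occurrence starts (forward
#'   strand of the reference).
#' @export
index_lookup <- function(index, kmer) {
  p0 <- cpp_index_lookup(index$ptr, toupper(kmer))
  to_local1(index$ref, p0)
}

alignment_df <- function(index, m, seqs, ids, mate, proper = NA) {
  loc <- to_local1(index$ref, pmax(m$pos0, 0L))
  data.frame(id = ids, mate = mate,
             contig = ifelse(m$mapped, loc$contig, NA_character_),
             pos = ifelse(m$mapped, loc$pos, 0L),
             strand = ifelse(m$strand == 1L, "-", "+"),
             mm = m$mm, mapq = m$mapq, tie_count = m$tie_count,
             mapped = m$mapped, proper = proper,
             seq = seqs, pos0 = ifelse(m$mapped, m$pos0, -1L),
             stringsAsFactors = FALSE)
}

#' Align a set of read pairs
#'
#' In paired mode, mates are placed jointly: combinations on opposite strands
#' with the leftmost mate forward and an implied insert inside
#' \code{insert_mean +/- 4 * insert_sd} are proper pairs, scored by summed
#' mismatches; joint ties move the pair as a unit with one random draw and
#' MAPQ 0 for both mates.  If no proper combination exists, mates fall back
#' to independent placement with MAPQ forced to 0.
#'
#' @param reads a \code{read_set}.
#' @param index a \code{kmer_index} over the reference.
#' @param cfg an \code{\link{align_config}}.
#' @param seed,round random stream key (defaults to the read set's own).
#' @return an object of class \code{alignment_set}: a long data.frame with
#'   one row per mate (id, mate, contig, 1-based pos, strand, mismatch count,
#'   mapq, tie_count, mapped, proper, seq) plus metadata.
#' @export
align_reads <- function(reads, index, cfg = align_config(), seed = NULL,
                        round = NULL) {
  stopifnot(inherits(reads, "read_set"), inherits(index, "kmer_index"))
  seed <- seed %||% (reads$seed %||% 1L)
  round <- round %||% (reads$round %||% 0L)
  err <- if (!is.null(reads$config)) reads$config$error_rate else 0.01
  max_mm <- cfg$max_mismatch %||% default_max_mismatch(err, reads$read_length)
  p <- reads$pairs
  if (cfg$paired) {
    m <- cpp_map_pairs(index$ptr, index$genome, p$seq1, p$seq2,
                       index$contig_start0, index$contig_end0, max_mm,
                       cfg$insert_mean - 4 * cfg$insert_sd,
                       cfg$insert_mean + 4 * cfg$insert_sd,
                       as.double(seed), as.double(round))
    a1 <- alignment_df(index,
                       list(mapped = m$mapped1, pos0 = m$pos1_0,
                            strand = m$strand1, mm = m$mm1, mapq = m$mapq1,
                            tie_count = m$tie1),
                       p$seq1, p$id, 1L, m$proper)
    a2 <- alignment_df(index,
                       list(mapped = m$mapped2, pos0 = m$pos2_0,
                            strand = m$strand2, mm = m$mm2, mapq = m$mapq2,
                            tie_count = m$tie2),
                       p$seq2, p$id, 2L, m$proper)
    aln <- rbind(a1, a2)
  } else {
    m1 <- cpp_map_single(index$ptr, index$genome, p$seq1,
                         index$contig_start0, index$contig_end0, max_mm,
                         as.double(seed), as.double(round))
    m2 <- cpp_map_single(index$ptr, index$genome, p$seq2,
                         index$contig_start0, index$contig_end0, max_mm,
                         as.double(seed + 1), as.double(round))
    aln <- rbind(alignment_df(index, m1, p$seq1, p$id, 1L, FALSE),
                 alignment_df(index, m2, p$seq2, p$id, 2L, FALSE))
  }
  aln <- aln[order(aln$id, aln$mate), , drop = FALSE]
  rownames(aln) <- NULL
  structure(list(alignments = aln, read_length = reads$read_length,
                 max_mismatch = max_mm, paired = cfg$paired,
                 base_quality = reads$base_quality,
                 index_k = index$k, seed = seed, round = round),
            class = "alignment_set")
}

#' Map a single read
#'
#' Convenience wrapper over the batch mapper for one read; see
#' \code{\link{align_reads}} for the placement rules.
#'
#' @param read a single sequence string.
#' @param index a \code{kmer_index}.
#' @param max_mismatch maximum mismatches for a valid placement.
#' @param seed,round,read_id key of the tie-breaking random draw.
#' @return one-row data.frame (contig, pos, strand, mm, mapq, tie_count,
#'   mapped).
#' @export
map_read <- function(read, index, max_mismatch = 8L, seed = 1L, round = 0L,
                     read_id = 0L) {
  stopifnot(length(read) == 1L)
  if (grepl("[^ACGTN]", read)) stop("read must be over {A,C,G,T,N}")
  # the tie-breaking draw is keyed on (seed, round, batch position), so a
  # read id is emulated through the batch position
  n <- as.integer(read_id) + 1L
  m <- cpp_map_single(index$ptr, index$genome, rep(read, n),
                      index$contig_start0, index$contig_end0,
                      as.integer(max_mismatch), as.double(seed),
                      as.double(round))
  m <- lapply(m, function(v) v[n])
  alignment_df(index, m, read, "read", 1L)[1, , drop = FALSE]
}

#' Map one read pair jointly
#'
#' @param seq1,seq2 mate sequences.
#' @inheritParams map_read
#' @param insert_mean,insert_sd proper-pair window parameters.
#' @return two-row data.frame as in \code{\link{align_reads}}.
#' @export
map_pair <- function(seq1, seq2, index, max_mismatch = 8L,
                     insert_mean = 500, insert_sd = 50, seed = 1L,
                     round = 0L) {
  m <- cpp_map_pairs(index$ptr, index$genome, seq1, seq2,
                     index$contig_start0, index$contig_end0,
                     as.integer(max_mismatch),
                     insert_mean - 4 * insert_sd, insert_mean + 4 * insert_sd,
                     as.double(seed), as.double(round))
  rbind(alignment_df(index,
                     list(mapped = m$mapped1, pos0 = m$pos1_0,
                          strand = m$strand1, mm = m$mm1, mapq = m$mapq1,
                          tie_count = m$tie1), seq1, "pair", 1L, m$proper),
        alignment_df(index,
                     list(mapped = m$mapped2, pos0 = m$pos2_0,
                          strand = m$strand2, mm = m$mm2, mapq = m$mapq2,
                          tie_count = m$tie2), seq2, "pair", 2L, m$proper))
}

#' @export
print.alignment_set <- function(x, ...) {
  a <- x$alignments
  cat("alignment_set:", nrow(a), "records;",
      sum(a$mapped), "mapped;", sum(a$mapq == 0 & a$mapped),
      "with MAPQ 0\n")
  invisible(x)
}
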