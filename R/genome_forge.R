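#' Specification for a synthetic reference genome
#'
#' Describes a genome built from exon-like target regions, a subset of which
#' belong to paralogous families of near-identical copies.  Divergence between
#' copies is controlled by \code{paralog_identity}: difference sites are drawn
#' per copy at rate \code{1 - paralog_identity} (binomially), placed uniformly
#' along the copy, with the alternative base drawn uniformly from the three
#' non-reference bases.  When \code{include_pseudogene} is \code{TRUE} for a
#' family, its last copy is left out of the target annotation, emulating a
#' non-coding pseudogene that attracts reads but contributes none.
#'
#' @param genome_length total contig length in bases.
#' @param n_paralog_families number of duplicated families.
#' @param copies_per_family copies per family (>= 2).
#' @param copy_length length of each duplicated block in bases.
#' @param paralog_identity pairwise identity between copies, in (0.9, 1.0).
#' @param pad_length padding added around each target region when deriving
#'   the read-sampling space (default 325, exome-style).
#' @param gc_content background GC fraction.
#' @param include_pseudogene logical, recycled per family: demote the last
#'   copy of the family to a non-target pseudogene.
#' @param n_unique_targets,unique_target_length additional single-copy
#'   exon-like target regions.
#' @param rng_seed integer seed; identical specs and seeds produce
#'   byte-identical genomes.
#' @return an object of class \code{genome_spec}.
#' @export
genome_spec <- function(genome_length = 200000L,
                        n_paralog_families = 2L,
                        copies_per_family = 2L,
                        copy_length = 10000L,
                        paralog_identity = 0.99,
                        pad_length = 325L,
                        gc_content = 0.42,
                        include_pseudogene = FALSE,
                        n_unique_targets = 10L,
                        unique_target_length = 5000L,
                        rng_seed = 1L) {
  spec <- list(genome_length = as.integer(genome_length),
               n_paralog_families = as.integer(n_paralog_families),
               copies_per_family = as.integer(copies_per_family),
               copy_length = as.integer(copy_length),
               paralog_identity = as.numeric(paralog_identity),
               pad_length = as.integer(pad_length),
               gc_content = as.numeric(gc_content),
               include_pseudogene = rep_len(as.logical(include_pseudogene),
                                            max(1L, as.integer(n_paralog_families))),
               n_unique_targets = as.integer(n_unique_targets),
               unique_target_length = as.integer(unique_target_length),
               rng_seed = as.integer(rng_seed))
  class(spec) <- "genome_spec"
  validate_genome_spec(spec)
  spec
}

validate_genome_spec <- function(spec) {
  if (spec$n_paralog_families > 0L) {
    if (spec$copies_per_family < 2L) stop("copies_per_family must be >= 2")
    if (spec$paralog_identity >= 1 || spec$paralog_identity <= 0.9)
      stop("paralog_identity must lie strictly within (0.9, 1.0)")
  }
  if (spec$gc_content <= 0 || spec$gc_content >= 1) stop("gc_content must be in (0,1)")
  blocks <- block_lengths(spec)
  min_gap <- min_block_gap(spec)
  if (sum(blocks) + (length(blocks) + 1L) * min_gap > spec$genome_length)
    stop("target and paralog blocks do not fit into genome_length")
  invisible(spec)
}

block_lengths <- function(spec) {
  c(rep(spec$unique_target_length, spec$n_unique_targets),
    rep(spec$copy_length, spec$n_paralog_families * spec$copies_per_family))
}

min_block_gap <- function(spec) max(spec$pad_length + 75L, 400L)

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Build a synthetic reference genome and its paralog ledger
#'
#' Lays out unique target regions and paralog family copies along a single
#' contig with randomised spacing, realising each family from a common
#' template plus per-copy difference sites.  The returned ledger records every
#' inter-copy difference site (the oracle for the miscall mechanism): for each
#' ordered copy pair it lists the within-copy offset, the genomic position in
#' either copy and the two alleles, along with the realised identity
#' \code{1 - n_diff / copy_length} computed by direct comparison of the
#' emitted sequences.
#'
#' @param spec a \code{\link{genome_spec}}.
#' @return a list with elements \code{reference} (class \code{ref_genome}:
#'   named \code{contigs} sequences and a \code{targets} data.frame) and
#'   \code{ledger} (class \code{paralog_ledger}: \code{copies}, \code{diffs}
#'   and \code{identity} tables).
#' @export
build_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  validate_genome_spec(spec)
  local_seed_eval(spec$rng_seed, {
    blocks <- block_lengths(spec)
    n_blocks <- length(blocks)
    kinds <- c(rep("unique", spec$n_unique_targets),
               rep("paralog", spec$n_paralog_families * spec$copies_per_family))
    fam <- c(rep(NA_integer_, spec$n_unique_targets),
             rep(seq_len(spec$n_paralog_families), each = spec$copies_per_family))
    cpy <- c(rep(NA_integer_, spec$n_unique_targets),
             rep(seq_len(spec$copies_per_family), spec$n_paralog_families))
    ord <- if (n_blocks > 0L) sample.int(n_blocks) else integer(0)

    min_gap <- min_block_gap(spec)
    slack <- spec$genome_length - sum(blocks) - (n_blocks + 1L) * min_gap
    extra <- if (n_blocks >= 0L && slack > 0L) {
      as.integer(stats::rmultinom(1, slack, rep(1, n_blocks + 1L)))
    } else rep(0L, n_blocks + 1L)
    gaps <- min_gap + extra

    # family templates and realised copy sequences
    fam_seqs <- vector("list", spec$n_paralog_families)
    if (spec$n_paralog_families > 0L) {
      for (f in seq_len(spec$n_paralog_families)) {
        template <- random_dna(spec$copy_length, spec$gc_content)
        seqs <- character(spec$copies_per_family)
        seqs[1] <- template
        for (j in seq_len(spec$copies_per_family)[-1]) {
          s <- strsplit(template, "")[[1]]
          n_diff <- rbinom(1, spec$copy_length, 1 - spec$paralog_identity)
          if (n_diff > 0) {
            sites <- sample.int(spec$copy_length, n_diff)
            for (i in sites) {
              s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
            }
          }
          seqs[j] <- paste(s, collapse = "")
        }
        fam_seqs[[f]] <- seqs
      }
    }

    # assemble the contig
    pieces <- character(2L * n_blocks + 1L)
    starts <- integer(n_blocks)   # 1-based start of each block, layout order
    cursor <- 0L
    for (b in seq_len(n_blocks + 1L)) {
      pieces[2L * b - 1L] <- random_dna(gaps[b], spec$gc_content)
      cursor <- cursor + gaps[b]
      if (b <= n_blocks) {
        i <- ord[b]
        starts[i] <- cursor + 1L
        pieces[2L * b] <- if (kinds[i] == "unique")
          random_dna(blocks[i], spec$gc_content)
        else fam_seqs[[fam[i]]][cpy[i]]
        cursor <- cursor + blocks[i]
      }
    }
    contig <- paste(pieces, collapse = "")
    stopifnot(nchar(contig) == spec$genome_length)

    is_pseudo <- !is.na(fam) & spec$include_pseudogene[pmax(fam, 1L)] &
      cpy == spec$copies_per_family
    targets <- data.frame(contig = "chr1",
                          start = starts,
                          end = starts + blocks - 1L,
                          type = kinds,
                          family = fam, copy = cpy,
                          stringsAsFactors = FALSE)[!is_pseudo, , drop = FALSE]
    targets <- targets[order(targets$start), , drop = FALSE]
    rownames(targets) <- NULL

    ref <- structure(list(contigs = c(chr1 = contig),
                          targets = targets,
                          pad_length = spec$pad_length,
                          spec = spec),
                     class = "ref_genome")

    copies <- data.frame(family = fam, copy = cpy, contig = "chr1",
                         start = starts, end = starts + blocks - 1L,
                         target = !is_pseudo,
                         stringsAsFactors = FALSE)[!is.na(fam), , drop = FALSE]
    copies <- copies[order(copies$family, copies$copy), , drop = FALSE]
    rownames(copies) <- NULL

    ledger <- build_ledger(copies, fam_seqs, spec)
    list(reference = ref, ledger = ledger)
  })
}

# Pairwise difference tables computed by direct comparison of the emitted
# copy sequences, so the ledger is definitionally complete.
build_ledger <- function(copies, fam_seqs, spec) {
  diffs <- list(); idtab <- list()
  if (nrow(copies) > 0L) {
    for (f in unique(copies$family)) {
      cc <- copies[copies$family == f, , drop = FALSE]
      seqs <- fam_seqs[[f]]
      for (i in seq_len(nrow(cc) - 1L)) {
        for (j in seq(i + 1L, nrow(cc))) {
          a <- strsplit(seqs[cc$copy[i]], "")[[1]]
          b <- strsplit(seqs[cc$copy[j]], "")[[1]]
          off <- which(a != b)
          if (length(off)) {
            diffs[[length(diffs) + 1L]] <- data.frame(
              family = f, copy_i = cc$copy[i], copy_j = cc$copy[j],
              offset = off,
              pos_i = cc$start[i] + off - 1L,
              pos_j = cc$start[j] + off - 1L,
              base_i = a[off], base_j = b[off],
              stringsAsFactors = FALSE)
          }
          idtab[[length(idtab) + 1L]] <- data.frame(
            family = f, copy_i = cc$copy[i], copy_j = cc$copy[j],
            n_diff = length(off),
            identity = 1 - length(off) / spec$copy_length)
        }
      }
    }
  }
  empty_diffs <- data.frame(family = integer(), copy_i = integer(),
                            copy_j = integer(), offset = integer(),
                            pos_i = integer(), pos_j = integer(),
                            base_i = character(), base_j = character(),
                            stringsAsFactors = FALSE)
  structure(list(copies = copies,
                 diffs = if (length(diffs)) do.call(rbind, diffs) else empty_diffs,
                 identity = if (length(idtab)) do.call(rbind, idtab) else
                   data.frame(family = integer(), copy_i = integer(),
                              copy_j = integer(), n_diff = integer(),
                              identity = numeric())),
            class = "paralog_ledger")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp;", nrow(x$targets), "target regions\n")
  invisible(x)
}

#' @export
print.paralog_ledger <- function(x, ...) {
  cat("paralog_ledger:", nrow(x$copies), "copies,",
      nrow(x$diffs), "pairwise difference sites\n")
  invisible(x)
}

#' Read-sampling intervals for a reference
#'
#' Target regions expanded by the padding on both sides, clipped to contig
#' bounds and merged where they overlap.  This is the exome-style space from
#' which fragments are drawn and in which individual variants are planted.
#'
#' @param ref a \code{ref_genome}.
#' @param pad padding in bases (defaults to the reference's own pad length).
#' @return data.frame with columns contig, start, end (1-based, inclusive).
#' @export
sampling_intervals <- function(ref, pad = NULL) {
  pad <- pad %||% ref$pad_length
  tg <- ref$targets
  out <- lapply(split(tg, tg$contig), function(d) {
    clen <- nchar(ref$contigs[[d$contig[1]]])
    s <- pmax(1L, d$start - pad)
    e <- pmin(clen, d$end + pad)
    o <- order(s)
    s <- s[o]; e <- e[o]
    ms <- s[1]; me <- e[1]; rs <- integer(); re <- integer()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me + 1L) me <- max(me, e[i])
      else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
    }
    rs <- c(rs, ms); re <- c(re, me)
    data.frame(contig = d$contig[1], start = rs, end = re,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Derive an individual genome from a reference
#'
#' Plants single-nucleotide variants into the target regions of the
#' reference and realises the individual's haplotype sequences.  (Variants
#' are confined to targets rather than the padded sampling space: padding
#' exists to buffer read coverage at target edges, and depth ramps there.)  A chosen fraction of the variants is placed inside paralog
#' target copies, emulating strain or private variation within duplicated
#' regions — the variation whose echo at the sister copy drives recurrent
#' miscalls.  SNVs only, so individual coordinates coincide with reference
#' coordinates.
#'
#' @param ref a \code{ref_genome}.
#' @param ledger the matching \code{paralog_ledger} (used for placement
#'   labels; may be \code{NULL} when the genome has no paralogs).
#' @param n_private_snvs number of variants to plant.
#' @param fraction_in_paralogs fraction placed inside paralog target copies;
#'   \code{NULL} means proportional to the paralog share of the sampling
#'   space.
#' @param zygosity_mode "hom" (default; inbred-strain analogue), "het", or
#'   "mixed" (each variant het with probability 1/2).
#' @param seed integer seed.
#' @param base_variants optional data.frame(contig, pos, ref, alt, zygosity)
#'   of shared (e.g. strain background) variants applied before the private
#'   ones; private placement avoids their positions.
#' @return an object of class \code{individual_genome} with elements
#'   \code{ref}, \code{variants} and \code{haplotypes} (two strings;
#'   identical where all variants are homozygous).
#' @export
derive_individual <- function(ref, ledger = NULL, n_private_snvs = 0L,
                              fraction_in_paralogs = NULL,
                              zygosity_mode = c("hom", "het", "mixed"),
                              seed = 1L, base_variants = NULL) {
  stopifnot(inherits(ref, "ref_genome"))
  zygosity_mode <- match.arg(zygosity_mode)
  n_private_snvs <- as.integer(n_private_snvs)
  # plant inside target regions only: the padding exists to buffer coverage
  # at target edges, so targets see flat depth while pad depth ramps
  tg <- ref$targets
  space <- unlist(mapply(function(s, e) s:e, tg$start, tg$end,
                         SIMPLIFY = FALSE))
  para_pos <- integer(0)
  if (!is.null(ledger) && nrow(ledger$copies) > 0L) {
    cc <- ledger$copies[ledger$copies$target, , drop = FALSE]
    para_pos <- unlist(mapply(function(s, e) s:e, cc$start, cc$end,
                              SIMPLIFY = FALSE))
  }
  uniq_pos <- setdiff(space, para_pos)
  taken <- if (!is.null(base_variants)) as.integer(base_variants$pos) else integer(0)

  local_seed_eval(seed, {
    frac <- fraction_in_paralogs %||% (length(para_pos) / length(space))
    n_para <- round(n_private_snvs * frac)
    n_uniq <- n_private_snvs - n_para
    if (n_para > length(setdiff(para_pos, taken)) ||
        n_uniq > length(setdiff(uniq_pos, taken)))
      stop("n_private_snvs exceeds available positions")
    pos <- c(integer(0),
             if (n_para > 0) sample(setdiff(para_pos, taken), n_para),
             if (n_uniq > 0) sample(setdiff(uniq_pos, taken), n_uniq))
    contig <- rep("chr1", length(pos))
    refb <- substr_at(ref$contigs[["chr1"]], pos)
    alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  "", USE.NAMES = FALSE)
    zyg <- switch(zygosity_mode,
                  hom = rep("hom", length(pos)),
                  het = rep("het", length(pos)),
                  mixed = sample(c("hom", "het"), length(pos), replace = TRUE))
    priv <- data.frame(contig = contig, pos = pos, ref = refb, alt = alt,
                       zygosity = zyg, private = rep(TRUE, length(pos)),
                       stringsAsFactors = FALSE)
    if (!is.null(base_variants)) {
      bv <- base_variants
      bv$private <- FALSE
      priv <- rbind(bv[, names(priv)], priv)
    }
    priv <- priv[order(priv$pos), , drop = FALSE]
    if (anyDuplicated(priv$pos)) stop("variant position collision")
    rb <- substr_at(ref$contigs[["chr1"]], priv$pos)
    if (!all(rb == priv$ref)) stop("variant ref allele does not match reference")

    priv$in_paralog <- priv$pos %in% para_pos
    priv$family <- rep(NA_integer_, nrow(priv)); priv$copy <- rep(NA_integer_, nrow(priv))
    if (!is.null(ledger) && nrow(ledger$copies) > 0L) {
      for (i in seq_len(nrow(ledger$copies))) {
        sel <- priv$pos >= ledger$copies$start[i] & priv$pos <= ledger$copies$end[i]
        priv$family[sel] <- ledger$copies$family[i]
        priv$copy[sel] <- ledger$copies$copy[i]
      }
    }
    rownames(priv) <- NULL

    # realise haplotypes; het variants land on haplotype 1 or 2 at random
    h <- rep(ref$contigs[["chr1"]], 2)
    hap_of <- ifelse(priv$zygosity == "hom", 0L,
                     sample(1:2, nrow(priv), replace = TRUE))
    for (i in seq_len(nrow(priv))) {
      tgt <- if (hap_of[i] == 0L) 1:2 else hap_of[i]
      for (t in tgt) substring(h[t], priv$pos[i], priv$pos[i]) <- priv$alt[i]
    }
    structure(list(ref = ref, ledger = ledger, variants = priv,
                   haplotypes = h, seed = as.integer(seed)),
              class = "individual_genome")
  })
}

#' @export
print.individual_genome <- function(x, ...) {
  cat("individual_genome:", nrow(x$variants), "variants (",
      sum(x$variants$in_paralog), "in paralog copies )\n")
  invisible(x)
}

#' Write the ledger and variant truth to TSV
#'
#' @param ledger a \code{paralog_ledger}.
#' @param path output file.
#' @export
write_ledger <- function(ledger, path) {
  write.table(ledger$diffs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @param individual an \code{individual_genome}.
#' @export
write_variant_truth <- function(individual, path) {
  write.table(individual$variants, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
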