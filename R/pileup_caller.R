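#' Build a pileup from alignments
#'
#' Duplicate pairs — identical (contig, position, strand) for both mates —
#' are collapsed to a single pair before piling (rmdup semantics), then
#' per-position allele counts are accumulated.  The default
#' \code{min_mapq = 0} keeps reads whose placement was a random tie-break
#' (MAPQ 0) in the pileup; this inclusion is what lets the recurrent-miscall
#' mechanism manifest, and raising the threshold to 1 demonstrates its
#' suppression.
#'
#' @param aln an \code{alignment_set}.
#' @param ref the \code{ref_genome} aligned against.
#' @param min_mapq minimum MAPQ for a read to enter the pileup.
#' @param rmdup collapse duplicate pairs first (default TRUE).
#' @return an object of class \code{pileup}: data.frame with contig, pos
#'   (1-based), ref, depth, counts for A/C/G/T and the number of MAPQ-0 reads
#'   covering the site; sites with zero depth are absent.
#' @export
build_pileup <- function(aln, ref, min_mapq = 0L, rmdup = TRUE) {
  stopifnot(inherits(aln, "alignment_set"))
  a <- aln$alignments[aln$alignments$mapped, , drop = FALSE]
  if (nrow(a) && rmdup) {
    o <- match(paste(a$id, 3L - a$mate), paste(a$id, a$mate))
    sig <- paste(a$contig, a$pos, a$strand,
                 ifelse(is.na(o), "*", paste(a$contig[o], a$pos[o], a$strand[o])))
    keep_pair <- !duplicated(sig[a$mate == 1L])
    keep_ids <- a$id[a$mate == 1L][keep_pair]
    orphan <- !(a$id %in% a$id[a$mate == 1L])  # mate-1 unmapped
    a <- a[a$id %in% keep_ids | orphan, , drop = FALSE]
  }
  genome <- concat_genome(ref$contigs)
  if (nrow(a) && any(a$pos0 + nchar(a$seq) > nchar(genome)))
    stop("alignment beyond contig end")
  res <- cpp_pileup(genome, a$pos0, ifelse(a$strand == "-", 1L, 0L),
                    a$seq, a$mapq, as.integer(min_mapq))
  loc <- to_local1(ref, res$pos0)
  depth <- res$A + res$C + res$G + res$T
  pu <- data.frame(contig = loc$contig, pos = loc$pos,
                   ref = substring(genome, res$pos0 + 1L, res$pos0 + 1L),
                   depth = depth, A = res$A, C = res$C, G = res$G, T = res$T,
                   n_mapq0 = res$n_mapq0, stringsAsFactors = FALSE)
  structure(list(sites = pu, min_mapq = as.integer(min_mapq)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup:", nrow(x$sites), "covered sites; mean depth",
      round(mean(x$sites$depth), 1), "\n")
  invisible(x)
}

empty_calls <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), caller_id = character(),
             filter = character(), stringsAsFactors = FALSE)
}

# long table of non-reference allele counts per site
alt_long <- function(pu) {
  s <- pu$sites
  out <- lapply(c("A", "C", "G", "T"), function(b) {
    sel <- s$ref != b & s[[b]] > 0L
    if (!any(sel)) return(NULL)
    data.frame(contig = s$contig[sel], pos = s$pos[sel], ref = s$ref[sel],
               alt = b, alt_count = s[[b]][sel], depth = s$depth[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(contig = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      alt_count = integer(), depth = integer(),
                                      stringsAsFactors = FALSE)
  out[order(out$contig, out$pos, out$alt), , drop = FALSE]
}

#' Threshold-based SNV calling (rule A)
#'
#' Emits an alternate allele at a site when depth, alternate count and
#' alternate fraction all clear their thresholds; the call quality is the
#' alternate read count.  A deliberately simple frequency-style rule, used
#' as one of two independent callers.
#'
#' @param pileup a \code{pileup}.
#' @param min_depth,min_alt_count,min_alt_frac calling thresholds
#'   (defaults 5, 3, 0.2).
#' @return data.frame of calls (contig, pos, ref, alt, qual, caller_id,
#'   filter).
#' @export
call_a_threshold <- function(pileup, min_depth = 5L, min_alt_count = 3L,
                             min_alt_frac = 0.2) {
  al <- alt_long(pileup)
  sel <- al$depth >= min_depth & al$alt_count >= min_alt_count &
    al$alt_count / al$depth >= min_alt_frac
  al <- al[sel, , drop = FALSE]
  out <- data.frame(contig = al$contig, pos = al$pos, ref = al$ref,
                    alt = al$alt, qual = as.numeric(al$alt_count),
                    caller_id = rep("A", nrow(al)),
                    filter = rep("PASS", nrow(al)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genotype-likelihood SNV calling (rule B)
#'
#' For each candidate alternate allele with count k at a site of depth n,
#' computes binomial likelihoods of the three diploid genotypes — RR with
#' success probability \code{error}, RA with 1/2, AA with \code{1 - error} —
#' and calls the allele when the best non-reference genotype is at least
#' \code{min_posterior_ratio} times as likely as RR.  Quality is
#' \code{10 * log10} of that ratio, rounded.
#'
#' @param pileup a \code{pileup}.
#' @param error assumed per-base error rate (default 0.01).
#' @param min_posterior_ratio likelihood-ratio threshold (default 10).
#' @return data.frame of calls as in \code{\link{call_a_threshold}}.
#' @export
call_b_likelihood <- function(pileup, error = 0.01, min_posterior_ratio = 10) {
  al <- alt_long(pileup)
  if (nrow(al) == 0L) return(empty_calls())
  k <- al$alt_count; n <- al$depth
  ll_rr <- dbinom(k, n, error, log = TRUE)
  ll_ra <- dbinom(k, n, 0.5, log = TRUE)
  ll_aa <- dbinom(k, n, 1 - error, log = TRUE)
  log_ratio <- pmax(ll_ra, ll_aa) - ll_rr
  sel <- log_ratio >= log(min_posterior_ratio)
  out <- data.frame(contig = al$contig[sel], pos = al$pos[sel],
                    ref = al$ref[sel], alt = al$alt[sel],
                    qual = round(10 * log_ratio[sel] / log(10)),
                    caller_id = rep("B", sum(sel)),
                    filter = rep("PASS", sum(sel)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

call_variants <- function(pileup, caller = c("A", "B"), params = list()) {
  caller <- match.arg(caller)
  if (caller == "A")
    do.call(call_a_threshold, c(list(pileup), params))
  else
    do.call(call_b_likelihood, c(list(pileup), params))
}
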