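#' Per-position alignability track
#'
#' The alignability (mappability) of a position is
#' \code{1 / (number of exact genome-wide occurrences of the k-mer starting
#' there)}, counting both strands: a unique k-mer scores 1, a k-mer shared
#' by a two-copy duplication scores 0.5.  Positions lacking a full window
#' carry no score.  Occurrence counting is exact-match (no mismatch
#' tolerance); \code{k} conventionally matches the read length of the run
#' under analysis.
#'
#' @param ref a \code{ref_genome} or named character vector of contigs.
#' @param k window length in bases.
#' @return an \code{alignability_track}: per-contig numeric score vectors
#'   (position i holds the score of the window starting at i).
#' @export
alignability_track <- function(ref, k = 120L) {
  contigs <- if (inherits(ref, "ref_genome")) ref$contigs else ref
  if (k > min(nchar(contigs))) stop("k must not exceed the shortest contig")
  # occurrences are counted genome-wide, so count on the concatenation but
  # drop windows spanning contig joins
  genome <- concat_genome(contigs)
  occ <- cpp_kmer_occ(genome, as.integer(k))
  len <- nchar(contigs)
  start0 <- cumsum(c(0L, unname(len[-length(len)])))
  scores <- vector("list", length(contigs))
  names(scores) <- names(contigs)
  for (i in seq_along(contigs)) {
    n <- len[i] - k + 1L
    o <- occ[(start0[i] + 1L):(start0[i] + n)]
    scores[[i]] <- 1 / o
  }
  structure(list(scores = scores, k = as.integer(k)),
            class = "alignability_track")
}

#' @export
print.alignability_track <- function(x, ...) {
  v <- unlist(x$scores)
  cat("alignability_track: k =", x$k, "; mean score",
      round(mean(v, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Alignability at given sites
#'
#' @param track an \code{alignability_track}.
#' @param sites data.frame(contig, pos) of 1-based positions.
#' @param summarize "cover" (default) averages the scores of every window
#'   overlapping the site — the uniqueness of the reads that pile up on it,
#'   which is the quantity the miscall mechanism acts through; "start"
#'   returns the score of the single window starting at the site.
#' @return numeric vector of scores.
#' @export
alignability_at <- function(track, sites, summarize = c("cover", "start")) {
  summarize <- match.arg(summarize)
  k <- track$k
  vapply(seq_len(nrow(sites)), function(i) {
    v <- track$scores[[sites$contig[i]]]
    if (is.null(v)) stop("contig not in track: ", sites$contig[i])
    p <- sites$pos[i]
    if (summarize == "start") return(v[min(p, length(v))])
    w <- max(1L, p - k + 1L):min(p, length(v))
    mean(v[w])
  }, 0)
}

#' Compare alignability between two site sets
#'
#' Welch two-sample t-test of mean alignability, one-sided with alternative
#' "sites_a lower than sites_b" by default — the association test between
#' recurrent false positive sites and low-alignability regions.
#'
#' @param sites_a,sites_b data.frames (contig, pos) of 1-based sites.
#' @param track an \code{alignability_track} covering them.
#' @param alternative passed to \code{t.test} ("less" by default).
#' @return list(t, df, p, mean_a, mean_b).
#' @export
compare_alignability <- function(sites_a, sites_b, track,
                                 alternative = "less") {
  if (!nrow(sites_a) || !nrow(sites_b)) stop("both site sets must be non-empty")
  a <- alignability_at(track, sites_a)
  b <- alignability_at(track, sites_b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate comparison: zero variance in both samples")
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Sample random sites from a reference
#'
#' Uniform draws without replacement, either within the target regions
#' (matching how random coding sites are chosen for the alignability
#' comparison) or over whole contigs.
#'
#' @param ref a \code{ref_genome}.
#' @param n number of sites.
#' @param within_target_regions restrict to target regions (default TRUE).
#' @param seed integer seed (deterministic draw).
#' @param exclude optional data.frame(contig, pos) of positions to avoid.
#' @return data.frame(contig, pos), 1-based.
#' @export
sample_random_sites <- function(ref, n, within_target_regions = TRUE,
                                seed = 1L, exclude = NULL) {
  if (within_target_regions) {
    tg <- ref$targets
    pool <- data.frame(
      contig = rep(tg$contig, tg$end - tg$start + 1L),
      pos = unlist(mapply(function(s, e) s:e, tg$start, tg$end,
                          SIMPLIFY = FALSE)),
      stringsAsFactors = FALSE)
  } else {
    pool <- do.call(rbind, lapply(seq_along(ref$contigs), function(i)
      data.frame(contig = names(ref$contigs)[i],
                 pos = seq_len(nchar(ref$contigs[[i]])),
                 stringsAsFactors = FALSE)))
  }
  if (!is.null(exclude)) {
    pool <- pool[!(paste(pool$contig, pool$pos) %in%
                     paste(exclude$contig, exclude$pos)), , drop = FALSE]
  }
  if (n > nrow(pool)) stop("n exceeds available positions")
  local_seed_eval(seed, {
    idx <- if (n == nrow(pool)) seq_len(n) else sample.int(nrow(pool), n)
    out <- pool[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Export an alignability track as BedGraph-style TSV
#'
#' Columns contig, start0, end0 (0-based half-open), score; adjacent
#' positions with equal score are merged into one interval.
#'
#' @param track an \code{alignability_track}.
#' @param path output file.
#' @export
write_track <- function(track, path) {
  rows <- lapply(names(track$scores), function(ct) {
    v <- track$scores[[ct]]
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- c(0L, e[-length(e)])
    data.frame(contig = ct, start0 = s, end0 = e, score = r$values,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
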