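#' Write alignments to SAM
#'
#' Emits a valid header (@HD, one @SQ per contig) and the 11 mandatory
#' fields.  CIGAR is always \code{<len>M} (the aligner is ungapped), the NM
#' tag carries the mismatch count, and unmapped reads get flag bit 0x4 with
#' POS 0.  Mates are written as a read pair with the standard flag bits.
#'
#' @param aln an \code{alignment_set}.
#' @param ref the \code{ref_genome} aligned against.
#' @param path output file.
#' @param sort_by_coordinate order records by (contig, pos).
#' @export
write_sam <- function(aln, ref, path, sort_by_coordinate = FALSE) {
  stopifnot(inherits(aln, "alignment_set"))
  a <- aln$alignments
  hdr <- c(sprintf("@HD\tVN:1.6\tSO:%s",
                   if (sort_by_coordinate) "coordinate" else "queryname"),
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$contigs),
                   nchar(ref$contigs)),
           "@PG\tID:rfpsim\tPN:rfpsim")
  # pair bookkeeping: mate coordinates
  key <- paste(a$id, a$mate)
  other <- match(paste(a$id, 3L - a$mate), key)
  flag <- 1L +                                  # paired
    ifelse(a$mapped, 0L, 4L) +
    ifelse(!is.na(other) & !a$mapped[other], 8L, 0L) +
    ifelse(a$mapped & a$strand == "-", 16L, 0L) +
    ifelse(!is.na(other) & a$mapped[other] & a$strand[other] == "-", 32L, 0L) +
    ifelse(a$mate == 1L, 64L, 128L) +
    ifelse(!is.na(a$proper) & a$proper, 2L, 0L)
  rnext <- ifelse(is.na(other) | !a$mapped[other], "*",
                  ifelse(a$mapped & a$contig == a$contig[other], "=",
                         a$contig[other]))
  pnext <- ifelse(is.na(other) | !a$mapped[other], 0L, a$pos[other])
  tlen <- integer(nrow(a))
  both <- !is.na(other) & a$mapped & a$mapped[other] &
    !is.na(a$contig) & a$contig == a$contig[other]
  L <- nchar(a$seq)
  lo <- pmin(a$pos, a$pos[other])
  hi <- pmax(a$pos + L - 1L, a$pos[other] + L[other] - 1L)
  tlen[both] <- ifelse(a$pos[both] <= a$pos[other][both],
                       hi[both] - lo[both] + 1L,
                       -(hi[both] - lo[both] + 1L))
  seq_out <- ifelse(a$mapped & a$strand == "-", revcomp(a$seq), a$seq)
  qchar <- rawToChar(as.raw((aln$base_quality %||% 25L) + 33L))
  qual <- vapply(L, function(n) strrep(qchar, n), "")
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d",
                 a$id, flag,
                 ifelse(a$mapped, a$contig, "*"),
                 ifelse(a$mapped, a$pos, 0L),
                 a$mapq,
                 ifelse(a$mapped, sprintf("%dM", L), "*"),
                 rnext, pnext, tlen, seq_out, qual,
                 ifelse(a$mapped, a$mm, 0L))
  if (sort_by_coordinate) {
    o <- order(match(a$contig, names(ref$contigs)), a$pos)
    rec <- rec[o]
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file written by this package
#'
#' Parses header and mandatory fields back into an alignment table.  Only the
#' ungapped single-block CIGARs emitted by \code{\link{write_sam}} are
#' understood.
#'
#' @param path SAM file.
#' @return list with \code{alignments} data.frame and \code{contigs} header
#'   table.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "@")]
  body <- ln[!startsWith(ln, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contigs <- data.frame(
    contig = sub(".*\tSN:([^\t]+).*", "\\1", sq),
    length = as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    stringsAsFactors = FALSE)
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 1L) < 11L)
  if (length(bad))
    stop("SAM parse error at record ", bad[1], ": fewer than 11 fields")
  g <- function(i) vapply(f, `[`, "", i)
  flag <- as.integer(g(2))
  nm <- vapply(f, function(x) {
    t <- grep("^NM:i:", x, value = TRUE)
    if (length(t)) as.integer(sub("NM:i:", "", t[1])) else NA_integer_
  }, 1L)
  aln <- data.frame(id = g(1), flag = flag, contig = g(3),
                    pos = as.integer(g(4)), mapq = as.integer(g(5)),
                    cigar = g(6), seq = g(10),
                    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
                    mapped = bitwAnd(flag, 4L) == 0L,
                    proper = bitwAnd(flag, 2L) > 0L,
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    mm = nm, stringsAsFactors = FALSE)
  list(alignments = aln, contigs = contigs)
}

#' Write SNV calls to VCF 4.2
#'
#' @param calls a data.frame with contig, pos, ref, alt, qual and optionally
#'   filter and caller_id columns (as produced by the callers).
#' @param ref the \code{ref_genome} the calls refer to.
#' @param path output file.
#' @export
write_vcf <- function(calls, ref, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rfpsim",
           sprintf("##contig=<ID=%s,length=%d>", names(ref$contigs),
                   nchar(ref$contigs)),
           "##FILTER=<ID=RFP,Description=\"Matches a recurrent false positive catalogue entry\">",
           "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Calling rule\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  filt <- if ("filter" %in% names(calls)) calls$filter else "PASS"
  info <- if ("caller_id" %in% names(calls))
    paste0("CALLER=", calls$caller_id) else "."
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
                 calls$contig, calls$pos, calls$ref, calls$alt,
                 format(round(as.numeric(calls$qual), 2), trim = TRUE),
                 filt, info)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a VCF file of SNV calls
#'
#' @param path VCF file.
#' @return data.frame(contig, pos, ref, alt, qual, filter, caller_id).
#' @export
read_vcf <- function(path) {
  ln <- readLines(path)
  if (!length(ln) || !startsWith(ln[1], "##fileformat=VCF"))
    stop("VCF parse error in '", path, "' at line 1: missing ##fileformat")
  body_at <- which(!startsWith(ln, "#"))
  out <- data.frame(contig = character(), pos = integer(), ref = character(),
                    alt = character(), qual = numeric(), filter = character(),
                    caller_id = character(), stringsAsFactors = FALSE)
  if (!length(body_at)) return(out)
  f <- strsplit(ln[body_at], "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 1L) < 8L)
  if (length(bad))
    stop("VCF parse error in '", path, "' at line ", body_at[bad[1]],
         ": fewer than 8 fields")
  g <- function(i) vapply(f, `[`, "", i)
  pos <- suppressWarnings(as.integer(g(2)))
  if (anyNA(pos))
    stop("VCF parse error in '", path, "' at line ",
         body_at[which(is.na(pos))[1]], ": non-numeric POS")
  info <- g(8)
  caller <- ifelse(grepl("CALLER=", info),
                   sub(".*CALLER=([^;]+).*", "\\1", info), NA_character_)
  data.frame(contig = g(1), pos = pos, ref = g(4), alt = g(5),
             qual = suppressWarnings(as.numeric(g(6))), filter = g(7),
             caller_id = caller, stringsAsFactors = FALSE)
}
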