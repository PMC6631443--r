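#' Write sequences to FASTA
#'
#' Accepts a \code{ref_genome}, an \code{individual_genome} (haplotype 1 is
#' written, or both when \code{haplotypes = TRUE}) or a named character
#' vector.  Sequences are wrapped at 60 columns.
#'
#' @param x genome object or named character vector.
#' @param path output file.
#' @param haplotypes write both haplotypes of an individual.
#' @export
write_fasta <- function(x, path, haplotypes = FALSE) {
  seqs <- if (inherits(x, "ref_genome")) x$contigs
  else if (inherits(x, "individual_genome")) {
    if (haplotypes) c(hap1 = x$haplotypes[1], hap2 = x$haplotypes[2])
    else stats::setNames(x$haplotypes[1], names(x$ref$contigs)[1])
  } else x
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (any(nchar(seqs) == 0L)) stop("empty sequence cannot be written")
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path input file.
#' @return named character vector, upper-cased.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0L) stop("FASTA parse error in '", path, "': no records")
  if (any(Biostrings::width(ss) == 0L))
    stop("FASTA parse error in '", path, "': empty sequence record")
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write read pairs to a pair of FASTQ files
#'
#' Phred+33 encoding with the constant base quality carried by the read set
#' (callers in this package do not use quality variation).  Mate ids carry
#' the conventional \code{/1} and \code{/2} suffixes.
#'
#' @param reads a \code{read_set} from \code{\link{sample_reads}}.
#' @param path1,path2 output FASTQ paths for mate 1 and mate 2.
#' @export
write_fastq <- function(reads, path1, path2) {
  stopifnot(inherits(reads, "read_set"))
  qchar <- rawToChar(as.raw(reads$base_quality + 33L))
  wr <- function(id, seq, path, mate) {
    qual <- vapply(nchar(seq), function(n) strrep(qchar, n), "")
    out <- rbind(paste0("@", id, "/", mate), seq, "+", qual)
    writeLines(as.vector(out), path)
  }
  wr(reads$pairs$id, reads$pairs$seq1, path1, 1L)
  wr(reads$pairs$id, reads$pairs$seq2, path2, 2L)
  invisible(c(path1, path2))
}

#' Read paired FASTQ files
#'
#' @param path1,path2 FASTQ paths (mate 1, mate 2); gzip transparent.
#' @return a \code{read_set} (truth fields absent).
#' @export
read_fastq <- function(path1, path2) {
  rd <- function(path, mate) {
    ln <- readLines(path)
    if (length(ln) == 0L)
      return(data.frame(id = character(), seq = character(),
                        stringsAsFactors = FALSE))
    if (length(ln) %% 4L != 0L)
      stop("FASTQ parse error in '", path, "': record count not a multiple of 4")
    id <- sub("^@", "", ln[seq(1, length(ln), 4)])
    id <- sub(paste0("/", mate, "$"), "", id)
    seq <- toupper(ln[seq(2, length(ln), 4)])
    qual <- ln[seq(4, length(ln), 4)]
    bad <- which(nchar(seq) != nchar(qual))
    if (length(bad))
      stop("FASTQ parse error in '", path, "' near line ", bad[1] * 4L,
           ": sequence/quality length mismatch")
    data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
  }
  r1 <- rd(path1, 1L); r2 <- rd(path2, 2L)
  if (nrow(r1) != nrow(r2)) stop("mate files differ in record count")
  bq <- if (nrow(r1)) utf8ToInt(substr(r1$qual[1], 1, 1)) - 33L else 25L
  pairs <- data.frame(id = r1$id, seq1 = r1$seq, seq2 = r2$seq,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, read_length = if (nrow(r1)) nchar(r1$seq[1]) else NA_integer_,
                 base_quality = bq, config = NULL),
            class = "read_set")
}
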