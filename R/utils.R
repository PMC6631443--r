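`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Hash-based derivation keyed on (master seed, stream index); children are
#' statistically independent of one another and of neighbouring indices, so
#' rounds of a simulation can be executed in any order with identical results.
#'
#' @param seed integer master seed.
#' @param index integer stream index (e.g. round number).
#' @return a single integer seed in \code{[0, 2^31)}.
#' @export
derive_seed <- function(seed, index) {
  as.integer(cpp_derive_seed(as.double(seed), as.double(index)))
}

# Run code with a temporarily-seeded R RNG, restoring state afterwards.
local_seed_eval <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Reverse-complement DNA strings
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

#' Canonical variant keys
#'
#' A variant key is the string \code{"contig:pos:ref>alt"} (1-based position);
#' it is the identity used for all set operations, incidence matrices and
#' catalogue comparisons.
#'
#' @param contig,pos,ref,alt vectors describing SNVs.
#' @return character vector of keys with a total ordering.
#' @export
variant_key <- function(contig, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", as.character(contig), as.integer(pos),
          as.character(ref), as.character(alt))
}

#' Split variant keys back into their components
#' @param key character vector of keys as made by \code{\link{variant_key}}.
#' @return data.frame with contig, pos, ref, alt columns.
#' @export
parse_variant_key <- function(key) {
  m <- regmatches(key, regexec("^(.+):(\\d+):([ACGT])>([ACGT])$", key))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("malformed variant key: ", key[bad][1])
  data.frame(contig = vapply(m, `[`, "", 2L),
             pos = as.integer(vapply(m, `[`, "", 3L)),
             ref = vapply(m, `[`, "", 4L),
             alt = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

# Contig offset table for a reference: 0-based global starts/ends.
contig_offsets <- function(ref) {
  len <- nchar(ref$contigs)
  start0 <- cumsum(c(0L, unname(len[-length(len)])))
  data.frame(contig = names(ref$contigs), start0 = start0,
             end0 = start0 + unname(len), stringsAsFactors = FALSE)
}

# Map (contig, pos 1-based) -> global 0-based position.
to_global0 <- function(ref, contig, pos) {
  off <- contig_offsets(ref)
  i <- match(contig, off$contig)
  if (anyNA(i)) stop("unknown contig: ", paste(unique(contig[is.na(i)]), collapse = ", "))
  off$start0[i] + as.integer(pos) - 1L
}

# Map global 0-based positions -> data.frame(contig, pos 1-based).
to_local1 <- function(ref, pos0) {
  off <- contig_offsets(ref)
  i <- findInterval(pos0, off$start0)
  data.frame(contig = off$contig[i], pos = as.integer(pos0 - off$start0[i] + 1L),
             stringsAsFactors = FALSE)
}

concat_genome <- function(seqs) paste(seqs, collapse = "")

# substring() rejects empty position vectors; this does not
substr_at <- function(s, pos) {
  if (length(pos)) substring(s, pos, pos) else character(0)
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x)) stop(name, " must be a non-missing scalar")
  invisible(x)
}
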