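#' Check catalogue entries against the paralog ledger (mechanism oracle)
#'
#' The miscall mechanism predicts that a recurrent false positive at a
#' position inside a paralog copy carries, as its alternate allele, the base
#' that the \emph{sister} copy holds at the homologous offset in the aligned
#' genome — the true inter-copy difference imported by misassigned reads.
#' Inter-copy differences comprise the reference difference sites recorded in
#' the ledger plus any individual variants planted inside a copy, so the
#' oracle looks the homologous base up in the individual's realised
#' haplotypes.
#'
#' @param keys character vector of variant keys (or an \code{rfp_catalogue},
#'   whose RFP-class keys are used).
#' @param ledger the \code{paralog_ledger} of the reference.
#' @param individual the \code{individual_genome} the rounds were run on.
#' @return logical vector: does the key sit inside a paralog copy with its
#'   alternate allele equal to a sister copy's base at the homologous
#'   position (and that base differing between the copies)?
#' @export
mechanism_check <- function(keys, ledger, individual) {
  if (inherits(keys, "rfp_catalogue")) keys <- catalogue_keys(keys, "RFP")
  if (!length(keys)) return(logical(0))
  kd <- parse_variant_key(keys)
  cp <- ledger$copies
  haps <- individual$haplotypes
  ok <- logical(length(keys))
  for (i in seq_along(keys)) {
    row <- which(cp$start <= kd$pos[i] & cp$end >= kd$pos[i])
    if (!length(row)) next
    row <- row[1]
    offset <- kd$pos[i] - cp$start[row]
    sisters <- which(cp$family == cp$family[row] & cp$copy != cp$copy[row])
    for (s in sisters) {
      spos <- cp$start[s] + offset
      sb <- unique(substring(haps, spos, spos))
      here <- unique(substring(haps, kd$pos[i], kd$pos[i]))
      if (kd$alt[i] %in% sb && !all(sb %in% here)) { ok[i] <- TRUE; break }
    }
  }
  ok
}

#' Fraction of RFP-class keys consistent with the paralog-miscall mechanism
#'
#' @inheritParams mechanism_check
#' @param catalogue an \code{rfp_catalogue}.
#' @return fraction in [0, 1] (NA when the catalogue has no RFP keys).
#' @export
sister_allele_fraction <- function(catalogue, ledger, individual) {
  keys <- catalogue_keys(catalogue, "RFP")
  if (!length(keys)) return(NA_real_)
  mean(mechanism_check(keys, ledger, individual))
}
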