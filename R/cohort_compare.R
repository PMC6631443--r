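#' Build a cohort call table
#'
#' Presence/absence of variant keys across individuals, with per-key
#' population frequency — the object the population-frequency
#' classification reads.
#'
#' @param call_sets named list, one element per individual: a character
#'   vector of variant keys, an \code{rfp_catalogue} (its non-sporadic keys
#'   are used), or a calls data.frame with contig/pos/ref/alt columns.
#' @return an object of class \code{cohort_table}: logical keys-by-individual
#'   matrix and per-key frequency.
#' @export
cohort_table <- function(call_sets) {
  if (is.null(names(call_sets)) || anyDuplicated(names(call_sets)))
    stop("call_sets must be uniquely named by individual")
  as_keys <- function(x) {
    if (inherits(x, "rfp_catalogue")) catalogue_keys(x, c("RFP", "consistent"))
    else if (is.data.frame(x)) unique(variant_key(x$contig, x$pos, x$ref, x$alt))
    else unique(as.character(x))
  }
  sets <- lapply(call_sets, as_keys)
  keys <- sort(unique(unlist(sets)))
  m <- vapply(sets, function(s) keys %in% s, logical(length(keys)))
  if (length(keys) == 1L) m <- matrix(m, nrow = 1L,
                                      dimnames = list(keys, names(sets)))
  rownames(m) <- keys
  structure(list(keys = keys, presence = m,
                 frequency = if (length(keys)) rowMeans(m) else numeric(0),
                 n_individuals = length(sets)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", length(x$keys), "keys across", x$n_individuals,
      "individuals\n")
  invisible(x)
}

#' Classify variants by population frequency across a cohort
#'
#' The cohort-scale analogue of per-round classification: variants present
#' in nearly all individuals are fixed (strain) variation, variants private
#' to a few individuals are rare (pedigree-specific), and variants at
#' intermediate population frequency are recurrent false positives.
#'
#' @param cohort a \code{cohort_table} built from >= 2 individuals.
#' @param f_low,f_high thresholds (defaults 0.05 and 0.95; strict
#'   inequalities delimit the RFP class).
#' @return data.frame(key, frequency, class) with class in
#'   \{fixed, RFP, rare\}.
#' @export
popfreq_classify <- function(cohort, f_low = 0.05, f_high = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (cohort$n_individuals < 2L) stop("need at least two individuals")
  f <- cohort$frequency
  cls <- ifelse(f >= f_high, "fixed", ifelse(f <= f_low, "rare", "RFP"))
  data.frame(key = cohort$keys, frequency = unname(f), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Jaccard similarity between two variant-key sets
#'
#' @param a,b character vectors of variant keys (or catalogues; RFP keys are
#'   used).
#' @return \code{|A intersect B| / |A union B|}; two empty sets compare as 1
#'   with a warning.
#' @export
jaccard <- function(a, b) {
  if (inherits(a, "rfp_catalogue")) a <- catalogue_keys(a, "RFP")
  if (inherits(b, "rfp_catalogue")) b <- catalogue_keys(b, "RFP")
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both sets empty; similarity defined as 1")
    return(1)
  }
  length(intersect(a, b)) / u
}

#' Pairwise similarity matrix between catalogues
#'
#' @param catalogues named list of key vectors or \code{rfp_catalogue}s.
#' @param metric similarity function taking two key vectors (default
#'   \code{\link{jaccard}}).
#' @return symmetric matrix with unit diagonal, class
#'   \code{similarity_matrix}, with the metric name attached.
#' @export
similarity_matrix <- function(catalogues, metric = jaccard) {
  sets <- lapply(catalogues, function(x)
    if (inherits(x, "rfp_catalogue")) catalogue_keys(x, "RFP") else
      unique(as.character(x)))
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- suppressWarnings(metric(sets[[i]], sets[[j]]))
      }
    }
  }
  attr(m, "metric") <- deparse(substitute(metric))
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Write a similarity matrix as TSV
#' @param m a \code{similarity_matrix}.
#' @param path output file.
#' @export
write_similarity <- function(m, path) {
  write.table(as.data.frame(unclass(m)), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Intersection of two call sets
#'
#' Variants identified by both callers; restricting a call set to this
#' intersection removes the bulk of recurrent false positives, since the two
#' rules rarely agree on marginal miscalled sites.
#'
#' @param calls_a,calls_b calls data.frames or key vectors.
#' @return character vector of shared variant keys.
#' @export
intersect_callers <- function(calls_a, calls_b) {
  as_keys <- function(x)
    if (is.data.frame(x)) unique(variant_key(x$contig, x$pos, x$ref, x$alt))
    else unique(as.character(x))
  intersect(as_keys(calls_a), as_keys(calls_b))
}

#' Soft-filter calls against an RFP catalogue
#'
#' Calls whose key is RFP-class in the catalogue get \code{FILTER = "RFP"};
#' all others \code{"PASS"}.  Removal is left to the caller (soft filter).
#'
#' @param calls calls data.frame (contig, pos, ref, alt, ...).
#' @param catalogue an \code{rfp_catalogue}.
#' @return the calls with a \code{filter} column set.
#' @export
blacklist_filter <- function(calls, catalogue) {
  meta <- attr(catalogue, "meta")
  if (nrow(calls) && nrow(catalogue) &&
      !any(unique(calls$contig) %in% unique(catalogue$contig)))
    stop("reference build mismatch: no shared contig names between calls ",
         "and catalogue")
  rfp <- catalogue_keys(catalogue, "RFP")
  keys <- variant_key(calls$contig, calls$pos, calls$ref, calls$alt)
  calls$filter <- ifelse(keys %in% rfp, "RFP", "PASS")
  calls
}

#' Read-length sweep of the resample-realign-recall procedure
#'
#' Repeats \code{\link{run_rounds}} at several read lengths with coverage
#' matched in sequenced bases (constant coverage, hence fewer, longer pairs),
#' isolating the read-length effect on recurrent miscalls.  Reports
#' per-length RFP counts, the pairwise Jaccard similarity of the per-length
#' RFP catalogues and the fraction of each catalogue unique to its length.
#'
#' @param individual an \code{individual_genome}.
#' @param lengths ascending read lengths in bases.
#' @param n_rounds rounds per length.
#' @param coverage depth over the sampling space, constant across lengths.
#' @param error_rate per-base error rate.
#' @param aligner_cfg an \code{\link{align_config}}.
#' @param caller calling rule.
#' @param master_seed master seed.
#' @param min_mapq pileup inclusion threshold.
#' @return list with \code{catalogues}, \code{rfp_counts},
#'   \code{similarity} matrix and \code{fraction_unique} per length.
#' @export
read_length_sweep <- function(individual, lengths = c(80L, 100L, 120L, 140L),
                              n_rounds = 30L, coverage = 30,
                              error_rate = 0.01,
                              aligner_cfg = align_config(),
                              caller = "A", master_seed = 1L, min_mapq = 0L) {
  if (is.unsorted(lengths, strictly = TRUE))
    stop("lengths must be strictly ascending")
  ledger <- individual$ledger
  if (!is.null(ledger) && nrow(ledger$copies)) {
    max_span <- max(lengths)
    if (max_span > individual$ref$spec$copy_length + 2L * individual$ref$pad_length)
      stop("read length exceeds copy_length + 2 * pad")
  }
  index <- build_index(individual$ref, aligner_cfg$k)
  cats <- stats::setNames(vector("list", length(lengths)),
                          paste0("L", lengths))
  for (i in seq_along(lengths)) {
    scfg <- sampler_config(read_length = lengths[i], error_rate = error_rate,
                           coverage = coverage)
    m <- run_rounds(individual, n_rounds = n_rounds, sampler_cfg = scfg,
                    aligner_cfg = aligner_cfg, caller = caller,
                    master_seed = derive_seed(master_seed, lengths[i]),
                    min_mapq = min_mapq, index = index)
    cats[[i]] <- classify_calls(m)
  }
  rfp_sets <- lapply(cats, catalogue_keys, "RFP")
  sim <- similarity_matrix(rfp_sets)
  frac_unique <- vapply(seq_along(rfp_sets), function(i) {
    others <- unique(unlist(rfp_sets[-i]))
    if (!length(rfp_sets[[i]])) return(NA_real_)
    mean(!(rfp_sets[[i]] %in% others))
  }, 0)
  names(frac_unique) <- names(cats)
  list(catalogues = cats,
       rfp_counts = vapply(rfp_sets, length, 0L),
       similarity = sim,
       fraction_unique = frac_unique)
}
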