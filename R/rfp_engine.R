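#' Run the resample-realign-recall procedure
#'
#' The core iterative procedure: in each round, reads are freshly sampled
#' from the individual genome, aligned to the reference and variants are
#' called; the per-round call sets are assembled into a boolean incidence
#' matrix over the union of variant keys.  Each round draws from an
#' independent random stream derived from \code{(master_seed, round)}, so the
#' result is fully reproducible and independent of execution order.
#'
#' @param individual an \code{individual_genome}.
#' @param n_rounds number of rounds (default 10, the recommended depth for
#'   recovering the bulk of recurrent miscalls).
#' @param sampler_cfg a \code{\link{sampler_config}}.
#' @param aligner_cfg an \code{\link{align_config}}.
#' @param caller "A", "B" or "both"; with "both" the two rules run on the
#'   identical per-round alignments and a matrix is returned per caller.
#' @param caller_params optional list of parameters passed to the caller(s);
#'   for "both", a list with elements \code{A} and \code{B}.
#' @param master_seed master seed for the whole run.
#' @param min_mapq pileup inclusion threshold (0 keeps tie-broken reads —
#'   required for miscalls to manifest; 1 suppresses them).
#' @param index optional prebuilt \code{kmer_index} over the reference.
#' @param retain_dir if non-NULL, per-round VCFs (and the reference) are
#'   written under this directory.
#' @return a \code{call_matrix} (or, for \code{caller = "both"}, a named
#'   list of two sharing the same rounds): variant keys, the keys-by-rounds
#'   incidence matrix, per-key call frequency and run metadata.
#' @export
run_rounds <- function(individual, n_rounds = 10L,
                       sampler_cfg = sampler_config(),
                       aligner_cfg = align_config(),
                       caller = c("A", "B", "both"),
                       caller_params = NULL,
                       master_seed = 1L, min_mapq = 0L,
                       index = NULL, retain_dir = NULL) {
  stopifnot(inherits(individual, "individual_genome"), n_rounds >= 1L)
  caller <- match.arg(caller)
  ref <- individual$ref
  if (is.null(index)) index <- build_index(ref, aligner_cfg$k)
  callers <- if (caller == "both") c("A", "B") else caller
  sets <- stats::setNames(vector("list", length(callers)), callers)
  for (cl in callers) sets[[cl]] <- vector("list", n_rounds)
  if (!is.null(retain_dir)) {
    dir.create(retain_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ref, file.path(retain_dir, "reference.fa"))
  }
  for (r in seq_len(n_rounds)) {
    step <- "sample"
    res <- tryCatch({
      reads <- sample_reads(individual, sampler_cfg, seed = master_seed,
                            round = r)
      step <- "align"
      aln <- align_reads(reads, index, aligner_cfg, seed = master_seed,
                         round = r)
      step <- "call"
      pu <- build_pileup(aln, ref, min_mapq = min_mapq)
      lapply(stats::setNames(callers, callers), function(cl) {
        prm <- if (caller == "both") caller_params[[cl]] else caller_params
        call_variants(pu, cl, prm %||% list())
      })
    }, error = function(e) {
      stop("round ", r, " failed at stage '", step, "': ",
           conditionMessage(e), call. = FALSE)
    })
    for (cl in callers) {
      calls <- res[[cl]]
      sets[[cl]][[r]] <- unique(variant_key(calls$contig, calls$pos,
                                            calls$ref, calls$alt))
      if (!is.null(retain_dir))
        write_vcf(calls, ref,
                  file.path(retain_dir,
                            sprintf("round%03d_caller%s.vcf", r, cl)))
    }
  }
  meta <- list(n_rounds = as.integer(n_rounds), master_seed = master_seed,
               read_length = sampler_cfg$read_length,
               error_rate = sampler_cfg$error_rate,
               min_mapq = as.integer(min_mapq),
               paired = aligner_cfg$paired)
  out <- lapply(stats::setNames(callers, callers), function(cl) {
    build_call_matrix(sets[[cl]], c(meta, caller_id = cl))
  })
  if (caller == "both") out else out[[1]]
}

#' Assemble a call matrix from per-round key sets
#'
#' @param round_keys list of character vectors of variant keys, one per
#'   round.
#' @param meta metadata list stored on the result.
#' @return an object of class \code{call_matrix}.
#' @export
build_call_matrix <- function(round_keys, meta = list()) {
  n_rounds <- length(round_keys)
  keys <- sort(unique(unlist(round_keys)))
  inc <- matrix(FALSE, nrow = length(keys), ncol = n_rounds,
                dimnames = list(keys, paste0("round", seq_len(n_rounds))))
  for (r in seq_len(n_rounds)) inc[match(round_keys[[r]], keys), r] <- TRUE
  structure(list(keys = keys, incidence = inc,
                 frequency = if (length(keys)) rowMeans(inc) else numeric(0),
                 n_rounds = n_rounds, meta = meta),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat("call_matrix:", length(x$keys), "variant keys over", x$n_rounds,
      "rounds\n")
  invisible(x)
}

#' Classify variants by call frequency across rounds
#'
#' Partition of the call matrix by per-key call frequency f: recurrent false
#' positive (RFP) when \code{f_low < f < f_high} (strict on both sides),
#' consistent when \code{f >= f_high} (predominantly true variation, retained
#' but flagged so it can be discarded downstream), sporadic when
#' \code{f <= f_low}.
#'
#' @param matrix a \code{call_matrix}.
#' @param f_low,f_high classification thresholds (defaults 0.05 and 0.95).
#' @return an \code{rfp_catalogue}: data.frame with contig, pos, ref, alt,
#'   n_called, n_rounds, frequency and class, with run metadata attached.
#' @export
classify_calls <- function(matrix, f_low = 0.05, f_high = 0.95) {
  stopifnot(inherits(matrix, "call_matrix"))
  if (!(f_low > 0 && f_low < f_high && f_high < 1))
    stop("thresholds must satisfy 0 < f_low < f_high < 1")
  f <- matrix$frequency
  cls <- ifelse(f >= f_high, "consistent",
                ifelse(f <= f_low, "sporadic", "RFP"))
  kd <- if (length(matrix$keys)) parse_variant_key(matrix$keys) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  out <- cbind(kd,
               data.frame(key = matrix$keys,
                          n_called = as.integer(round(f * matrix$n_rounds)),
                          n_rounds = rep(matrix$n_rounds, length(f)),
                          frequency = unname(f), class = unname(cls),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "meta") <- c(matrix$meta, list(f_low = f_low, f_high = f_high))
  class(out) <- c("rfp_catalogue", "data.frame")
  out
}

#' Keys of a catalogue by class
#' @param catalogue an \code{rfp_catalogue}.
#' @param class classes to keep (default "RFP").
#' @return character vector of variant keys.
#' @export
catalogue_keys <- function(catalogue, class = "RFP") {
  catalogue$key[catalogue$class %in% class]
}

#' Accumulation of unique intermittent variants over rounds
#'
#' Candidate keys are those with intermediate call frequency in the final
#' matrix (a fixed-endpoint universe, so the curve is reproducible); the
#' curve counts cumulative unique candidates by first round of appearance.
#' The per-round increment rate is summarised by its sample mean (rounds
#' >= 2; the first round is burn-in since every candidate present then is
#' "new") and the variance/mean dispersion statistic, allowing comparison
#' with a Poisson increment model.
#'
#' @param matrix a \code{call_matrix} with at least 2 rounds.
#' @param f_low,f_high candidate thresholds, as in
#'   \code{\link{classify_calls}}.
#' @return an \code{accumulation_curve}: cumulative counts, increments,
#'   \code{lambda_hat} and \code{dispersion}.
#' @export
accumulation <- function(matrix, f_low = 0.05, f_high = 0.95) {
  stopifnot(inherits(matrix, "call_matrix"), matrix$n_rounds >= 2L)
  f <- matrix$frequency
  cand <- matrix$incidence[f > f_low & f < f_high, , drop = FALSE]
  if (nrow(cand)) {
    first <- apply(cand, 1L, function(x) which(x)[1])
    cum <- cumsum(tabulate(first, nbins = matrix$n_rounds))
  } else {
    cum <- rep(0L, matrix$n_rounds)
  }
  inc <- diff(c(0L, cum))
  lam <- mean(inc[-1])
  disp <- if (lam > 0) var(inc[-1]) / lam else NA_real_
  structure(list(cumulative = cum, increments = inc,
                 lambda_hat = lam, dispersion = disp,
                 n_rounds = matrix$n_rounds),
            class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat("accumulation_curve:", x$cumulative[x$n_rounds], "candidates after",
      x$n_rounds, "rounds; lambda_hat =", round(x$lambda_hat, 3), "\n")
  invisible(x)
}

#' Fraction of intermittent variants discovered by an early round
#'
#' \code{cumulative(n_small) / cumulative(n_large)} — e.g. the share of the
#' 100-round total already found after 10 rounds.
#'
#' @param curve an \code{accumulation_curve}.
#' @param n_small,n_large round indices, \code{n_small < n_large <= rounds}.
#' @return a fraction in [0, 1].
#' @export
fraction_discovered <- function(curve, n_small, n_large) {
  stopifnot(inherits(curve, "accumulation_curve"),
            n_small <= n_large, n_large <= curve$n_rounds)
  denom <- curve$cumulative[n_large]
  if (denom == 0)
    stop("no intermittent variants accumulated by round ", n_large,
         "; fraction undefined")
  curve$cumulative[n_small] / denom
}

#' Write an RFP catalogue to TSV (with a YAML metadata sidecar)
#'
#' @param catalogue an \code{rfp_catalogue}.
#' @param path output TSV; metadata goes to \code{<path>.meta.yaml}.
#' @export
write_catalogue <- function(catalogue, path) {
  cols <- c("contig", "pos", "ref", "alt", "n_called", "n_rounds",
            "frequency", "class")
  df <- as.data.frame(catalogue)[, cols]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- attr(catalogue, "meta")
  if (!is.null(meta))
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an RFP catalogue TSV
#' @param path TSV written by \code{\link{write_catalogue}}.
#' @return an \code{rfp_catalogue}.
#' @export
read_catalogue <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(contig = "character", ref = "character",
                                  alt = "character", class = "character"))
  df$key <- variant_key(df$contig, df$pos, df$ref, df$alt)
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path))
    attr(df, "meta") <- yaml::read_yaml(meta_path)
  class(df) <- c("rfp_catalogue", "data.frame")
  df
}
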