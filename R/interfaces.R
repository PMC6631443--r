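#' Assemble a run configuration
#'
#' A fully serialisable description of an end-to-end run: genome
#' specification, individual derivation, sampler/aligner/caller parameter
#' blocks, round count and master seed.  A persisted configuration plus its
#' seed reproduces a run exactly.
#'
#' @param genome list of \code{\link{genome_spec}} arguments.
#' @param individual list of \code{\link{derive_individual}} arguments
#'   (n_private_snvs, fraction_in_paralogs, zygosity_mode, seed).
#' @param sampler list of \code{\link{sampler_config}} arguments.
#' @param aligner list of \code{\link{align_config}} arguments.
#' @param caller "A", "B" or "both".
#' @param rounds number of resample-realign-recall rounds.
#' @param min_mapq pileup inclusion threshold.
#' @param master_seed master seed.
#' @return a \code{run_config} list.
#' @export
run_config <- function(genome = list(), individual = list(),
                       sampler = list(), aligner = list(),
                       caller = "A", rounds = 10L, min_mapq = 0L,
                       master_seed = 1L) {
  structure(list(genome = genome, individual = individual,
                 sampler = sampler, aligner = aligner,
                 caller = caller, rounds = as.integer(rounds),
                 min_mapq = as.integer(min_mapq),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Read/write run configurations as YAML
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' @rdname read_run_config
#' @param config a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Execute a full run from a configuration
#'
#' Forges the genome, derives the individual, runs the rounds, classifies the
#' call matrix and writes all artifacts (configuration copy, reference and
#' individual FASTA, ledger and truth TSV, catalogue TSV with metadata
#' sidecar, optional per-round VCFs, log) under \code{out_dir}.
#'
#' @param config a \code{run_config} (or path to one).
#' @param out_dir run directory to create.
#' @param retain_rounds keep per-round VCFs.
#' @return the \code{rfp_catalogue}, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir, retain_rounds = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  logf <- file.path(out_dir, "run.log")
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                              "\n", sep = "", file = logf, append = TRUE)
  logmsg("forge: building reference")
  built <- do.call(genome_spec, config$genome)
  fr <- build_reference(built)
  write_fasta(fr$reference, file.path(out_dir, "reference.fa"))
  write_ledger(fr$ledger, file.path(out_dir, "ledger.tsv"))
  ind_args <- c(list(ref = fr$reference, ledger = fr$ledger),
                config$individual)
  ind <- do.call(derive_individual, ind_args)
  write_fasta(ind, file.path(out_dir, "individual.fa"))
  write_variant_truth(ind, file.path(out_dir, "truth.tsv"))
  logmsg("rfp: ", config$rounds, " rounds, caller ", config$caller,
         ", seed ", config$master_seed)
  m <- run_rounds(ind, n_rounds = config$rounds,
                  sampler_cfg = do.call(sampler_config, config$sampler),
                  aligner_cfg = do.call(align_config, config$aligner),
                  caller = config$caller, master_seed = config$master_seed,
                  min_mapq = config$min_mapq,
                  retain_dir = if (retain_rounds) file.path(out_dir, "rounds"))
  mats <- if (inherits(m, "call_matrix")) list(m) else m
  cat_out <- NULL
  for (i in seq_along(mats)) {
    cl <- mats[[i]]$meta$caller_id
    catg <- classify_calls(mats[[i]])
    write_catalogue(catg, file.path(out_dir,
                                    sprintf("catalogue_caller%s.tsv", cl)))
    logmsg("caller ", cl, ": ", sum(catg$class == "RFP"), " RFP / ",
           sum(catg$class == "consistent"), " consistent / ",
           sum(catg$class == "sporadic"), " sporadic keys")
    if (is.null(cat_out)) cat_out <- catg
  }
  invisible(cat_out)
}

cli_usage <- function() {
  cat("usage: rfpsim <subcommand> [--flag value ...]\n",
      "subcommands:\n",
      "  forge      --out DIR [--genome-length N --families N --copies N\n",
      "             --copy-length N --identity F --pseudogene 0|1 --seed N]\n",
      "  reads      --individual-dir DIR --out-prefix P [--read-length N\n",
      "             --error-rate F --coverage F --n-pairs N --seed N]\n",
      "  align      --ref FA --fastq1 F --fastq2 F --out SAM [--k N\n",
      "             --max-mismatch N --seed N]\n",
      "  call       --ref FA --sam F --out VCF [--caller A|B --min-mapq N]\n",
      "  rfp        --config YAML --out DIR [--rounds N --seed N]\n",
      "  popfreq    --catalogues TSV,TSV,... --out TSV\n",
      "  sweep      --config YAML --out DIR [--lengths 80,100,120,140]\n",
      "  mappability --ref FA --k N --out TSV\n",
      "  compare    --catalogues TSV,TSV,... --out TSV\n",
      "  filter     --vcf F --catalogue TSV --out VCF\n", sep = "")
}

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args)) stop("missing value for --", key)
    out[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

num <- function(x, default = NULL) if (is.null(x)) default else as.numeric(x)
int <- function(x, default = NULL) if (is.null(x)) default else as.integer(x)

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package functions; see
#' \code{system.file("exec", "rfpsim", package = "rfpsim")} for the
#' executable wrapper.  Returns (rather than calls) the exit status so it
#' can be driven from tests.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return integer exit status: 0 on success, 2 on usage errors, 1 on
#'   runtime failure.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) { cli_usage(); return(2L) }
  sub <- argv[1]
  known <- c("forge", "reads", "align", "call", "rfp", "popfreq", "sweep",
             "mappability", "compare", "filter")
  if (!(sub %in% known)) {
    message("unknown subcommand: ", sub); cli_usage(); return(2L)
  }
  fl <- tryCatch(parse_flags(argv[-1]),
                 error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(fl)) { cli_usage(); return(2L) }
  status <- tryCatch({
    switch(sub,
      forge = {
        out <- fl$out %||% stop("--out required")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        spec <- genome_spec(
          genome_length = int(fl$genome_length, 200000L),
          n_paralog_families = int(fl$families, 2L),
          copies_per_family = int(fl$copies, 2L),
          copy_length = int(fl$copy_length, 10000L),
          paralog_identity = num(fl$identity, 0.99),
          include_pseudogene = int(fl$pseudogene, 0L) > 0L,
          n_unique_targets = int(fl$unique_targets, 2L),
          unique_target_length = int(fl$target_length, 3000L),
          rng_seed = int(fl$seed, 1L))
        fr <- build_reference(spec)
        write_fasta(fr$reference, file.path(out, "reference.fa"))
        write_ledger(fr$ledger, file.path(out, "ledger.tsv"))
        n <- int(fl$snvs, 0L)
        ind <- derive_individual(fr$reference, fr$ledger, n,
                                 seed = int(fl$seed, 1L))
        write_fasta(ind, file.path(out, "individual.fa"))
        write_variant_truth(ind, file.path(out, "truth.tsv"))
      },
      reads = {
        dirn <- fl$individual_dir %||% stop("--individual-dir required")
        pre <- fl$out_prefix %||% stop("--out-prefix required")
        ind <- rebuild_individual_from_dir(dirn)
        cfg <- sampler_config(read_length = int(fl$read_length, 120L),
                              error_rate = num(fl$error_rate, 0.01),
                              n_pairs = int(fl$n_pairs),
                              coverage = num(fl$coverage))
        rd <- sample_reads(ind, cfg, seed = int(fl$seed, 1L))
        write_fastq(rd, paste0(pre, "_1.fastq"), paste0(pre, "_2.fastq"))
      },
      align = {
        ref <- fasta_as_ref(fl$ref %||% stop("--ref required"))
        rd <- read_fastq(fl$fastq1 %||% stop("--fastq1 required"),
                         fl$fastq2 %||% stop("--fastq2 required"))
        idx <- build_index(ref, int(fl$k, 20L))
        cfg <- align_config(k = int(fl$k, 20L),
                            max_mismatch = int(fl$max_mismatch))
        aln <- align_reads(rd, idx, cfg, seed = int(fl$seed, 1L), round = 0L)
        write_sam(aln, ref, fl$out %||% stop("--out required"))
      },
      call = {
        ref <- fasta_as_ref(fl$ref %||% stop("--ref required"))
        sam <- read_sam(fl$sam %||% stop("--sam required"))
        aln <- sam_as_alignment_set(sam, ref)
        pu <- build_pileup(aln, ref, min_mapq = int(fl$min_mapq, 0L))
        calls <- call_variants(pu, fl$caller %||% "A")
        write_vcf(calls, ref, fl$out %||% stop("--out required"))
      },
      rfp = {
        cfgp <- fl$config %||% stop("--config required")
        cfg <- read_run_config(cfgp)
        if (!is.null(fl$rounds)) cfg$rounds <- int(fl$rounds)
        if (!is.null(fl$seed)) cfg$master_seed <- int(fl$seed)
        run_pipeline(cfg, fl$out %||% stop("--out required"))
      },
      popfreq = {
        paths <- strsplit(fl$catalogues %||% stop("--catalogues required"),
                          ",")[[1]]
        cats <- lapply(paths, read_catalogue)
        names(cats) <- basename(paths)
        cls <- popfreq_classify(cohort_table(cats))
        write.table(cls, fl$out %||% stop("--out required"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      },
      sweep = {
        cfg <- read_run_config(fl$config %||% stop("--config required"))
        out <- fl$out %||% stop("--out required")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        lens <- as.integer(strsplit(fl$lengths %||% "80,100,120,140",
                                    ",")[[1]])
        fr <- build_reference(do.call(genome_spec, cfg$genome))
        ind <- do.call(derive_individual,
                       c(list(ref = fr$reference, ledger = fr$ledger),
                         cfg$individual))
        sw <- read_length_sweep(ind, lengths = lens, n_rounds = cfg$rounds,
                                caller = cfg$caller,
                                master_seed = cfg$master_seed,
                                min_mapq = cfg$min_mapq)
        for (nm in names(sw$catalogues))
          write_catalogue(sw$catalogues[[nm]],
                          file.path(out, paste0("catalogue_", nm, ".tsv")))
        write_similarity(sw$similarity, file.path(out, "similarity.tsv"))
      },
      mappability = {
        ref <- fasta_as_ref(fl$ref %||% stop("--ref required"))
        tr <- alignability_track(ref, int(fl$k, 120L))
        write_track(tr, fl$out %||% stop("--out required"))
      },
      compare = {
        paths <- strsplit(fl$catalogues %||% stop("--catalogues required"),
                          ",")[[1]]
        cats <- lapply(paths, read_catalogue)
        names(cats) <- basename(paths)
        write_similarity(similarity_matrix(cats),
                         fl$out %||% stop("--out required"))
      },
      filter = {
        calls <- read_vcf(fl$vcf %||% stop("--vcf required"))
        catg <- read_catalogue(fl$catalogue %||% stop("--catalogue required"))
        filt <- blacklist_filter(calls, catg)
        ctg <- stats::setNames(strrep("N", max(c(filt$pos, 1L)) + 1L),
                               unique(c(filt$contig, "chr1"))[1])
        ref <- structure(list(contigs = ctg), class = "ref_genome")
        write_vcf(filt, ref, fl$out %||% stop("--out required"))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("required", conditionMessage(e))) 2L else 1L
  })
  status
}

# Wrap a bare FASTA into a ref_genome whose single target spans each contig.
fasta_as_ref <- function(path) {
  seqs <- read_fasta(path)
  structure(list(contigs = seqs,
                 targets = data.frame(contig = names(seqs), start = 1L,
                                      end = nchar(seqs), type = "unique",
                                      family = NA_integer_, copy = NA_integer_,
                                      stringsAsFactors = FALSE),
                 pad_length = 0L),
            class = "ref_genome")
}

# Reconstruct an individual from a forge output directory (reference +
# individual FASTA + truth TSV).
rebuild_individual_from_dir <- function(dirn) {
  ref <- fasta_as_ref(file.path(dirn, "reference.fa"))
  hap <- read_fasta(file.path(dirn, "individual.fa"))
  truth_path <- file.path(dirn, "truth.tsv")
  vars <- if (file.exists(truth_path))
    read.table(truth_path, sep = "\t", header = TRUE,
               colClasses = c(contig = "character", ref = "character",
                              alt = "character"))
  else data.frame(contig = character(), pos = integer(), ref = character(),
                  alt = character(), zygosity = character(),
                  stringsAsFactors = FALSE)
  structure(list(ref = ref, ledger = NULL, variants = vars,
                 haplotypes = rep(unname(hap[1]), 2)),
            class = "individual_genome")
}

# Lift a parsed SAM into the alignment_set shape build_pileup expects.
sam_as_alignment_set <- function(sam, ref) {
  a <- sam$alignments
  seq_fwd <- ifelse(a$mapped & a$strand == "-", revcomp(a$seq), a$seq)
  aln <- data.frame(id = a$id, mate = a$mate, contig = a$contig,
                    pos = a$pos, strand = a$strand,
                    mm = ifelse(is.na(a$mm), 0L, a$mm),
                    mapq = a$mapq, tie_count = NA_integer_,
                    mapped = a$mapped, proper = a$proper,
                    seq = seq_fwd, stringsAsFactors = FALSE)
  aln$pos0 <- rep(-1L, nrow(aln))
  if (any(aln$mapped))
    aln$pos0[aln$mapped] <- to_global0(ref, aln$contig[aln$mapped],
                                       aln$pos[aln$mapped])
  structure(list(alignments = aln, read_length = nchar(a$seq[1]),
                 max_mismatch = NA_integer_, paired = TRUE,
                 base_quality = 25L),
            class = "alignment_set")
}
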