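#' Run the full variant-detection pipeline
#'
#' Fits the insert-size model from a sample of pairs, then processes each
#' chromosome in one pass: evidence scan, breakpoint clustering, binomial
#' significance scoring, SNV filtering, start/end breakpoint matching for
#' indels and SVs, and windowed read-depth CNV detection. Translocation
#' breakpoints are matched after all chromosomes. Output is deterministic
#' for a fixed input.
#'
#' @param bam coordinate-sorted, indexed BAM.
#' @param ref_fasta reference FASTA (indexable; contig names must match).
#' @param out_vcf path for the VCF of calls, or `NULL` to skip writing.
#' @param out_cnv_bed path for the CNV BED, or `NULL` to skip writing.
#' @param options a [scan_options()] list.
#' @param sample_pairs pairs sampled for the insert model.
#' @param regions optional character vector of chromosomes to process.
#' @param sample sample name in the VCF.
#' @return list with `calls` (all calls, internal 0-based representation),
#'   `cnv` (CNV segments), `model` (the [insert_model()] or `NULL` for
#'   single-end input), and `report` (per-chromosome counts and settings).
#' @export
run_pipeline <- function(bam, ref_fasta, out_vcf = NULL, out_cnv_bed = NULL,
                         options = scan_options(), sample_pairs = 1e6,
                         regions = NULL, sample = "SAMPLE") {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  contigs <- hdr$targets
  genome_dss <- Biostrings::readDNAStringSet(ref_fasta)
  names(genome_dss) <- sub("\\s.*", "", names(genome_dss))
  if (!all(names(contigs) %in% names(genome_dss))) {
    stop("reference/BAM contig mismatch: ",
         paste(setdiff(names(contigs), names(genome_dss)), collapse = ", "))
  }
  chroms <- names(contigs)
  if (!is.null(regions)) chroms <- intersect(chroms, regions)

  sizes <- sample_insert_sizes(bam, max_pairs = sample_pairs,
                               min_pairs = min(1000, sample_pairs))
  read_len <- .modal_read_length(bam)
  single_end <- length(sizes) == 0
  model <- if (single_end) NULL else fit_insert_model(sizes, read_len)
  if (!single_end) check_mixed_library(sizes[sizes <= 5 * median(sizes)])
  # clustering still needs a length tolerance in single-end mode; within-read
  # indel lengths are near-exact, so a tight fallback tolerance is used
  cl_model <- if (single_end) {
    insert_model(2 * read_len, 2 * read_len + 15, 2 * read_len + 30, read_len)
  } else model
  tab <- build_tables(options$mapq_threshold, options$n_max)

  all_calls <- list()
  tra_clusters <- list()
  cnv_windows <- list()
  report <- list(model = model, single_end = single_end,
                 options = options, chromosomes = list())

  for (ch in chroms) {
    ref_seq <- as.character(genome_dss[[ch]])
    sc <- scan_chromosome(bam, ch, model, ref_seq, options)
    read_depth <- .read_depth_only(bam, ch, contigs[[ch]])

    clusters <- cluster_candidates(sc$cands, cl_model)
    if (nrow(clusters)) {
      pidx <- pmin(clusters$pos + 1L, length(sc$depth))
      clusters$depth <- pmax(as.integer(sc$depth[pidx]), 1L)
      clusters <- score_clusters(clusters, tab)
      clusters <- clusters[clusters$p_bc <= options$alpha, , drop = FALSE]
    } else {
      clusters$depth <- integer(0); clusters$p_bc <- numeric(0)
    }

    snv_calls <- call_snvs(sc$snv, sc$depth, read_depth, ch, tab, options)

    indel <- clusters[clusters$type %in% c("DEL", "INS") &
                        clusters$L_bc < options$indel_sv_boundary, ,
                      drop = FALSE]
    sv <- clusters[clusters$type %in% c("DEL", "DUP", "INV", "INS") &
                     clusters$L_bc >= options$indel_sv_boundary, ,
                   drop = FALSE]
    tra <- clusters[clusters$type == "TRA", , drop = FALSE]
    if (nrow(tra)) tra_clusters[[ch]] <- tra

    indel_sel <- select_breakpoints(indel, cl_model, gap = 2)
    indel_calls <- call_small_indels(indel_sel, cl_model)

    sv_calls <- NULL
    if (!single_end && nrow(sv)) {
      W <- model$i_max - model$i_min
      sv_sel <- select_breakpoints(sv, model, gap = W)
      parts <- list()
      for (ty in c("DEL", "DUP", "INV")) {
        st <- sv_sel[sv_sel$type == ty & sv_sel$side == "start", , drop = FALSE]
        en <- sv_sel[sv_sel$type == ty & sv_sel$side == "end", , drop = FALSE]
        parts[[ty]] <- match_breakpoints(st, en, model)
      }
      ins <- sv_sel[sv_sel$type == "INS", , drop = FALSE]
      if (nrow(ins)) {
        parts$INS <- data.frame(
          chrom = ins$chrom, pos = ins$pos, end = ins$pos, type = "INS",
          len = round(ins$L_bc), support = ins$support, p_bc = ins$p_bc,
          anchored = ins$anchored, stringsAsFactors = FALSE)
      }
      sv_calls <- do.call(rbind, parts)
    }

    chrom_calls <- .combine_chrom_calls(snv_calls, indel_calls, sv_calls,
                                        read_depth)
    all_calls[[ch]] <- chrom_calls

    win <- depth_windows(sc$depth, ch, ref_seq, options$cnv_window)
    cnv_windows[[ch]] <- win
    report$chromosomes[[ch]] <- list(
      n_records = sc$stats$n_records,
      n_duplicates = sc$stats$n_duplicates,
      n_snv = if (is.null(snv_calls)) 0L else nrow(snv_calls),
      n_indel = if (is.null(indel_calls)) 0L else nrow(indel_calls),
      n_sv = if (is.null(sv_calls)) 0L else nrow(sv_calls),
      class_counts = sc$stats$class_counts)
  }

  # translocations: whole genome
  tra_calls <- NULL
  if (length(tra_clusters) && !single_end) {
    tra_all <- do.call(rbind, tra_clusters)
    tra_sel <- select_breakpoints(tra_all, model,
                                  gap = model$i_max - model$i_min)
    tm <- match_translocations(tra_sel, model)
    if (nrow(tm)) {
      tra_calls <- data.frame(
        chrom = tm$chrom, pos = tm$pos, end = NA_real_, type = "TRA",
        len = NA_real_, ref = NA_character_, alt = NA_character_,
        support = tm$support, p_bc = tm$p_bc, gt = "0/1",
        mate_chrom = tm$mate_chrom, mate_pos = tm$mate_pos,
        stringsAsFactors = FALSE)
    }
  }

  calls <- do.call(rbind, c(all_calls, list(tra_calls)))
  if (is.null(calls)) calls <- .empty_calls()
  rownames(calls) <- NULL

  wins <- do.call(rbind, cnv_windows)
  cnv <- tryCatch({
    wins <- gc_normalize(wins)
    segment_cnv(wins, options$cnv_min_windows, options$cnv_low,
                options$cnv_high)
  }, error = function(e) NULL)

  if (!is.null(out_vcf)) {
    genome_chr <- lapply(seq_along(genome_dss), function(i)
      as.character(genome_dss[[i]]))
    names(genome_chr) <- names(genome_dss)
    write_vcf(calls, out_vcf, contigs, genome = genome_chr, sample = sample)
  }
  if (!is.null(out_cnv_bed) && !is.null(cnv) && nrow(cnv)) {
    write.table(cnv[, c("chrom", "start", "end", "type")], out_cnv_bed,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  list(calls = calls, cnv = cnv, model = model, report = report)
}

.empty_calls <- function() {
  data.frame(chrom = character(0), pos = numeric(0), end = numeric(0),
             type = character(0), len = numeric(0), ref = character(0),
             alt = character(0), support = numeric(0), p_bc = numeric(0),
             gt = character(0), mate_chrom = character(0),
             mate_pos = numeric(0), stringsAsFactors = FALSE)
}

.combine_chrom_calls <- function(snv_calls, indel_calls, sv_calls,
                                 read_depth) {
  out <- list()
  if (!is.null(snv_calls) && nrow(snv_calls)) {
    out$snv <- data.frame(
      chrom = snv_calls$chrom, pos = snv_calls$pos, end = snv_calls$pos + 1,
      type = "SNV", len = 1, ref = snv_calls$ref, alt = snv_calls$alt,
      support = snv_calls$count, p_bc = snv_calls$p_bc, gt = snv_calls$gt,
      mate_chrom = NA_character_, mate_pos = NA_real_,
      stringsAsFactors = FALSE)
  }
  for (nm in c("indel", "sv")) {
    cc <- if (nm == "indel") indel_calls else sv_calls
    if (is.null(cc) || nrow(cc) == 0) next
    rd <- pmax(as.integer(read_depth[pmin(cc$pos + 1, length(read_depth))]), 1)
    denom <- ifelse(cc$type %in% c("DEL", "DUP", "INV"), 2 * rd, rd)
    af <- cc$support / denom
    out[[nm]] <- data.frame(
      chrom = cc$chrom, pos = cc$pos, end = cc$end, type = cc$type,
      len = cc$len, ref = NA_character_, alt = NA_character_,
      support = cc$support, p_bc = cc$p_bc,
      gt = ifelse(af >= 0.8, "1/1", "0/1"),
      mate_chrom = NA_character_, mate_pos = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# aligned-read depth (sequenced bases only), used for allele fractions
.read_depth_only <- function(bam, chrom, chromlen) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("pos", "cigar"),
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(1, chromlen)))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(x$pos) == 0) return(S4Vectors::Rle(0L, chromlen))
  w <- .cig_ref_width(x$cigar)
  iv <- IRanges::restrict(IRanges::IRanges(x$pos, width = w), 1L, chromlen)
  IRanges::coverage(iv, width = chromlen)
}

.modal_read_length <- function(bam) {
  bf <- Rsamtools::BamFile(bam, yieldSize = 10000)
  open(bf); on.exit(close(bf))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = "qwidth")
  x <- Rsamtools::scanBam(bf, param = param)[[1]]$qwidth
  if (length(x) == 0) return(100L)
  as.integer(names(which.max(table(x))))
}
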