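# Shared fixtures: simulations are cached per test run so several test files
# can reuse the same BAM without re-simulating.

.fix_cache <- new.env(parent = emptyenv())

basic_variants <- function() {
  data.frame(chrom = "chr1",
             type = c("SNV", "SNV", "DEL", "INS", "DEL", "DUP", "INV"),
             pos = c(10000, 12000, 20000, 25000, 40000, 60000, 80000),
             len = c(1, 1, 10, 8, 1000, 1000, 1000),
             zygosity = c("het", "hom", "hom", "het", "hom", "het", "hom"),
             stringsAsFactors = FALSE)
}

fixture_sim <- function(name) {
  if (!is.null(.fix_cache[[name]])) return(.fix_cache[[name]])
  dir <- file.path(tempdir(), paste0("omnivar_fix_", name))
  spec <- switch(
    name,
    basic = sim_spec(chrom_lengths = c(chr1 = 100000),
                     variants = basic_variants(), coverage = 30, seed = 7),
    flat = sim_spec(chrom_lengths = c(chr1 = 60000), coverage = 30,
                    seed = 3),
    tra = sim_spec(
      chrom_lengths = c(chr1 = 100000, chr2 = 80000),
      variants = data.frame(chrom = "chr1", type = "TRA", pos = 60000,
                            len = NA, zygosity = "het", alt = NA,
                            chrom2 = "chr2", pos2 = 30000,
                            stringsAsFactors = FALSE),
      coverage = 30, duplicate_fraction = 0.1, seed = 11),
    stop("unknown fixture: ", name))
  out <- simulate_reads(spec, dir)
  out$spec <- spec
  .fix_cache[[name]] <- out
  out
}

fixture_model <- function(fix) {
  key <- paste0("model_", digest_path(fix$bam))
  if (!is.null(.fix_cache[[key]])) return(.fix_cache[[key]])
  m <- fit_insert_model(sample_insert_sizes(fix$bam, max_pairs = 1e6),
                        fix$spec$read_length)
  .fix_cache[[key]] <- m
  m
}

fixture_ref <- function(fix, chrom = "chr1") {
  as.character(Biostrings::readDNAStringSet(fix$fasta)[[chrom]])
}

digest_path <- function(p) gsub("[^A-Za-z0-9]", "_", p)

# Hand-built tiny BAMs for exact-evidence tests ------------------------------

tiny_bam <- function(records, chromlens, dir = tempfile("tinybam"),
                     sort_order = "coordinate") {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "t.sam")
  hdr <- c(sprintf("@HD\tVN:1.6\tSO:%s", sort_order),
           sprintf("@SQ\tSN:%s\tLN:%d", names(chromlens),
                   as.integer(chromlens)))
  writeLines(c(hdr, records), sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "u"), overwrite = TRUE,
                           indexDestination = FALSE)
  if (sort_order != "coordinate") return(bam0)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "t"))
  Rsamtools::indexBam(bam)
  bam
}

sam_rec <- function(qname, flag, rname, pos1, mapq, cigar, rnext = "*",
                    pnext = 0, tlen = 0, qlen = NULL, opt = NULL) {
  if (is.null(qlen)) {
    qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  }
  line <- paste(qname, flag, rname, pos1, mapq, cigar, rnext, pnext, tlen,
                strrep("A", qlen), strrep("?", qlen), sep = "\t")
  if (!is.null(opt)) line <- paste(line, opt, sep = "\t")
  line
}

# Independent greedy-clustering oracle: a direct transcription of the
# assignment rules, kept free of the package's data structures.
oracle_cluster <- function(lengths, weights, ids, base_term) {
  cl <- list()
  for (i in seq_along(lengths)) {
    if (length(cl)) {
      sup <- vapply(cl, function(c) c$support, numeric(1))
      mu <- vapply(cl, function(c) c$mean, numeric(1))
      has <- vapply(cl, function(c) ids[i] %in% c$ids, logical(1))
      tol <- base_term * (1 + 1 / sup)
      dd <- abs(mu - lengths[i])
      elig <- which(dd <= tol & !has)
      if (length(elig)) {
        j <- elig[order(-sup[elig], dd[elig], elig)][1]
        cl[[j]]$mean <- (cl[[j]]$mean * cl[[j]]$support +
                           lengths[i] * weights[i]) /
          (cl[[j]]$support + weights[i])
        cl[[j]]$support <- cl[[j]]$support + weights[i]
        cl[[j]]$ids <- c(cl[[j]]$ids, ids[i])
        next
      }
      if (any(dd <= tol & has)) next   # only duplicate-read clusters fit
    }
    cl[[length(cl) + 1]] <- list(mean = lengths[i], support = weights[i],
                                 ids = ids[i])
  }
  cl
}

# canonical comparable form of a cluster list (package or oracle fields)
cluster_signature <- function(cl) {
  sig <- lapply(cl, function(c)
    list(mean = round(if (is.null(c$mean)) c$L_bc else c$mean, 9),
         support = if (is.null(c$support)) c$x_bc else c$support,
         ids = sort(as.character(c$ids))))
  sig[order(vapply(sig, function(s) s$mean, numeric(1)),
            vapply(sig, function(s) s$support, numeric(1)))]
}
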