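#' Specification of a synthetic paired-end library
#'
#' Describes a synthetic genome, the variants planted on it, and the
#' sequencing library drawn from the variant haplotypes. Defaults describe a
#' typical modern short-read WGS library: 30-fold read coverage, 150-base
#' reads, fragment (insert) sizes Normal(500, 50), 0.1% per-base substitution
#' error. Variants are planted on a diploid sample: homozygous variants on
#' both haplotypes, heterozygous on one.
#'
#' @param chrom_lengths named integer vector of reference chromosome lengths.
#' @param variants data.frame with columns `chrom`, `type` (one of SNV, INS,
#'   DEL, DUP, INV, TRA), `pos` (0-based), `len`, `zygosity` ("het"/"hom"),
#'   and optionally `alt` (SNV alternate base or insertion sequence),
#'   `chrom2`, `pos2` (TRA partner breakpoint). May be empty.
#' @param coverage total read (sequence) coverage, fold.
#' @param read_length read length, bases.
#' @param insert_mean,insert_sd insert-size distribution, bases.
#' @param error_rate per-base substitution error probability.
#' @param duplicate_fraction fraction of extra duplicate fragments added
#'   (copies of existing fragments, sharing external coordinates).
#' @param gc_range per-kilobase GC content is drawn uniformly in this range.
#' @param gc_bias linear coverage bias: fragments are accepted with
#'   probability proportional to `1 + gc_bias * 2 * (gc - 0.5)`.
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(chrom_lengths = c(chr1 = 1e6), variants = NULL,
                     coverage = 30, read_length = 150,
                     insert_mean = 500, insert_sd = 50,
                     error_rate = 0.001, duplicate_fraction = 0,
                     gc_range = c(0.4, 0.6), gc_bias = 0, seed = 1) {
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(0), type = character(0),
                           pos = numeric(0), len = numeric(0),
                           zygosity = character(0), stringsAsFactors = FALSE)
  }
  for (col in c("alt", "chrom2", "pos2")) {
    if (is.null(variants[[col]])) variants[[col]] <- rep(NA, nrow(variants))
  }
  spec <- list(chrom_lengths = chrom_lengths, variants = variants,
               coverage = coverage, read_length = read_length,
               insert_mean = insert_mean, insert_sd = insert_sd,
               error_rate = error_rate,
               duplicate_fraction = duplicate_fraction,
               gc_range = gc_range, gc_bias = gc_bias, seed = seed)
  class(spec) <- "sim_spec"
  .validate_variants(spec)
  spec
}

.validate_variants <- function(spec) {
  v <- spec$variants
  if (nrow(v) == 0) return(invisible(TRUE))
  stopifnot(all(v$type %in% c("SNV", "INS", "DEL", "DUP", "INV", "TRA")))
  iv <- data.frame(chrom = v$chrom, start = v$pos,
                   end = ifelse(v$type %in% c("DEL", "DUP", "INV"),
                                v$pos + v$len, v$pos + 1))
  if (any(v$type == "TRA")) {
    t <- v[v$type == "TRA", ]
    iv <- rbind(iv, data.frame(chrom = t$chrom2, start = t$pos2,
                               end = t$pos2 + 1))
  }
  conflicts <- character(0)
  for (ch in unique(iv$chrom)) {
    x <- iv[iv$chrom == ch, ]
    x <- x[order(x$start), ]
    bad <- which(x$start[-1] < x$end[-nrow(x)])
    if (length(bad)) {
      conflicts <- c(conflicts, sprintf("%s:%d-%d overlaps %s:%d-%d",
        ch, x$start[bad + 1], x$end[bad + 1], ch, x$start[bad], x$end[bad]))
    }
    lens <- spec$chrom_lengths[[ch]]
    if (any(x$start < 0) || any(x$end > lens)) {
      conflicts <- c(conflicts, sprintf("variant outside %s bounds", ch))
    }
  }
  if (length(conflicts)) {
    stop("overlapping/out-of-bounds variants:\n  ",
         paste(conflicts, collapse = "\n  "))
  }
  invisible(TRUE)
}

.BASES <- c("A", "C", "G", "T")

#' Standard mixed evaluation scenario
#'
#' A 1 Mb diploid genome (two chromosomes) carrying all variant classes at
#' typical WGS study conditions: 100 SNVs and 20 short indels (2-40 bases,
#' mixed zygosity), deletions, tandem duplications and inversions of 300,
#' 1000 and 5000 bases, one reciprocal translocation, 30-fold coverage,
#' 150-base reads, inserts Normal(500, 50), 0.1% base error and 5% duplicate
#' pairs. Variant positions are fixed so the truth set is stable; only the
#' genome sequence, fragment sampling and errors depend on the seed.
#'
#' @param seed RNG seed for [simulate_reads()].
#' @return a [sim_spec()].
#' @export
mixed_scenario_spec <- function(seed = 1) {
  snv1 <- seq(5000, by = 800, length.out = 50)
  snv2 <- seq(5000, by = 800, length.out = 50)
  indel_pos <- seq(530000, by = 1500, length.out = 20)
  indel_len <- rep(c(2, 5, 8, 12, 16, 20, 25, 30, 35, 40), 2)
  zyg <- function(n) rep(c("het", "hom"), length.out = n)
  v <- rbind(
    data.frame(chrom = "chr1", type = "SNV", pos = snv1, len = 1,
               zygosity = zyg(50), stringsAsFactors = FALSE),
    data.frame(chrom = "chr2", type = "SNV", pos = snv2, len = 1,
               zygosity = zyg(50), stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", type = rep(c("DEL", "INS"), 10),
               pos = indel_pos, len = indel_len, zygosity = zyg(20),
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", type = "DEL",
               pos = c(50000, 100000, 150000), len = c(300, 1000, 5000),
               zygosity = c("hom", "het", "hom"), stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", type = "DUP",
               pos = c(220000, 270000, 320000), len = c(300, 1000, 5000),
               zygosity = c("het", "hom", "het"), stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", type = "INV",
               pos = c(400000, 450000, 500000), len = c(300, 1000, 5000),
               zygosity = c("hom", "het", "hom"), stringsAsFactors = FALSE))
  v$alt <- NA; v$chrom2 <- NA; v$pos2 <- NA
  v <- rbind(v, data.frame(
    chrom = "chr1", type = "TRA", pos = 620000, len = NA, zygosity = "het",
    alt = NA, chrom2 = "chr2", pos2 = 150000, stringsAsFactors = FALSE))
  sim_spec(chrom_lengths = c(chr1 = 700000, chr2 = 300000), variants = v,
           coverage = 30, read_length = 150, insert_mean = 500,
           insert_sd = 50, error_rate = 0.001, duplicate_fraction = 0.05,
           seed = seed)
}

# Fill in unspecified SNV alternate bases and insertion sequences (uses the
# seeded RNG of simulate_reads, so results are reproducible).
.fill_variant_alleles <- function(v, genome) {
  if (nrow(v) == 0) return(v)
  v$alt <- as.character(v$alt)
  for (i in which(v$type == "SNV" & is.na(v$alt))) {
    ref <- substr(genome[[v$chrom[i]]], v$pos[i] + 1, v$pos[i] + 1)
    v$alt[i] <- sample(setdiff(.BASES, ref), 1)
  }
  for (i in which(v$type == "INS" & is.na(v$alt))) {
    v$alt[i] <- paste(sample(.BASES, v$len[i], replace = TRUE),
                      collapse = "")
  }
  v
}

.random_genome <- function(chrom_lengths, gc_range) {
  lapply(chrom_lengths, function(len) {
    nblk <- ceiling(len / 1000)
    gc <- runif(nblk, gc_range[1], gc_range[2])
    blocks <- vapply(seq_len(nblk), function(i) {
      w <- min(1000, len - (i - 1) * 1000)
      p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
      paste(sample(.BASES, w, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    paste(blocks, collapse = "")
  })
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Segment map of one derived (sample) chromosome: data.frame with ref chrom
# (NA for inserted sequence), ref start/end (0-based half-open), strand, and
# the inserted sequence for ins segments.
.identity_segs <- function(chrom, len) {
  data.frame(chrom = chrom, start = 0, end = len, strand = "+",
             ins_seq = NA_character_, stringsAsFactors = FALSE)
}

# Apply one intra-chromosomal variant to a list of derived chromosomes.
.apply_variant <- function(ders, v) {
  for (d in seq_along(ders)) {
    segs <- ders[[d]]
    hit <- which(!is.na(segs$chrom) & segs$chrom == v$chrom &
                   segs$strand == "+" &
                   segs$start <= v$pos & v$pos + .v_span(v) <= segs$end)
    if (length(hit) == 0) next
    i <- hit[1]
    seg <- segs[i, ]
    left <- seg; left$end <- v$pos
    right <- seg; right$start <- v$pos + .v_span(v)
    mid <- switch(v$type,
      DEL = NULL,
      INS = data.frame(chrom = NA_character_, start = 0,
                       end = nchar(v$alt), strand = "+",
                       ins_seq = v$alt, stringsAsFactors = FALSE),
      DUP = data.frame(chrom = rep(v$chrom, 2),
                       start = rep(v$pos, 2), end = rep(v$pos + v$len, 2),
                       strand = rep("+", 2),
                       ins_seq = rep(NA_character_, 2),
                       stringsAsFactors = FALSE),
      INV = data.frame(chrom = v$chrom, start = v$pos, end = v$pos + v$len,
                       strand = "-", ins_seq = NA_character_,
                       stringsAsFactors = FALSE))
    parts <- rbind(if (left$end > left$start) left, mid,
                   if (right$end > right$start) right)
    ders[[d]] <- rbind(
      if (i > 1) segs[seq_len(i - 1), ], parts,
      if (i < nrow(segs)) segs[(i + 1):nrow(segs), ])
    return(ders)
  }
  stop("variant does not fit in any forward segment: ", v$chrom, ":", v$pos)
}

.v_span <- function(v) {
  if (v$type %in% c("DEL", "DUP", "INV")) v$len else 0
}

# Build derived chromosomes (segment maps) for one haplotype.
.build_derived <- function(spec, hap) {
  v <- spec$variants
  use <- v$zygosity == "hom" | (hap == 1 & v$zygosity == "het")
  v <- v[use & v$type != "SNV", , drop = FALSE]
  ders <- lapply(names(spec$chrom_lengths), function(ch) {
    .identity_segs(ch, spec$chrom_lengths[[ch]])
  })
  names(ders) <- names(spec$chrom_lengths)
  tra <- v[v$type == "TRA", , drop = FALSE]
  if (nrow(tra) > 1) stop("at most one translocation per genome is supported")
  if (nrow(tra) == 1) {
    a <- tra$chrom[1]; pa <- tra$pos[1]
    b <- tra$chrom2[1]; pb <- tra$pos2[1]
    la <- spec$chrom_lengths[[a]]; lb <- spec$chrom_lengths[[b]]
    ders[[a]] <- data.frame(chrom = c(a, b), start = c(0, pb),
                            end = c(pa, lb), strand = "+",
                            ins_seq = NA_character_, stringsAsFactors = FALSE)
    ders[[b]] <- data.frame(chrom = c(b, a), start = c(0, pa),
                            end = c(pb, la), strand = "+",
                            ins_seq = NA_character_, stringsAsFactors = FALSE)
  }
  v2 <- v[v$type != "TRA", , drop = FALSE]
  if (nrow(v2)) {
    v2 <- v2[order(v2$chrom, -v2$pos), ]
    for (k in seq_len(nrow(v2))) ders <- .apply_variant(ders, v2[k, ])
  }
  ders
}

# Haplotype sequence + cumulative offsets for a derived chromosome.
.der_sequence <- function(segs, genome, snvs) {
  w <- segs$end - segs$start
  pieces <- character(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (is.na(segs$chrom[i])) {
      pieces[i] <- segs$ins_seq[i]
    } else {
      s <- substr(genome[[segs$chrom[i]]], segs$start[i] + 1, segs$end[i])
      pieces[i] <- if (segs$strand[i] == "-") .revcomp(s) else s
    }
  }
  seq <- paste(pieces, collapse = "")
  hs <- cumsum(c(0, w))[seq_len(nrow(segs))]
  if (nrow(snvs)) {
    for (k in seq_len(nrow(snvs))) {
      i <- which(!is.na(segs$chrom) & segs$chrom == snvs$chrom[k] &
                   segs$strand == "+" &
                   segs$start <= snvs$pos[k] & snvs$pos[k] < segs$end)
      if (length(i) == 0) next
      hp <- hs[i[1]] + (snvs$pos[k] - segs$start[i[1]])
      substr(seq, hp + 1, hp + 1) <- snvs$alt[k]
    }
  }
  list(seq = seq, hap_start = hs, segs = segs, len = nchar(seq))
}

# Map a read interval [s, e) on a derived chromosome to reference alignment
# parts. Returns a list of parts: chrom, ref0, ref1, strand, q0, q1, cigar
# ops (list of (op, len) in hap-forward query order). Colinear pieces are
# merged across small deletions (< 50, D op) and small insertions (< 50,
# I op); anything else breaks the read into separate parts (soft-clips or
# supplementary split alignments).
.map_interval <- function(der, s, e) {
  segs <- der$segs; hs <- der$hap_start
  he <- hs + (segs$end - segs$start)
  idx <- which(hs < e & he > s)
  pieces <- lapply(idx, function(i) {
    q0 <- max(s, hs[i]) - s; q1 <- min(e, he[i]) - s
    if (is.na(segs$chrom[i])) {
      return(list(ins = TRUE, q0 = q0, q1 = q1))
    }
    off0 <- max(s, hs[i]) - hs[i]; off1 <- min(e, he[i]) - hs[i]
    if (segs$strand[i] == "+") {
      list(ins = FALSE, q0 = q0, q1 = q1, chrom = segs$chrom[i],
           ref0 = segs$start[i] + off0, ref1 = segs$start[i] + off1,
           strand = "+")
    } else {
      list(ins = FALSE, q0 = q0, q1 = q1, chrom = segs$chrom[i],
           ref0 = segs$end[i] - off1, ref1 = segs$end[i] - off0,
           strand = "-")
    }
  })
  parts <- list()
  cur <- NULL
  pend_ins <- 0
  for (p in pieces) {
    if (p$ins) { pend_ins <- pend_ins + (p$q1 - p$q0); next }
    if (!is.null(cur)) {
      g <- if (cur$strand == "+") p$ref0 - cur$ref1 else cur$ref0 - p$ref1
      same <- p$chrom == cur$chrom && p$strand == cur$strand
      join_op <- NULL
      if (same && pend_ins == 0 && g == 0) join_op <- list()
      else if (same && pend_ins == 0 && g > 0 && g < 50) {
        join_op <- list(c("D", g))
      } else if (same && pend_ins > 0 && pend_ins < 50 && g == 0) {
        join_op <- list(c("I", pend_ins))
      }
      if (!is.null(join_op)) {
        cur$cigar <- c(cur$cigar, join_op, list(c("M", p$q1 - p$q0)))
        cur$q1 <- p$q1
        if (cur$strand == "+") cur$ref1 <- p$ref1 else cur$ref0 <- p$ref0
        pend_ins <- 0
        next
      }
      parts <- c(parts, list(cur))
    }
    pend_ins <- 0
    cur <- list(chrom = p$chrom, ref0 = p$ref0, ref1 = p$ref1,
                strand = p$strand, q0 = p$q0, q1 = p$q1,
                cigar = list(c("M", p$q1 - p$q0)))
  }
  if (!is.null(cur)) parts <- c(parts, list(cur))
  parts
}

.cigar_string <- function(ops) {
  op <- vapply(ops, `[`, character(1), 1)
  len <- as.numeric(vapply(ops, `[`, character(1), 2))
  # collapse adjacent identical operations
  keep <- c(TRUE, op[-1] != op[-length(op)])
  grp <- cumsum(keep)
  paste(paste0(tapply(len, grp, sum)[as.character(unique(grp))],
               op[keep]), collapse = "")
}

#' Simulate a paired-end library with planted variants
#'
#' Generates a random reference genome, plants the variants of `spec` on a
#' diploid sample, draws fragments with normal insert sizes from the variant
#' haplotypes, and synthesizes idealized alignments back to the reference:
#' reads crossing small indels get within-read I/D CIGAR operations, reads
#' crossing SV junctions get soft-clips and (for mapped splits of at least
#' 20 bases on each side) supplementary split alignments, and fragments
#' spanning SVs get discordant orientations and template lengths. Alignment
#' is synthesized directly rather than through an external aligner, so
#' mapping is idealized: no mismapping, constant MAPQ 60, constant base
#' quality Q30.
#'
#' @param spec a [sim_spec()].
#' @param out_dir output directory (created if needed).
#' @param basename stem for output files.
#' @return list with paths `fasta`, `bam`, `truth_vcf`, `truth_bed`,
#'   `spec_json`, and the truth variant data.frame `truth`.
#' @export
simulate_reads <- function(spec, out_dir, basename = "sim") {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  genome <- .random_genome(spec$chrom_lengths, spec$gc_range)
  spec$variants <- .fill_variant_alleles(spec$variants, genome)
  L <- spec$read_length

  recs <- list()
  for (hap in 1:2) {
    ders <- .build_derived(spec, hap)
    v <- spec$variants
    snvs <- v[v$type == "SNV" &
                (v$zygosity == "hom" | (hap == 1 & v$zygosity == "het")), ,
              drop = FALSE]
    for (dn in names(ders)) {
      der <- .der_sequence(ders[[dn]], genome, snvs)
      n_frag <- round(spec$coverage / 2 * der$len / (2 * L))
      if (n_frag == 0) next
      ins <- pmax(round(rnorm(n_frag, spec$insert_mean, spec$insert_sd)), L)
      ins <- pmin(ins, der$len)
      st <- floor(runif(n_frag, 0, der$len - ins + 1))
      if (spec$gc_bias != 0) {
        gcv <- cumsum(strsplit(der$seq, "")[[1]] %in% c("G", "C"))
        frac <- (gcv[st + ins] - ifelse(st > 0, gcv[st], 0)) / ins
        wts <- pmax(1 + spec$gc_bias * 2 * (frac - 0.5), 0.05)
        keep <- runif(n_frag) < wts / max(wts)
        ins <- ins[keep]; st <- st[keep]; n_frag <- sum(keep)
      }
      dup_of <- rep(NA_integer_, n_frag)
      if (spec$duplicate_fraction > 0 && n_frag > 0) {
        n_dup <- rbinom(1, n_frag, spec$duplicate_fraction)
        src <- sample.int(n_frag, n_dup, replace = TRUE)
        ins <- c(ins, ins[src]); st <- c(st, st[src])
        dup_of <- c(dup_of, src)
      }
      recs[[paste0(hap, dn)]] <- .frags_to_records(
        der, st, ins, spec, prefix = sprintf("h%d%s", hap, dn),
        dup_of = dup_of)
    }
  }
  sam <- do.call(rbind, recs)

  paths <- .write_sim_outputs(spec, genome, sam, out_dir, basename)
  paths
}

# Generate SAM record rows for fragments on one derived chromosome.
# Fast path (vectorised): reads fully inside one mapped segment get a pure-M
# alignment; only junction-spanning reads go through .map_interval.
.frags_to_records <- function(der, st, ins, spec, prefix, dup_of) {
  L <- spec$read_length
  n <- length(st)
  if (n == 0) return(NULL)
  qname <- sprintf("%s_f%06d", prefix, seq_len(n))
  qname[!is.na(dup_of)] <- sprintf("%s_f%06d_dup%d", prefix,
                                   dup_of[!is.na(dup_of)],
                                   seq_len(sum(!is.na(dup_of))))
  hs <- der$hap_start
  he <- hs + (der$segs$end - der$segs$start)

  r2 <- rep(c(FALSE, TRUE), each = n)
  s <- c(st, st + ins - L)
  e <- s + L
  n2 <- 2L * n
  qn <- rep(qname, 2)

  # primary alignment per read
  pchrom <- rep(NA_character_, n2)
  pref0 <- rep(NA_real_, n2); pref1 <- rep(NA_real_, n2)
  pstrand <- rep(NA_character_, n2)
  pq0 <- rep(0, n2); pq1 <- rep(L, n2)

  i0 <- findInterval(s, hs)
  inside <- i0 == findInterval(e - 0.5, hs) &
    !is.na(der$segs$chrom[i0]) & e <= he[i0]
  fi <- i0[inside]
  fwd <- der$segs$strand[fi] == "+"
  pchrom[inside] <- der$segs$chrom[fi]
  pstrand[inside] <- der$segs$strand[fi]
  pref0[inside] <- ifelse(fwd, der$segs$start[fi] + (s[inside] - hs[fi]),
                          der$segs$end[fi] - (e[inside] - hs[fi]))
  pref1[inside] <- pref0[inside] + L

  slow <- which(!inside)
  parts_per_read <- vector("list", n2)
  for (k in slow) {
    parts <- .map_interval(der, s[k], e[k])
    parts_per_read[[k]] <- parts
    if (length(parts)) {
      alen <- vapply(parts, function(p) p$q1 - p$q0, numeric(1))
      p <- parts[[which.max(alen)]]
      pchrom[k] <- p$chrom; pstrand[k] <- p$strand
      pref0[k] <- p$ref0; pref1[k] <- p$ref1
      pq0[k] <- p$q0; pq1[k] <- p$q1
    }
  }

  # sequencing errors on the hap-forward read sequence
  seq_fwd <- substring(der$seq, s + 1, e)
  nerr <- rbinom(n2, L, spec$error_rate)
  for (k in which(nerr > 0)) {
    pos <- sample.int(L, nerr[k])
    x <- seq_fwd[k]
    for (p in pos) {
      cur <- substr(x, p, p)
      substr(x, p, p) <- sample(setdiff(.BASES, cur), 1)
    }
    seq_fwd[k] <- x
  }

  # mate lookup: reads k and k + n (k <= n) are mates
  mk <- ifelse(r2, seq_len(n2) - n, seq_len(n2) + n)
  mmapped <- !is.na(pchrom[mk])
  self_mapped <- !is.na(pchrom)

  # stored (reference-forward) sequence; reverse flag relative to sequencing
  need_rc <- self_mapped & pstrand == "-"
  seq_out <- seq_fwd
  if (any(need_rc, na.rm = TRUE)) {
    seq_out[which(need_rc)] <- .revcomp(seq_fwd[which(need_rc)])
  }
  rev_self <- ifelse(r2, pstrand == "+", pstrand == "-")
  rev_mate <- ifelse(!r2, pstrand[mk] == "+", pstrand[mk] == "-")

  qual <- paste(rep("?", L), collapse = "")   # Q30

  # proper-pair flag as an aligner would set it: same chromosome, FR
  # orientation, insert within 4 SD of the library mean
  same_chrom0 <- self_mapped & mmapped & pchrom == pchrom[mk]
  fr <- same_chrom0 &
    ifelse(pref0 <= pref0[mk], !rev_self & rev_mate, rev_self & !rev_mate)
  span <- pmax(pref1, pref1[mk]) - pmin(pref0, pref0[mk])
  proper <- fr & abs(span - spec$insert_mean) <= 4 * spec$insert_sd &
    pq0 == 0 & pq1 == L & pq0[mk] == 0 & pq1[mk] == L
  proper[is.na(proper)] <- FALSE

  flag <- 1L + ifelse(proper, 2L, 0L) + ifelse(self_mapped, 0L, 4L) +
    ifelse(self_mapped & rev_self, 16L, 0L) +
    ifelse(mmapped, ifelse(rev_mate, 32L, 0L), 8L) +
    ifelse(r2, 128L, 64L)

  # CIGAR for primary records
  cig <- rep("*", n2)
  simple <- self_mapped & pq0 == 0 & pq1 == L & inside
  cig[simple] <- paste0(L, "M")
  for (k in which(self_mapped & !simple)) {
    parts <- parts_per_read[[k]]
    alen <- vapply(parts, function(p) p$q1 - p$q0, numeric(1))
    p <- parts[[which.max(alen)]]
    cig[k] <- .part_cigar(p, L)
  }

  rname <- ifelse(self_mapped, pchrom, pchrom[mk])
  pos1 <- ifelse(self_mapped, pref0, pref0[mk]) + 1
  mapq <- ifelse(self_mapped, 60L, 0L)
  rnext <- ifelse(!mmapped, "=",
                  ifelse(!self_mapped | pchrom[mk] == pchrom, "=", pchrom[mk]))
  pnext <- ifelse(mmapped, pref0[mk] + 1, pos1)
  same_chrom <- self_mapped & mmapped & pchrom == pchrom[mk]
  lo <- pmin(pref0, pref0[mk]); hi <- pmax(pref1, pref1[mk])
  tlen <- ifelse(same_chrom,
                 ifelse(pref0 < pref0[mk] | (pref0 == pref0[mk] & !r2),
                        hi - lo, lo - hi), 0)

  keep <- self_mapped | mmapped   # drop pairs with both reads unmapped
  df <- data.frame(qname = qn, flag = flag, rname = rname, pos = pos1,
                   mapq = mapq, cigar = cig, rnext = rnext, pnext = pnext,
                   tlen = tlen, seq = seq_out, qual = qual, opt = "",
                   stringsAsFactors = FALSE)

  # supplementary records + SA tags for split reads (each split >= 20 bases)
  sa_entry <- function(pt, is_r2) {
    rev_pt <- if (is_r2) pt$strand == "+" else pt$strand == "-"
    sprintf("%s,%d,%s,%s,60,0;", pt$chrom, as.integer(pt$ref0 + 1),
            if (rev_pt) "-" else "+", .part_cigar(pt, L))
  }
  supp <- list()
  for (k in slow) {
    parts <- parts_per_read[[k]]
    if (length(parts) < 2 || !self_mapped[k]) next
    if (pq1[k] - pq0[k] < 20) next
    alen <- vapply(parts, function(p) p$q1 - p$q0, numeric(1))
    pidx <- which.max(alen)
    qual_j <- which(alen >= 20)
    if (length(qual_j) < 2) next
    prim_pt <- parts[[pidx]]
    df$opt[k] <- paste0("SA:Z:", paste(vapply(
      parts[setdiff(qual_j, pidx)], sa_entry, character(1), r2[k]),
      collapse = ""))
    for (j in setdiff(qual_j, pidx)) {
      pt <- parts[[j]]
      rev_pt <- if (r2[k]) pt$strand == "+" else pt$strand == "-"
      fl <- 1L + 2048L + (if (rev_pt) 16L else 0L) +
        (if (r2[k]) 128L else 64L) +
        (if (mmapped[k]) (if (rev_mate[k]) 32L else 0L) else 8L)
      sq <- if (pt$strand == "-") .revcomp(seq_fwd[k]) else seq_fwd[k]
      supp[[length(supp) + 1]] <- data.frame(
        qname = qn[k], flag = fl, rname = pt$chrom, pos = pt$ref0 + 1,
        mapq = 60L, cigar = .part_cigar(pt, L),
        rnext = if (!mmapped[k] || pchrom[mk[k]] == pt$chrom) "=" else pchrom[mk[k]],
        pnext = if (mmapped[k]) pref0[mk[k]] + 1 else pt$ref0 + 1,
        tlen = 0, seq = sq, qual = qual,
        opt = paste0("SA:Z:", sa_entry(prim_pt, r2[k])),
        stringsAsFactors = FALSE)
    }
  }
  df <- df[keep, ]
  if (length(supp)) df <- rbind(df, do.call(rbind, supp))
  df
}

# CIGAR string (reference-ascending) for one alignment part of a read of
# length L: soft-clips around the part's merged M/D/I operations.
.part_cigar <- function(pt, L) {
  ops <- pt$cigar
  lead <- pt$q0; trail <- L - pt$q1
  if (pt$strand == "-") {
    ops <- rev(ops); tmp <- lead; lead <- trail; trail <- tmp
  }
  paste0(if (lead > 0) paste0(lead, "S"), .cigar_string(ops),
         if (trail > 0) paste0(trail, "S"))
}

.write_sim_outputs <- function(spec, genome, sam, out_dir, basename) {
  fa <- file.path(out_dir, paste0(basename, ".fa"))
  seqs <- Biostrings::DNAStringSet(unlist(genome))
  names(seqs) <- names(genome)
  Biostrings::writeXStringSet(seqs, fa)
  Rsamtools::indexFa(fa)

  sam_path <- file.path(out_dir, paste0(basename, ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(spec$chrom_lengths),
                   as.integer(spec$chrom_lengths)))
  for (col in c("flag", "pos", "mapq", "pnext", "tlen")) {
    sam[[col]] <- as.integer(sam[[col]])
  }
  ord <- order(match(sam$rname, names(spec$chrom_lengths)),
               as.integer(sam$pos), sam$qname)
  sam <- sam[ord, ]
  opt <- sam$opt
  sam$opt <- NULL
  body <- do.call(paste, c(as.list(sam), sep = "\t"))
  body <- ifelse(nzchar(opt), paste(body, opt, sep = "\t"), body)
  writeLines(c(hdr, body), sam_path)
  bam0 <- Rsamtools::asBam(sam_path, file.path(out_dir, paste0(basename, "_u")),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(out_dir, basename))
  Rsamtools::indexBam(bam)
  unlink(c(bam0, sam_path))

  truth <- spec$variants
  tv <- file.path(out_dir, paste0(basename, ".truth.vcf"))
  write_truth_vcf(truth, genome, spec$chrom_lengths, tv)
  tb <- file.path(out_dir, paste0(basename, ".truth.bed"))
  bed <- data.frame(chrom = truth$chrom, start = as.integer(truth$pos),
                    end = as.integer(truth$pos + ifelse(
                      truth$type %in% c("DEL", "DUP", "INV"), truth$len, 1)),
                    name = truth$type)
  write.table(bed, tb, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  sj <- file.path(out_dir, paste0(basename, ".spec.json"))
  jsonlite::write_json(unclass(spec), sj, auto_unbox = TRUE, digits = NA)
  list(fasta = fa, bam = bam, truth_vcf = tv, truth_bed = tb,
       spec_json = sj, truth = truth)
}
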