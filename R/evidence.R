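#' Scan options
#'
#' Tunable thresholds of the evidence pass. `mapq_threshold` is the phred
#' mapping-quality threshold `m` that defines the per-read mismapping
#' probability `10^(-m/10)` (default 20, i.e. p = 0.01); `alpha` is the call
#' threshold on the binomial mismapping probability; `clip_min` and
#' `split_min` are the minimum soft-clip (5) and mapped split-segment (20)
#' sizes that may contribute breakpoint evidence; reads with MAPQ below
#' `candidate_mapq_min` count toward depth but produce no candidates.
#'
#' @param alpha call threshold on `p_bc`.
#' @param mapq_threshold phred threshold `m` for the mismapping model.
#' @param baseq_min per-base quality for a read base to count as SNV evidence.
#' @param snv_baseq_min minimum mean base quality of alt reads (`Q_min`).
#' @param snv_min_alt minimum alt read count (`k_min`).
#' @param clip_min minimum soft-clip length.
#' @param split_min minimum mapped length of each split segment.
#' @param candidate_mapq_min minimum MAPQ for breakpoint/SNV evidence.
#' @param dup_filter filter duplicate pairs inline.
#' @param n_max largest depth precomputed in the significance table.
#' @param indel_sv_boundary events shorter than this are indels (50).
#' @param cnv_window,cnv_min_windows,cnv_low,cnv_high windowed read-depth
#'   CNV parameters (window width in bases, minimum run length, depth
#'   thresholds as fractions of the genome median).
#' @return list of options.
#' @export
scan_options <- function(alpha = 1e-5, mapq_threshold = 20, baseq_min = 13,
                         snv_baseq_min = 20, snv_min_alt = 3,
                         clip_min = 5, split_min = 20,
                         candidate_mapq_min = 1, dup_filter = TRUE,
                         n_max = 1000, indel_sv_boundary = 50,
                         cnv_window = 100, cnv_min_windows = 5,
                         cnv_low = 0.6, cnv_high = 1.4) {
  list(alpha = alpha, mapq_threshold = mapq_threshold, baseq_min = baseq_min,
       snv_baseq_min = snv_baseq_min, snv_min_alt = snv_min_alt,
       clip_min = clip_min, split_min = split_min,
       candidate_mapq_min = candidate_mapq_min, dup_filter = dup_filter,
       n_max = n_max, indel_sv_boundary = indel_sv_boundary,
       cnv_window = cnv_window, cnv_min_windows = cnv_min_windows,
       cnv_low = cnv_low, cnv_high = cnv_high)
}

.cig_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

.clip_left <- function(cigar) {
  out <- integer(length(cigar))
  hit <- grepl("^[0-9]+S", cigar)
  out[hit] <- as.integer(sub("^([0-9]+)S.*", "\\1", cigar[hit]))
  out
}

.clip_right <- function(cigar) {
  m <- regmatches(cigar, regexpr("[0-9]+S$", cigar))
  out <- integer(length(cigar))
  hit <- grepl("[0-9]+S$", cigar)
  out[hit] <- as.integer(sub("S$", "", m))
  out
}

#' Single-pass evidence scan of one chromosome
#'
#' Reads all alignments on `chrom` once and accumulates (i) physical depth:
#' coverage of aligned read spans, unsequenced inter-mate gaps of concordant
#' pairs and potential-breakpoint extents of discordant pairs and clipped
#' reads; (ii) per-base mismatch (SNV) evidence; (iii) weighted breakpoint
#' candidates from CIGAR indels, soft-clips, split alignments and discordant
#' pairs, with clip anchoring (candidates at a clip/split boundary keep full
#' weight, other candidates in the same read window are half-weighted).
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param chrom chromosome name.
#' @param model an [insert_model()], or `NULL` for single-end mode.
#' @param ref_seq chromosome reference sequence as a character string.
#' @param options a [scan_options()] list.
#' @return list with `depth` (integer Rle over the chromosome), `snv`
#'   (per-(position, alt) evidence), `cands` (breakpoint candidate table),
#'   `boundaries` (clip/split boundary positions, 0-based), and `stats`.
#' @export
scan_chromosome <- function(bam, chrom, model, ref_seq,
                            options = scan_options()) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  if (!chrom %in% names(hdr$targets)) {
    stop("unknown chromosome: ", chrom)
  }
  so <- unname(grep("^SO:", unlist(hdr$text["@HD"]), value = TRUE))
  if (length(so) && !any(so == "SO:coordinate")) {
    stop("BAM is not coordinate-sorted")
  }
  chromlen <- unname(hdr$targets[[chrom]])
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = c("qname", "flag", "strand", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq", "qual"),
    tag = "SA",
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(1, chromlen)))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$pos)
  stats <- list(n_records = n, n_duplicates = 0L, n_unmapped_mate = 0L)
  if (n == 0) {
    return(list(depth = S4Vectors::Rle(0L, chromlen),
                snv = .empty_snv(), cands = .empty_cands(),
                boundaries = integer(0), stats = stats))
  }

  flag <- x$flag
  supp <- bitwAnd(flag, 2048L) > 0
  pos0 <- x$pos - 1L
  rw <- .cig_ref_width(x$cigar)
  end0 <- pos0 + rw
  strand <- ifelse(bitwAnd(flag, 16L) > 0, "-", "+")
  paired <- bitwAnd(flag, 1L) > 0
  mate_unmapped <- paired & bitwAnd(flag, 8L) > 0
  mate_strand <- ifelse(bitwAnd(flag, 32L) > 0, "-", "+")
  mate_mapped <- paired & !mate_unmapped
  mchrom <- as.character(x$mrnm)
  mpos0 <- x$mpos - 1L
  lclip <- .clip_left(x$cigar)
  rclip <- .clip_right(x$cigar)

  # ---- inline duplicate filtering (pair level) ------------------------------
  drop <- rep(FALSE, n)
  if (isTRUE(options$dup_filter)) {
    prim <- !supp
    ext_adj <- ifelse(strand == "+", pos0 - lclip, end0 + rclip)
    canon <- prim & (
      (!mate_mapped) |
      (mate_mapped & mchrom != chrom) |
      (mate_mapped & mchrom == chrom &
         (pos0 < mpos0 | (pos0 == mpos0 & bitwAnd(flag, 64L) > 0))))
    idx <- which(canon)
    if (length(idx)) {
      ptab <- data.frame(
        chrom1 = chrom, ext1 = ext_adj[idx], strand1 = strand[idx],
        chrom2 = ifelse(mate_mapped[idx], mchrom[idx], NA_character_),
        ext2 = ifelse(mate_mapped[idx], mpos0[idx], NA_real_),
        strand2 = ifelse(mate_mapped[idx], mate_strand[idx], NA_character_),
        mapq = x$mapq[idx], stringsAsFactors = FALSE)
      dd <- dedupe(ptab, enabled = TRUE)
      stats$n_duplicates <- dd$n_duplicates
      bad_qnames <- x$qname[idx[!dd$keep]]
      drop <- x$qname %in% bad_qnames
    }
  }
  keep <- which(!drop)
  if (length(keep) < n) {
    for (nm in c("qname", "flag", "pos", "mapq", "cigar", "mrnm", "mpos",
                 "isize")) x[[nm]] <- x[[nm]][keep]
    x$seq <- x$seq[keep]; x$qual <- x$qual[keep]; x$strand <- x$strand[keep]
    x$tag$SA <- x$tag$SA[keep]
    flag <- flag[keep]; supp <- supp[keep]; pos0 <- pos0[keep]
    rw <- rw[keep]; end0 <- end0[keep]; strand <- strand[keep]
    paired <- paired[keep]; mate_unmapped <- mate_unmapped[keep]
    mate_strand <- mate_strand[keep]; mate_mapped <- mate_mapped[keep]
    mchrom <- mchrom[keep]; mpos0 <- mpos0[keep]
    lclip <- lclip[keep]; rclip <- rclip[keep]
    n <- length(keep)
  }
  stats$n_unmapped_mate <- sum(mate_unmapped & !supp)

  prim <- which(!supp)
  can_ev <- x$mapq >= options$candidate_mapq_min   # MAPQ gate for evidence

  # ---- clip boundaries ------------------------------------------------------
  # clip boundaries from primaries and supplementaries: each mapped segment
  # of a split read marks its own junction edge
  bl <- which(lclip >= options$clip_min & can_ev)
  br <- which(rclip >= options$clip_min & can_ev)
  boundary_bases <- c(pos0[bl], end0[br])   # one per clipped segment
  boundaries <- sort(unique(boundary_bases))

  # ---- CIGAR indel candidates ----------------------------------------------
  cig_cands <- candidates_from_cigar(x$cigar[prim], pos0[prim],
                                     x$qname[prim], can_ev[prim], chrom)

  # ---- split-read candidates (from SA tags) --------------------------------
  split_cands <- .split_candidates(x, pos0, end0, strand, lclip, rclip,
                                   can_ev, chrom, options)

  # ---- discordant-pair windows ---------------------------------------------
  disc <- .discordant_windows(x, prim, pos0, end0, strand, mate_strand,
                              mate_mapped, mate_unmapped, mchrom, mpos0,
                              can_ev, chrom, chromlen, model, options)
  win_cands <- apply_clip_anchoring(disc$cands, boundaries)

  cands <- rbind(cig_cands, split_cands, win_cands)

  # ---- physical depth -------------------------------------------------------
  # aligned spans of all mapped records; a split read's supplementary
  # segment covers reference its primary does not
  spans <- IRanges::IRanges(start = pos0 + 1L, end = end0)
  gaps <- disc$conc_gaps
  extents <- IRanges::IRanges(
    start = c(disc$win_lo + 1L, boundary_bases + 1L),
    end = c(disc$win_hi, boundary_bases + 1L))
  all_iv <- c(spans, gaps, extents)
  all_iv <- IRanges::restrict(all_iv, start = 1L, end = chromlen)
  depth <- IRanges::coverage(all_iv, width = chromlen)

  # ---- SNV evidence ---------------------------------------------------------
  snv <- .snv_evidence(x, prim, pos0, ref_seq, can_ev, options)

  stats$class_counts <- disc$class_counts
  list(depth = depth, snv = snv, cands = cands, boundaries = boundaries,
       stats = stats)
}

.empty_cands <- function() {
  data.frame(chrom = character(0), pos = numeric(0), side = character(0),
             type = character(0), length = numeric(0), weight = numeric(0),
             read = character(0), source = character(0),
             mate_chrom = character(0), M = numeric(0),
             window = integer(0), stringsAsFactors = FALSE)
}

.empty_snv <- function() {
  data.frame(pos = numeric(0), ref = character(0), alt = character(0),
             count = numeric(0), mean_baseq = numeric(0),
             mean_mapq = numeric(0), stringsAsFactors = FALSE)
}

#' Breakpoint candidates from CIGAR indel operations
#'
#' A deletion of length k at reference position p yields one start candidate
#' at p and one end candidate at p + k (weight 1, type DEL, length k); an
#' insertion yields a single INS candidate at the insertion point with the
#' inserted length.
#'
#' @param cigar,pos0,qname parallel vectors of primary-alignment CIGARs,
#'   0-based positions and read names.
#' @param eligible logical; reads failing the MAPQ gate contribute nothing.
#' @param chrom chromosome name.
#' @return candidate data.frame (see [scan_chromosome()]).
#' @export
candidates_from_cigar <- function(cigar, pos0, qname, eligible, chrom) {
  has <- which(grepl("[DI]", cigar) & eligible)
  if (length(has) == 0) return(.empty_cands())
  rngD <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar[has], pos = pos0[has] + 1L, ops = "D")
  rngI <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar[has], pos = pos0[has] + 1L, ops = "I")
  qI <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar[has], ops = "I")
  out <- list()
  nD <- S4Vectors::elementNROWS(rngD)
  if (sum(nD)) {
    ur <- unlist(rngD)
    rd <- rep(qname[has], nD)
    ds <- IRanges::start(ur) - 1L   # first deleted base, 0-based
    de <- IRanges::end(ur)          # first base after the deletion
    k <- IRanges::width(ur)
    out$D <- data.frame(
      chrom = chrom, pos = c(ds, de), side = rep(c("start", "end"), each = length(ds)),
      type = "DEL", length = c(k, k), weight = 1,
      read = c(rd, rd), source = "cigar", mate_chrom = NA_character_,
      M = NA_real_, window = NA_integer_, stringsAsFactors = FALSE)
  }
  nI <- S4Vectors::elementNROWS(rngI)
  if (sum(nI)) {
    ur <- unlist(rngI)
    ql <- IRanges::width(unlist(qI))
    rd <- rep(qname[has], nI)
    ip <- IRanges::start(ur) - 1L   # insertion point (before this base)
    out$I <- data.frame(
      chrom = chrom, pos = ip, side = "start", type = "INS",
      length = ql, weight = 1, read = rd, source = "cigar",
      mate_chrom = NA_character_, M = NA_real_, window = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(.empty_cands())
  do.call(rbind, out)
}

# Split-read candidates from SA tags. Each record (primary or supplementary)
# carrying an SA tag describes a split read; the partner segment may sit on
# another chromosome, so every record emits the candidates that fall on the
# chromosome being scanned. Both mapped segments must be >= split_min bases.
# Junction edges are the query-inner ref edges of the two segments ordered
# along the read; candidates from a read's two records carry the same read
# id, so clusters never count a split read twice.
.split_candidates <- function(x, pos0, end0, strand, lclip, rclip,
                              can_ev, chrom, options) {
  sa <- x$tag$SA
  has <- which(!is.na(sa) & nzchar(sa) & can_ev)
  if (length(has) == 0) return(.empty_cands())
  mate_bit <- bitwAnd(x$flag, 192L)          # first/second in pair
  rows <- list()
  for (k in has) {
    self_alen <- end0[k] - pos0[k]
    if (self_alen < options$split_min) next
    pa <- strsplit(strsplit(sa[k], ";", fixed = TRUE)[[1]][1], ",")[[1]]
    if (length(pa) < 4) next
    p_chrom <- pa[1]; p_pos0 <- as.numeric(pa[2]) - 1
    p_strand <- pa[3]; p_cig <- pa[4]
    p_rw <- .cig_ref_width(p_cig)
    p_l <- .clip_left(p_cig); p_r <- .clip_right(p_cig)
    p_alen <- GenomicAlignments::cigarWidthAlongQuerySpace(p_cig) - p_l - p_r
    if (p_alen < options$split_min) next
    # work in the frame of this record's stored orientation
    same_o <- p_strand == strand[k]
    qF_self <- lclip[k]
    qF_part <- if (same_o) p_l else p_r
    dir_part <- if (same_o) "+" else "-"
    p_end0 <- p_pos0 + p_rw
    # (edge, side) of self and partner given segment order along the read
    self_first <- qF_self <= qF_part
    edge_of <- function(first, dir, a0, a1) {
      # query-late edge for the first segment, query-early for the second
      if (first) { if (dir == "+") a1 else a0 }
      else { if (dir == "+") a0 else a1 }
    }
    J_self <- edge_of(self_first, "+", pos0[k], end0[k])
    J_part <- edge_of(!self_first, dir_part, p_pos0, p_end0)
    rdid <- paste0(x$qname[k], "/", mate_bit[k])
    if (p_chrom != chrom) {
      # translocation: emit this chromosome's breakend only
      side <- if (self_first) "start" else "end"
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, pos = J_self, side = side, type = "TRA",
        length = NA_real_, weight = 1, read = rdid, source = "split",
        mate_chrom = p_chrom, M = J_part, window = NA_integer_,
        stringsAsFactors = FALSE)
    } else if (dir_part == "-") {
      lo <- min(J_self, J_part); hi <- max(J_self, J_part)
      if (hi > lo) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = c(lo, hi), side = c("start", "end"),
          type = "INV", length = hi - lo, weight = 1, read = rdid,
          source = "split", mate_chrom = NA_character_, M = NA_real_,
          window = NA_integer_, stringsAsFactors = FALSE)
      }
    } else {
      J1 <- if (self_first) J_self else J_part
      J2 <- if (self_first) J_part else J_self
      if (J2 > J1) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = c(J1, J2), side = c("start", "end"),
          type = "DEL", length = J2 - J1, weight = 1, read = rdid,
          source = "split", mate_chrom = NA_character_, M = NA_real_,
          window = NA_integer_, stringsAsFactors = FALSE)
      } else if (J2 < J1) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = c(J2, J1), side = c("start", "end"),
          type = "DUP", length = J1 - J2, weight = 1, read = rdid,
          source = "split", mate_chrom = NA_character_, M = NA_real_,
          window = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(.empty_cands())
  do.call(rbind, rows)
}

#' Breakpoint candidate windows from a discordant pair
#'
#' For a discordant pair the exact breakpoint is unknown; a candidate is
#' recorded at every reference base at which a breakpoint would let the
#' fragment form a concordant insert, giving a window of width
#' `i_max - i_min` adjacent to the read (after a forward read's end, before
#' a reverse read's start, clamped at the mate). All candidates of a read
#' carry the same implied length: `insert - i_median` for deletions,
#' `i_median - insert` for small-insert (insertion) pairs,
#' `insert + i_median - 2 L_r` for tandem duplications, and the mate start
#' minus the read start for inversions.
#'
#' @param geom data.frame with one row per generating read: `pos0`, `end0`,
#'   `strand`, `mpos0`, `mate_strand`, `insert`, `class` (a
#'   [classify_pair()] label), `qname`.
#' @param model an [insert_model()].
#' @param chrom,chromlen chromosome name and length.
#' @return candidate data.frame with one row per (read, reference base).
#' @export
candidates_from_discordant_pair <- function(geom, model, chrom, chromlen) {
  W <- model$i_max - model$i_min
  Lr <- model$read_length
  cl <- as.character(geom$class)

  # up to two windows per generating read; built columnwise then expanded
  w <- list(lo = numeric(0), hi = numeric(0), side = character(0),
            type = character(0), len = numeric(0), read = character(0),
            mchrom = character(0), r_inner = numeric(0),
            mpos0 = numeric(0), mstrand = character(0))
  push <- function(lo, hi, side, type, len, read, mchrom = NA_character_,
                   r_inner = NA_real_, mpos0 = NA_real_,
                   mstrand = NA_character_) {
    n <- length(lo)
    w$lo <<- c(w$lo, lo); w$hi <<- c(w$hi, hi)
    w$side <<- c(w$side, rep_len(side, n)); w$type <<- c(w$type, rep_len(type, n))
    w$len <<- c(w$len, rep_len(len, n)); w$read <<- c(w$read, rep_len(read, n))
    w$mchrom <<- c(w$mchrom, rep_len(mchrom, n))
    w$r_inner <<- c(w$r_inner, rep_len(r_inner, n))
    w$mpos0 <<- c(w$mpos0, rep_len(mpos0, n))
    w$mstrand <<- c(w$mstrand, rep_len(mstrand, n))
  }
  i <- which(cl == "discordant_deletion")
  if (length(i)) {
    len <- geom$insert[i] - model$i_median
    push(geom$end0[i], pmin(geom$end0[i] + W, geom$mpos0[i]),
         "start", "DEL", len, geom$qname[i])
    push(pmax(geom$mpos0[i] - W, geom$end0[i]), geom$mpos0[i],
         "end", "DEL", len, geom$qname[i])
  }
  i <- which(cl == "discordant_insertion")
  if (length(i)) {
    push(geom$end0[i], geom$end0[i] + W, "start", "INS",
         model$i_median - geom$insert[i], geom$qname[i])
  }
  i <- which(cl == "discordant_duplication")
  if (length(i)) {
    len <- geom$insert[i] + model$i_median - 2 * Lr
    ok <- len > 0
    push(geom$pos0[i][ok] - W, geom$pos0[i][ok], "start", "DUP", len[ok],
         geom$qname[i][ok])
    push(geom$mpos0[i][ok] + Lr, geom$mpos0[i][ok] + Lr + W, "end", "DUP",
         len[ok], geom$qname[i][ok])
  }
  i <- which(cl == "discordant_inversion")
  if (length(i)) {
    len <- geom$mpos0[i] - geom$pos0[i]
    ff <- geom$strand[i] == "+"
    ok <- len > 0
    ii <- i[ok & ff]
    if (length(ii)) {  # FF: windows right of both reads' ends
      lenf <- geom$mpos0[ii] - geom$pos0[ii]
      push(geom$end0[ii], geom$end0[ii] + W, "start", "INV", lenf,
           geom$qname[ii])
      push(geom$mpos0[ii] + Lr, geom$mpos0[ii] + Lr + W, "end", "INV", lenf,
           geom$qname[ii])
    }
    ii <- i[ok & !ff]
    if (length(ii)) {  # RR: windows left of both reads' starts
      lenr <- geom$mpos0[ii] - geom$pos0[ii]
      push(geom$pos0[ii] - W, geom$pos0[ii], "start", "INV", lenr,
           geom$qname[ii])
      push(geom$mpos0[ii] - W, geom$mpos0[ii], "end", "INV", lenr,
           geom$qname[ii])
    }
  }
  i <- which(cl == "discordant_translocation")
  if (length(i)) {
    fwd <- geom$strand[i] == "+"
    r_inner <- ifelse(fwd, geom$end0[i], geom$pos0[i])
    push(ifelse(fwd, geom$end0[i], geom$pos0[i] - W),
         ifelse(fwd, geom$end0[i] + W, geom$pos0[i]),
         ifelse(fwd, "start", "end"), "TRA", NA_real_, geom$qname[i],
         mchrom = geom$mchrom[i], r_inner = r_inner,
         mpos0 = geom$mpos0[i], mstrand = geom$mate_strand[i])
  }

  w$lo <- pmax(w$lo, 0); w$hi <- pmin(w$hi, chromlen)
  ok <- w$hi > w$lo
  for (nm in names(w)) w[[nm]] <- w[[nm]][ok]
  if (length(w$lo) == 0) return(.empty_cands())
  nw <- length(w$lo)
  wid <- w$hi - w$lo
  rep_i <- rep.int(seq_len(nw), wid)
  pos <- sequence(wid, from = w$lo)
  out <- data.frame(
    chrom = chrom, pos = pos, side = w$side[rep_i], type = w$type[rep_i],
    length = w$len[rep_i], weight = 1, read = w$read[rep_i],
    source = "window", mate_chrom = w$mchrom[rep_i], M = NA_real_,
    window = rep_i, stringsAsFactors = FALSE)
  tra <- out$type == "TRA"
  if (any(tra)) {
    # implied mate-junction position assuming a median-insert fragment
    d <- abs(out$pos[tra] - w$r_inner[rep_i][tra])
    r <- model$i_median - 2 * Lr - d
    out$M[tra] <- ifelse(w$mstrand[rep_i][tra] == "+",
                         w$mpos0[rep_i][tra] + Lr + r,
                         w$mpos0[rep_i][tra] - r)
  }
  out
}

# Build discordant windows + concordant gap intervals from scan vectors.
.discordant_windows <- function(x, prim, pos0, end0, strand, mate_strand,
                                mate_mapped, mate_unmapped, mchrom, mpos0,
                                can_ev, chrom, chromlen, model, options) {
  p <- prim
  res <- list(cands = .empty_cands(),
              conc_gaps = IRanges::IRanges(),
              win_lo = integer(0), win_hi = integer(0),
              class_counts = table(character(0)))
  if (is.null(model) || length(p) == 0) return(res)
  pairs <- data.frame(
    chrom1 = chrom, pos1 = pos0[p], strand1 = strand[p],
    chrom2 = mchrom[p], pos2 = mpos0[p], strand2 = mate_strand[p],
    insert = abs(x$isize[p]),
    mate_mapped = mate_mapped[p], stringsAsFactors = FALSE)
  pairs$insert[is.na(pairs$insert)] <- 0
  pairs$chrom2[!pairs$mate_mapped] <- chrom
  pairs$pos2[!pairs$mate_mapped] <- pairs$pos1[!pairs$mate_mapped]
  pairs$strand2[!pairs$mate_mapped] <- "+"
  unpaired <- !(bitwAnd(x$flag[p], 1L) > 0)
  cls <- classify_pair(pairs, model)
  cls[unpaired] <- NA
  res$class_counts <- table(cls)

  # concordant inter-mate gaps, one per pair (leftmost record)
  conc <- which(!is.na(cls) & cls == "concordant" &
                  (pos0[p] < mpos0[p] |
                     (pos0[p] == mpos0[p] & bitwAnd(x$flag[p], 64L) > 0)))
  if (length(conc)) {
    gs <- end0[p][conc] + 1L
    ge <- mpos0[p][conc]
    ok <- ge >= gs
    res$conc_gaps <- IRanges::IRanges(start = gs[ok], end = ge[ok])
  }

  # candidate-generating discordant reads
  left <- pos0[p] < mpos0[p] | (pos0[p] == mpos0[p] & bitwAnd(x$flag[p], 64L) > 0)
  gen_same <- !is.na(cls) & can_ev[p] &
    cls %in% c("discordant_deletion", "discordant_insertion",
               "discordant_duplication", "discordant_inversion") & left
  gen_tra <- !is.na(cls) & can_ev[p] & cls == "discordant_translocation"
  gi <- which(gen_same | gen_tra)
  if (length(gi)) {
    geom <- data.frame(
      pos0 = pos0[p][gi], end0 = end0[p][gi], strand = strand[p][gi],
      mpos0 = mpos0[p][gi], mate_strand = mate_strand[p][gi],
      mchrom = mchrom[p][gi], insert = abs(x$isize[p][gi]),
      class = as.character(cls[gi]), qname = x$qname[p][gi],
      stringsAsFactors = FALSE)
    cands <- candidates_from_discordant_pair(geom, model, chrom, chromlen)
    res$cands <- cands
    if (nrow(cands)) {
      agg_lo <- tapply(cands$pos, cands$window, min)
      agg_hi <- tapply(cands$pos, cands$window, max)
      res$win_lo <- as.integer(agg_lo)
      res$win_hi <- as.integer(agg_hi) + 1L
    }
  }
  res
}

#' Reweight discordant-window candidates near clip/split boundaries
#'
#' When at least one qualifying soft-clip or split-read boundary falls inside
#' a candidate window, candidates at a boundary base keep weight 1.0 and all
#' other candidates of that window are half-weighted; windows without a
#' boundary are left unchanged. This gives base-resolution breakpoints while
#' a single aberrant clipped read cannot dominate.
#'
#' @param cands window candidate table (with a `window` id column).
#' @param boundaries sorted vector of 0-based clip/split boundary positions.
#' @return the candidate table with adjusted weights.
#' @export
apply_clip_anchoring <- function(cands, boundaries) {
  if (nrow(cands) == 0 || length(boundaries) == 0) return(cands)
  is_b <- cands$pos %in% boundaries
  has_b <- stats::ave(as.numeric(is_b), cands$window, FUN = max) > 0
  cands$weight <- ifelse(has_b & !is_b, 0.5, cands$weight)
  cands
}

# ---- SNV evidence ----------------------------------------------------------

# Mismatch collection. Fast path: alignments whose CIGAR is a single M run
# (with optional soft-clips) are compared to the reference in bulk via byte
# comparison; alignments with I/D are walked per M block.
.snv_evidence <- function(x, prim, pos0, ref_seq, can_ev, options) {
  use <- prim[can_ev[prim]]
  if (length(use) == 0) return(.empty_snv())
  cig <- x$cigar[use]
  simple <- grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", cig)
  recs <- list()
  if (any(simple)) {
    i <- use[simple]
    recs$fast <- .mismatches_bulk(x, i, pos0[i], ref_seq, options)
  }
  if (any(!simple)) {
    i <- use[!simple]
    recs$slow <- .mismatches_blocks(x, i, pos0[i], ref_seq, options)
  }
  mm <- do.call(rbind, recs)
  if (is.null(mm) || nrow(mm) == 0) return(.empty_snv())
  key <- paste(mm$pos, mm$alt)
  agg <- data.frame(
    pos = tapply(mm$pos, key, `[`, 1),
    ref = tapply(mm$ref, key, `[`, 1),
    alt = tapply(mm$alt, key, `[`, 1),
    count = as.numeric(tapply(rep(1, nrow(mm)), key, sum)),
    mean_baseq = as.numeric(tapply(mm$baseq, key, mean)),
    mean_mapq = as.numeric(tapply(mm$mapq, key, mean)),
    stringsAsFactors = FALSE)
  agg$pos <- as.numeric(agg$pos)
  rownames(agg) <- NULL
  agg[order(agg$pos), ]
}

.DNA_LETTER <- local({
  m <- rep(NA_character_, 16)
  m[c(1, 2, 4, 8)] <- c("A", "C", "G", "T")
  m
})

.mismatches_bulk <- function(x, idx, p0, ref_seq, options) {
  cig <- x$cigar[idx]
  lc <- .clip_left(cig)
  m <- as.integer(sub(".*?([0-9]+)M.*", "\\1", cig))
  rd <- Biostrings::subseq(x$seq[idx], start = lc + 1L, width = m)
  ql <- Biostrings::subseq(x$qual[idx], start = lc + 1L, width = m)
  refs <- Biostrings::DNAStringSet(
    Biostrings::DNAString(ref_seq), start = p0 + 1L, width = m)
  rb <- as.integer(BiocGenerics::unlist(rd))
  fb <- as.integer(BiocGenerics::unlist(refs))
  qb <- as.integer(BiocGenerics::unlist(Biostrings::BStringSet(ql))) - 33L
  mis <- which(rb != fb)   # rare; filter the small subset only
  mis <- mis[rb[mis] %in% c(1L, 2L, 4L, 8L) & fb[mis] %in% c(1L, 2L, 4L, 8L) &
               qb[mis] >= options$baseq_min]
  diffidx <- mis
  if (length(diffidx) == 0) return(NULL)
  cw <- cumsum(c(0L, m))
  rec <- findInterval(diffidx - 1L, cw[-length(cw)], rightmost.closed = FALSE)
  off <- diffidx - 1L - cw[rec]
  data.frame(pos = p0[rec] + off,
             ref = .DNA_LETTER[fb[diffidx]],
             alt = .DNA_LETTER[rb[diffidx]],
             baseq = qb[diffidx],
             mapq = x$mapq[idx][rec], stringsAsFactors = FALSE)
}

.mismatches_blocks <- function(x, idx, p0, ref_seq, options) {
  cig <- x$cigar[idx]
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, pos = p0 + 1L,
                                                          ops = "M")
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "M")
  out <- list()
  for (k in seq_along(idx)) {
    rs <- IRanges::start(rr[[k]]); re <- IRanges::end(rr[[k]])
    qs <- IRanges::start(qr[[k]]); qe <- IRanges::end(qr[[k]])
    seqk <- as.character(x$seq[idx[k]])
    qualk <- as.integer(charToRaw(as.character(x$qual[idx[k]]))) - 33L
    for (b in seq_along(rs)) {
      a <- strsplit(substr(seqk, qs[b], qe[b]), "")[[1]]
      r <- strsplit(substr(ref_seq, rs[b], re[b]), "")[[1]]
      d <- which(a != r & a %in% .BASES & r %in% .BASES)
      if (length(d) == 0) next
      q <- qualk[qs[b] + d - 1L]
      okq <- q >= options$baseq_min
      if (!any(okq)) next
      out[[length(out) + 1]] <- data.frame(
        pos = rs[b] + d[okq] - 2L,   # 0-based reference position
        ref = r[d[okq]], alt = a[d[okq]], baseq = q[okq],
        mapq = x$mapq[idx[k]], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}
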