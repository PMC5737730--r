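#' Windowed read-depth profile of a chromosome
#'
#' Fixed-width windows of mean physical depth plus GC fraction, the input to
#' read-depth CNV detection. This is a deliberately transparent windowed
#' method: low or high coverage is evidence of a deletion or duplication.
#'
#' @param depth physical-depth Rle from [scan_chromosome()].
#' @param chrom chromosome name.
#' @param ref_seq chromosome sequence (character).
#' @param width window width in bases (default 100).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `depth`, `gc` (NA for all-N windows).
#' @export
depth_windows <- function(depth, chrom, ref_seq, width = 100) {
  len <- length(depth)
  starts <- seq.int(1L, len, by = width)
  ends <- pmin(starts + width - 1L, len)
  v <- IRanges::Views(depth, start = starts, end = ends)
  mu <- IRanges::viewMeans(v)
  dna <- Biostrings::DNAString(ref_seq)
  vv <- Biostrings::Views(dna, start = starts, end = ends)
  fr <- Biostrings::letterFrequency(vv, c("CG", "N"))
  w <- ends - starts + 1
  gc <- ifelse(fr[, "N"] >= w, NA_real_, fr[, "C|G"] / pmax(w - fr[, "N"], 1))
  data.frame(chrom = chrom, start = starts - 1L, end = ends,
             depth = as.numeric(mu), gc = gc, stringsAsFactors = FALSE)
}

#' GC-normalize window depths
#'
#' Median-ratio correction in 1% GC bins: corrected depth is
#' `depth * global_median / bin_median`. Bins holding fewer than 20 windows
#' borrow their nearest populated neighbours; all-N windows are excluded.
#'
#' @param windows data.frame from [depth_windows()] (possibly several
#'   chromosomes row-bound together; at least 1000 windows).
#' @return `windows` with a `depth_corrected` column.
#' @export
gc_normalize <- function(windows) {
  if (nrow(windows) == 0) stop("no depth windows to normalize")
  windows <- windows[!is.na(windows$gc), , drop = FALSE]
  if (nrow(windows) == 0) stop("all windows are N-only")
  if (nrow(windows) < 1000) {
    windows$depth_corrected <- windows$depth
    return(windows)
  }
  gmed <- stats::median(windows$depth)
  bin <- pmin(pmax(floor(windows$gc * 100), 0), 99)
  med <- tapply(windows$depth, bin, stats::median)
  cnt <- table(bin)
  bins <- as.integer(names(med))
  # bins with < 20 windows borrow the nearest well-populated bin
  good <- bins[cnt >= 20]
  if (length(good) == 0) {
    windows$depth_corrected <- windows$depth
    return(windows)
  }
  nearest <- good[pmax(1, findInterval(bins, good))]
  alt <- good[pmin(length(good), findInterval(bins, good) + 1)]
  use <- ifelse(abs(bins - nearest) <= abs(bins - alt), nearest, alt)
  bmed <- med[as.character(ifelse(bins %in% good, bins, use))]
  names(bmed) <- bins
  corr <- gmed / bmed[as.character(bin)]
  corr[!is.finite(corr)] <- 1
  windows$depth_corrected <- windows$depth * as.numeric(corr)
  windows
}

#' Segment corrected depths into CNV calls
#'
#' Consecutive runs of at least `min_windows` windows with corrected depth
#' below `low * median` (deletion) or above `high * median` (duplication)
#' are merged into calls with a z-score against the genome-wide spread.
#'
#' @param windows data.frame with `depth_corrected` (from [gc_normalize()]).
#' @param min_windows minimum run length (default 5).
#' @param low,high thresholds as fractions of the global median depth.
#' @return data.frame of CNV calls (`chrom`, `start`, `end`, `type`,
#'   `depth_ratio`, `z`).
#' @export
segment_cnv <- function(windows, min_windows = 5, low = 0.6, high = 1.4) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), type = character(0),
                      depth_ratio = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  gmed <- stats::median(windows$depth_corrected)
  gsd <- stats::mad(windows$depth_corrected)
  if (gmed <= 0) return(empty)
  state <- ifelse(windows$depth_corrected < low * gmed, "DEL",
                  ifelse(windows$depth_corrected > high * gmed, "DUP", "NEU"))
  out <- list()
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    r <- rle(state[wi])
    endi <- cumsum(r$lengths)
    starti <- endi - r$lengths + 1
    for (j in which(r$values != "NEU" & r$lengths >= min_windows)) {
      rows <- wi[starti[j]:endi[j]]
      mu <- mean(windows$depth_corrected[rows])
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = windows$start[rows[1]],
        end = windows$end[rows[length(rows)]],
        type = r$values[j], depth_ratio = mu / gmed,
        z = if (gsd > 0) (mu - gmed) / gsd else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}
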