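#' Library insert-size model
#'
#' Concordance thresholds estimated from a sample of read pairs. Insert-size
#' distributions of short-read libraries are right-skewed, so thresholds are
#' rank-based rather than moment-based: after discarding outliers larger than
#' five times the median, `i_min` and `i_max` are the empirical quantiles at
#' the normal tail levels Phi(-3) and Phi(3) (~0.00135 and ~0.99865), i.e.
#' the points that would sit three standard deviations from the median were
#' the distribution normal. Quantiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' The model drives everything downstream: pair concordance classification,
#' discordant-pair candidate windows, the cluster length tolerance
#' (base term `i_max - i_min + i_median - 2 * L_r`) and the breakpoint
#' matching window `(3/8) * (i_max - i_min)`.
#'
#' @param i_min,i_median,i_max concordant insert-size thresholds (bases).
#' @param read_length read length `L_r` (bases; modal length for
#'   variable-length libraries).
#' @param n_sampled number of pairs the model was fitted from.
#' @param outliers_removed pairs dropped by the 5x-median filter.
#' @return object of class `insert_model`.
#' @export
insert_model <- function(i_min, i_median, i_max, read_length,
                         n_sampled = NA_integer_, outliers_removed = 0L) {
  stopifnot(i_min > 0, i_min <= i_median, i_median <= i_max)
  structure(
    list(i_min = i_min, i_median = i_median, i_max = i_max,
         read_length = read_length, n_sampled = n_sampled,
         outliers_removed = outliers_removed),
    class = "insert_model"
  )
}

#' @export
print.insert_model <- function(x, ...) {
  cat(sprintf(
    "insert model: i_min=%g i_median=%g i_max=%g L_r=%g (n=%s, %d outliers removed)\n",
    x$i_min, x$i_median, x$i_max, x$read_length,
    format(x$n_sampled), x$outliers_removed))
  invisible(x)
}

# tail levels for "3 SD from the median under a normal distribution"
.Q_LO <- stats::pnorm(-3)
.Q_HI <- stats::pnorm(3)

#' Fit an insert-size model from sampled template lengths
#'
#' @param sizes numeric vector of absolute template lengths, one per pair.
#' @param read_length read length in bases.
#' @return an [insert_model()].
#' @examples
#' fit_insert_model(rnorm(1e5, 500, 50), read_length = 150)
#' @export
fit_insert_model <- function(sizes, read_length) {
  if (length(sizes) == 0) stop("no insert sizes to fit")
  med0 <- stats::median(sizes)
  keep <- sizes <= 5 * med0
  if (!any(keep)) stop("all insert sizes filtered as outliers; pathological library")
  filtered <- sizes[keep]
  qs <- stats::quantile(filtered, c(.Q_LO, 0.5, .Q_HI), names = FALSE, type = 7)
  insert_model(
    i_min = qs[1], i_median = qs[2], i_max = qs[3],
    read_length = read_length,
    n_sampled = length(sizes),
    outliers_removed = sum(!keep)
  )
}

#' Sample insert sizes from a BAM file
#'
#' Collects absolute template lengths (TLEN) of mapped, paired, primary
#' alignments whose mate maps to the same chromosome, one value per pair
#' (the record with TLEN > 0), stopping after `max_pairs`. An empty result
#' signals a single-end library; fewer than `min_pairs` usable pairs is an
#' error.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param max_pairs stop after this many pairs (default 1e7).
#' @param min_pairs hard minimum of usable pairs (default 1000); ignored for
#'   single-end libraries (zero paired reads).
#' @return numeric vector of insert sizes (possibly empty for single-end).
#' @export
sample_insert_sizes <- function(bam, max_pairs = 1e7, min_pairs = 1000) {
  stopifnot(max_pairs >= 1)
  bf <- Rsamtools::BamFile(bam, yieldSize = 1e6)
  open(bf)
  on.exit(close(bf))
  flag <- Rsamtools::scanBamFlag(
    isPaired = NA, isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("flag", "rname", "mrnm", "isize"))
  sizes <- numeric(0)
  proper_sizes <- numeric(0)
  any_paired <- FALSE
  repeat {
    chunk <- Rsamtools::scanBam(bf, param = param)[[1]]
    if (length(chunk$flag) == 0) break
    paired <- bitwAnd(chunk$flag, 1L) > 0
    any_paired <- any_paired || any(paired)
    # TLEN > 0 picks one record per pair; TLEN == 0 pairs are unusable
    use <- paired &
      bitwAnd(chunk$flag, 8L) == 0 &            # mate mapped
      !is.na(chunk$isize) & chunk$isize > 0 &
      !is.na(chunk$mrnm) & chunk$mrnm == chunk$rname
    sizes <- c(sizes, as.numeric(chunk$isize[use]))
    proper_sizes <- c(proper_sizes,
                      as.numeric(chunk$isize[use & bitwAnd(chunk$flag, 2L) > 0]))
    if (length(sizes) >= max_pairs) break
  }
  if (!any_paired) return(numeric(0))       # single-end library
  # prefer aligner-marked proper pairs: SV-spanning discordant pairs would
  # otherwise leak into the upper tail of the insert sample
  if (length(proper_sizes) >= min_pairs) sizes <- proper_sizes
  if (length(sizes) > max_pairs) sizes <- sizes[seq_len(max_pairs)]
  if (length(sizes) < min_pairs) stop("insufficient pairs for insert model")
  sizes
}

#' Classify read pairs by orientation and insert size
#'
#' Vectorised total classification of mapped pairs. Same-chromosome FR pairs
#' with insert in `[i_min, i_max]` are concordant; larger inserts indicate a
#' deletion, smaller inserts are treated as small-insertion evidence, RF
#' (outward) orientation indicates a tandem duplication, same-strand pairs an
#' inversion, and mates on different chromosomes a translocation.
#'
#' @param pairs data.frame with columns `chrom1`, `pos1`, `strand1` ("+"/"-"),
#'   `chrom2`, `pos2`, `strand2`, `insert` (absolute outer span; NA allowed
#'   for cross-chromosome pairs) and logical `mate_mapped`.
#' @param model an [insert_model()].
#' @return factor with levels `concordant`, `discordant_deletion`,
#'   `discordant_insertion`, `discordant_duplication`,
#'   `discordant_inversion`, `discordant_translocation`, `unmapped_mate`.
#' @export
classify_pair <- function(pairs, model) {
  lv <- c("concordant", "discordant_deletion", "discordant_insertion",
          "discordant_duplication", "discordant_inversion",
          "discordant_translocation", "unmapped_mate")
  n <- nrow(pairs)
  out <- character(n)
  unm <- !pairs$mate_mapped
  tra <- !unm & pairs$chrom1 != pairs$chrom2
  same <- !unm & !tra
  # orientation on the same chromosome: strand of the leftmost mate first
  left_fwd <- ifelse(pairs$pos1 <= pairs$pos2,
                     pairs$strand1 == "+", pairs$strand2 == "+")
  right_fwd <- ifelse(pairs$pos1 <= pairs$pos2,
                      pairs$strand2 == "+", pairs$strand1 == "+")
  inv <- same & (pairs$strand1 == pairs$strand2)
  dup <- same & !inv & !left_fwd & right_fwd            # RF, outward
  fr <- same & !inv & left_fwd & !right_fwd             # FR, inward
  out[unm] <- "unmapped_mate"
  out[tra] <- "discordant_translocation"
  out[inv] <- "discordant_inversion"
  out[dup] <- "discordant_duplication"
  out[fr & pairs$insert > model$i_max] <- "discordant_deletion"
  out[fr & pairs$insert < model$i_min] <- "discordant_insertion"
  out[fr & pairs$insert >= model$i_min & pairs$insert <= model$i_max] <- "concordant"
  factor(out, levels = lv)
}

#' Base term of the cluster length tolerance
#' @param model an [insert_model()].
#' @return `i_max - i_min + i_median - 2 * L_r`, in bases.
#' @export
cluster_base_term <- function(model) {
  model$i_max - model$i_min + model$i_median - 2 * model$read_length
}

#' Serialize / restore an insert model as a JSON sidecar
#' @param model an [insert_model()].
#' @param path output (input) file path.
#' @return `read_insert_model` returns an [insert_model()].
#' @export
write_insert_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_insert_model
#' @export
read_insert_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  insert_model(x$i_min, x$i_median, x$i_max, x$read_length,
               n_sampled = x$n_sampled,
               outliers_removed = as.integer(x$outliers_removed))
}

#' Warn about apparently mixed (multimodal) insert libraries
#'
#' Cheap dip diagnostic: for a unimodal distribution the density at the
#' median exceeds the density at the quartiles. Libraries mixing two insert
#' distributions distort the matching windows and should be run separately;
#' only a warning is emitted.
#'
#' @param sizes numeric vector of insert sizes (outliers already removed).
#' @return logical, `TRUE` when a dip was flagged (invisibly).
#' @export
check_mixed_library <- function(sizes) {
  if (length(sizes) < 1000) return(invisible(FALSE))
  d <- stats::density(sizes, n = 512)
  at <- function(x) stats::approx(d$x, d$y, xout = x)$y
  qs <- stats::quantile(sizes, c(0.25, 0.5, 0.75), names = FALSE)
  dipped <- isTRUE(at(qs[2]) < 0.9 * max(at(qs[1]), at(qs[3])))
  if (dipped) {
    warning("insert-size distribution looks multimodal; ",
            "mixed libraries should be analysed in separate runs")
  }
  invisible(dipped)
}
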