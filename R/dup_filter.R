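#' Duplicate-pair key
#'
#' PCR/optical duplicate pairs share orientation and external mapping
#' coordinates. The read's own external coordinate is its 5'-most unclipped
#' position (soft-clip adjusted: `pos - left_clip` for forward reads,
#' `end + right_clip` for reverse reads); the mate's coordinate is taken
#' as stored, unadjusted, so the key is computable in a single pass from one
#' record plus its mate fields. Mates may map to different chromosomes. The
#' key is canonicalised under mate swap.
#'
#' @param pairs data.frame with columns `chrom1`, `ext1`, `strand1`,
#'   `chrom2`, `ext2`, `strand2` (`chrom2`/`ext2`/`strand2` NA for
#'   single-end reads).
#' @return character vector of canonical keys.
#' @export
duplicate_key <- function(pairs) {
  single <- is.na(pairs$chrom2)
  a <- paste(pairs$chrom1, pairs$ext1, pairs$strand1, sep = ":")
  b <- paste(pairs$chrom2, pairs$ext2, pairs$strand2, sep = ":")
  swap <- !single & (b < a)
  key <- ifelse(swap, paste(b, a, sep = "|"), paste(a, b, sep = "|"))
  key[single] <- a[single]
  key
}

#' Filter duplicate read pairs
#'
#' Among pairs sharing a [duplicate_key()], exactly one is retained: the one
#' with the highest summed pair mapping quality, ties broken by encounter
#' order. Opposite-orientation pairs at the same coordinates have different
#' keys and are all retained. Idempotent.
#'
#' @param pairs data.frame as for [duplicate_key()], plus a `mapq` column
#'   (summed pair MAPQ).
#' @param enabled set `FALSE` to pass everything through unchanged.
#' @return list with `keep` (logical vector over rows of `pairs`) and
#'   `n_duplicates` (number of rows filtered).
#' @export
dedupe <- function(pairs, enabled = TRUE) {
  n <- nrow(pairs)
  if (!enabled || n == 0) {
    return(list(keep = rep(TRUE, n), n_duplicates = 0L))
  }
  key <- duplicate_key(pairs)
  # stable max-by-mapq within key: order by key, then -mapq, then row;
  # the first row of each key block wins
  ord <- order(key, -pairs$mapq, seq_len(n))
  first <- !duplicated(key[ord])
  keep <- logical(n)
  keep[ord[first]] <- TRUE
  list(keep = keep, n_duplicates = as.integer(n - sum(keep)))
}
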