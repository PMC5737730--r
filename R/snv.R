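#' Call SNVs from per-base allele evidence
#'
#' Each base with alternate-allele observations is scored with the same
#' binomial mismapping model as breakpoint clusters: `p_bc` is the tail
#' probability of at least `alt_count` mismapped reads given the physical
#' depth `n` at the base. A candidate is emitted when `p_bc <= alpha`, the
#' alt read count is at least `snv_min_alt`, the mean base quality of alt
#' reads is at least `snv_baseq_min`, and their mean MAPQ is at least the
#' mapping-quality threshold. The genotype is a simple allele-fraction
#' heuristic (fraction of sequenced reads carrying the alt: >= 0.8 gives
#' 1/1, else 0/1) and is explicitly heuristic, not a genotype likelihood.
#'
#' @param snv per-(position, alt) evidence from [scan_chromosome()].
#' @param depth physical-depth Rle from [scan_chromosome()].
#' @param read_depth aligned-read depth Rle (for the allele fraction).
#' @param chrom chromosome name.
#' @param tab a `significance_table`.
#' @param options a [scan_options()] list.
#' @return data.frame of SNV calls.
#' @export
call_snvs <- function(snv, depth, read_depth, chrom, tab,
                      options = scan_options()) {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      count = numeric(0), depth = numeric(0),
                      p_bc = numeric(0), gt = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(snv) == 0) return(empty)
  n <- as.integer(depth[snv$pos + 1])
  x <- round_half_up(snv$count)
  x <- pmin(x, n)
  p_bc <- lookup_tail(tab, n, x)
  rd <- as.integer(read_depth[snv$pos + 1])
  ok <- snv$count >= options$snv_min_alt &
    snv$mean_baseq >= options$snv_baseq_min &
    snv$mean_mapq >= options$mapq_threshold &
    p_bc <= options$alpha
  if (!any(ok)) return(empty)
  af <- snv$count[ok] / pmax(rd[ok], 1)
  data.frame(chrom = chrom, pos = snv$pos[ok], ref = snv$ref[ok],
             alt = snv$alt[ok], count = snv$count[ok], depth = n[ok],
             p_bc = p_bc[ok], gt = ifelse(af >= 0.8, "1/1", "0/1"),
             stringsAsFactors = FALSE)
}
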