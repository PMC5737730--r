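#' Benchmark matching rules
#'
#' The matching rules used to score calls against a truth set: indel
#' breakpoints must lie within 2 bases of the benchmark, insertion SVs
#' within 10 bases, and all other SVs need a reciprocal overlap of at least
#' 50% (10% for low-resolution benchmark technologies). Calls smaller or
#' larger than the benchmark's shortest or longest event of the same type
#' are ignored rather than counted as false positives, since a benchmark
#' cannot refute calls outside its own size range.
#'
#' @param indel_tol indel breakpoint tolerance (bases).
#' @param ins_tol insertion-SV position tolerance (bases).
#' @param reciprocal_overlap minimum reciprocal overlap for DEL/DUP/INV SVs.
#' @param tra_tol breakend position tolerance for translocations (bases).
#' @param size_clamp drop calls outside the truth size range per type.
#' @return list of rules.
#' @export
benchmark_rules <- function(indel_tol = 2, ins_tol = 10,
                            reciprocal_overlap = 0.5, tra_tol = 100,
                            size_clamp = TRUE) {
  stopifnot(indel_tol >= 0, ins_tol >= 0,
            reciprocal_overlap > 0, reciprocal_overlap <= 1)
  list(indel_tol = indel_tol, ins_tol = ins_tol,
       reciprocal_overlap = reciprocal_overlap, tra_tol = tra_tol,
       size_clamp = size_clamp)
}

#' Reciprocal overlap of two intervals
#'
#' `min(overlap/|a|, overlap/|b|)`; 0 when disjoint. Vectorised.
#'
#' @param a_start,a_end,b_start,b_end interval bounds (half-open).
#' @return overlap fraction in [0, 1].
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  wa <- a_end - a_start; wb <- b_end - b_start
  if (any(wa <= 0) || any(wb <= 0)) stop("zero-length interval")
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  pmin(ov / wa, ov / wb)
}

.is_indel <- function(type, len) type %in% c("DEL", "INS") & len < 50

#' Evaluate calls against a truth set
#'
#' Per-type matching with the benchmark rules; each truth entry is matched
#' at most once, calls are processed in descending support order. SNVs must
#' match position and alternate allele exactly.
#'
#' @param calls,truth call data.frames in the internal representation (as
#'   returned by [read_calls_vcf()] or [run_pipeline()]).
#' @param rules a [benchmark_rules()] list.
#' @return list with `sensitivity`, `precision`, counts, a per-type
#'   data.frame, and the matched/unmatched row indices.
#' @export
evaluate_calls <- function(calls, truth, rules = benchmark_rules()) {
  if (nrow(calls) && nrow(truth)) {
    bad <- setdiff(unique(calls$chrom), unique(c(truth$chrom,
                                                 truth$mate_chrom)))
    # contig naming sanity: all call contigs unknown to the truth set is a
    # configuration error, not 0% sensitivity
    if (length(bad) == length(unique(calls$chrom))) {
      stop("no shared contigs between calls and truth: ",
           paste(bad, collapse = ", "))
    }
  }
  cls <- function(df) ifelse(df$type == "SNV", "SNV",
                      ifelse(df$type == "TRA", "TRA",
                      ifelse(.is_indel(df$type, df$len),
                             paste0("indel_", df$type),
                             paste0("sv_", df$type))))
  calls$class <- if (nrow(calls)) cls(calls) else character(0)
  truth$class <- if (nrow(truth)) cls(truth) else character(0)

  # size-range clamp: ignore SV calls outside the benchmark's size range
  ignored <- rep(FALSE, nrow(calls))
  if (rules$size_clamp && nrow(calls) && nrow(truth)) {
    for (k in unique(calls$class[startsWith(calls$class, "sv_")])) {
      if (k == "sv_INS") next   # insertion lengths are often unknown
      ti <- truth$class == k
      ci <- calls$class == k
      if (!any(ti)) next
      lo <- min(truth$len[ti]); hi <- max(truth$len[ti])
      ignored <- ignored | (ci & (calls$len < lo | calls$len > hi))
    }
  }

  truth_hit <- rep(FALSE, nrow(truth))
  call_tp <- rep(FALSE, nrow(calls))
  ord <- if (nrow(calls)) {
    order(-ifelse(is.na(calls$support), 0, calls$support), calls$pos)
  } else integer(0)
  for (i in ord) {
    if (ignored[i]) next
    k <- calls$class[i]
    cand <- which(!truth_hit & truth$class == k &
                    truth$chrom == calls$chrom[i])
    if (length(cand) == 0) next
    m <- NA_integer_
    if (k == "SNV") {
      hit <- cand[truth$pos[cand] == calls$pos[i] &
                    truth$alt[cand] == calls$alt[i]]
      if (length(hit)) m <- hit[1]
    } else if (k == "TRA") {
      hit <- cand[truth$mate_chrom[cand] == calls$mate_chrom[i] &
                    abs(truth$pos[cand] - calls$pos[i]) <= rules$tra_tol &
                    abs(truth$mate_pos[cand] - calls$mate_pos[i]) <= rules$tra_tol]
      if (length(hit)) m <- hit[1]
    } else if (k %in% c("indel_DEL")) {
      hit <- cand[abs(truth$pos[cand] - calls$pos[i]) <= rules$indel_tol &
                    abs(truth$end[cand] - calls$end[i]) <= rules$indel_tol]
      if (length(hit)) m <- hit[1]
    } else if (k == "indel_INS") {
      hit <- cand[abs(truth$pos[cand] - calls$pos[i]) <= rules$indel_tol]
      if (length(hit)) m <- hit[1]
    } else if (k == "sv_INS") {
      hit <- cand[abs(truth$pos[cand] - calls$pos[i]) <= rules$ins_tol]
      if (length(hit)) m <- hit[1]
    } else {
      ro <- reciprocal_overlap(calls$pos[i], calls$end[i],
                               truth$pos[cand], truth$end[cand])
      hit <- cand[ro >= rules$reciprocal_overlap]
      if (length(hit)) m <- hit[which.max(ro[match(hit, cand)])]
    }
    if (!is.na(m)) {
      truth_hit[m] <- TRUE
      call_tp[i] <- TRUE
    }
  }
  n_eval <- sum(!ignored)
  per_type <- do.call(rbind, lapply(sort(unique(truth$class)), function(k) {
    ti <- truth$class == k
    ci <- calls$class == k & !ignored
    data.frame(class = k, n_truth = sum(ti), tp = sum(truth_hit & ti),
               n_calls = sum(ci), fp = sum(ci & !call_tp),
               sensitivity = if (sum(ti)) sum(truth_hit & ti) / sum(ti) else NA_real_,
               precision = if (sum(ci)) sum(ci & call_tp) / sum(ci) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(
    sensitivity = if (nrow(truth)) sum(truth_hit) / nrow(truth) else NA_real_,
    precision = if (n_eval) sum(call_tp[!ignored]) / n_eval else NA_real_,
    tp = sum(call_tp), fp = sum(!call_tp & !ignored),
    fn = sum(!truth_hit), n_ignored = sum(ignored),
    per_type = per_type,
    truth_matched = which(truth_hit), call_tp = which(call_tp),
    call_fp = which(!call_tp & !ignored))
}
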