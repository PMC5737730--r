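#' Breakpoint matching window
#'
#' Start and end breakpoints of one event must be mutually consistent with
#' the cluster mean lengths to within `c * (i_max - i_min)` with `c = 3/8`.
#'
#' @param model an [insert_model()].
#' @return window in bases.
#' @export
match_window <- function(model) {
  w <- (3 / 8) * (model$i_max - model$i_min)
  stopifnot(w > 0)
  w
}

#' Select representative breakpoint clusters (non-maximum suppression)
#'
#' Discordant-pair windows leave a run of near-identical clusters around each
#' true breakpoint. Per (chromosome, type, side), clusters are grouped into
#' regions separated by more than `gap` bases; within a region the
#' highest-support cluster is kept (ties: anchored first, then leftmost),
#' then any remaining cluster whose length differs by more than the cluster
#' base term is treated as a distinct event and kept by the same rule
#' (overlapping events of clearly different lengths survive).
#'
#' @param clusters scored cluster data.frame.
#' @param model an [insert_model()].
#' @param gap region separation in bases.
#' @return filtered cluster data.frame.
#' @export
select_breakpoints <- function(clusters, model, gap) {
  if (nrow(clusters) == 0) return(clusters)
  base <- cluster_base_term(model)
  key <- paste(clusters$chrom, clusters$type, clusters$side, sep = "\r")
  keep_idx <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(clusters$pos[idx])]
    reg <- cumsum(c(1, diff(clusters$pos[idx]) > gap))
    for (r in unique(reg)) {
      cand <- idx[reg == r]
      while (length(cand)) {
        o <- order(-clusters$support[cand], !clusters$anchored[cand],
                   clusters$pos[cand])
        top <- cand[o[1]]
        keep_idx <- c(keep_idx, top)
        lv <- if (clusters$type[top] == "TRA") clusters$M else clusters$L_bc
        cand <- cand[abs(lv[cand] - lv[top]) > base & cand != top]
      }
    }
  }
  clusters[sort(keep_idx), , drop = FALSE]
}

#' Match start and end breakpoint clusters into calls
#'
#' A (start, end) cluster pair on the same chromosome is a candidate call
#' when both consistency conditions hold with the clusters' mean lengths
#' `L_s`, `L_e`: `|B_s + L_s - B_e| <= w` and `|B_e - L_e - B_s| <= w`.
#' Matching is greedy by descending combined support; each cluster is used
#' at most once. The reported length is the mean of `L_s`, `L_e` and
#' `B_e - B_s` when both breakpoints are clip/split-anchored, otherwise
#' `B_e - B_s`.
#'
#' @param starts,ends cluster data.frames (same chromosome set, same type).
#' @param model an [insert_model()].
#' @param window matching window in bases (default [match_window()]).
#' @return data.frame of calls.
#' @export
match_breakpoints <- function(starts, ends, model,
                              window = match_window(model)) {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      end = numeric(0), type = character(0),
                      len = numeric(0), support = numeric(0),
                      p_bc = numeric(0), anchored = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(starts) == 0 || nrow(ends) == 0) return(empty)
  pairs <- list()
  for (ch in intersect(unique(starts$chrom), unique(ends$chrom))) {
    si <- which(starts$chrom == ch)
    ei <- which(ends$chrom == ch)
    g <- expand.grid(s = si, e = ei)
    ok <- abs(starts$pos[g$s] + starts$L_bc[g$s] - ends$pos[g$e]) <= window &
      abs(ends$pos[g$e] - ends$L_bc[g$e] - starts$pos[g$s]) <= window &
      starts$pos[g$s] < ends$pos[g$e]
    if (any(ok)) pairs[[ch]] <- g[ok, , drop = FALSE]
  }
  if (length(pairs) == 0) return(empty)
  g <- do.call(rbind, pairs)
  comb <- starts$support[g$s] + ends$support[g$e]
  g <- g[order(-comb), , drop = FALSE]
  used_s <- logical(nrow(starts)); used_e <- logical(nrow(ends))
  out <- list()
  for (i in seq_len(nrow(g))) {
    s <- g$s[i]; e <- g$e[i]
    if (used_s[s] || used_e[e]) next
    used_s[s] <- TRUE; used_e[e] <- TRUE
    anch <- starts$anchored[s] && ends$anchored[e]
    span <- ends$pos[e] - starts$pos[s]
    # clip/split-anchored breakpoints are base-resolved, so the span is the
    # best length estimate; without anchors the cluster mean lengths carry
    # independent information and are averaged in
    len <- if (anch) span else mean(c(starts$L_bc[s], ends$L_bc[e], span))
    out[[length(out) + 1]] <- data.frame(
      chrom = starts$chrom[s], pos = starts$pos[s], end = ends$pos[e],
      type = starts$type[s], len = round(len),
      support = starts$support[s] + ends$support[e],
      p_bc = max(starts$p_bc[s], ends$p_bc[e]), anchored = anch,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Match translocation breakpoint clusters across chromosomes
#'
#' Run after all chromosomes are scanned. A start cluster at `B_s` with mean
#' mate position `M_s` matches an end cluster at `B_e` (on the partner
#' chromosome) with mean mate position `M_e` when `|M_s - B_e| <= w` and
#' `|M_e - B_s| <= w`. Greedy by combined support; emitted as breakend pairs.
#'
#' @param clusters genome-wide TRA cluster data.frame.
#' @param model an [insert_model()].
#' @param window matching window (default [match_window()]).
#' @return data.frame of TRA calls (`chrom`, `pos`, `mate_chrom`,
#'   `mate_pos`, `support`, `p_bc`).
#' @export
match_translocations <- function(clusters, model,
                                 window = match_window(model)) {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      mate_chrom = character(0), mate_pos = numeric(0),
                      support = numeric(0), p_bc = numeric(0),
                      stringsAsFactors = FALSE)
  st <- clusters[clusters$side == "start", , drop = FALSE]
  en <- clusters[clusters$side == "end", , drop = FALSE]
  if (nrow(st) == 0 || nrow(en) == 0) return(empty)
  g <- expand.grid(s = seq_len(nrow(st)), e = seq_len(nrow(en)))
  ok <- st$chrom[g$s] != en$chrom[g$e] &
    st$mate_chrom[g$s] == en$chrom[g$e] &
    en$mate_chrom[g$e] == st$chrom[g$s] &
    abs(st$M[g$s] - en$pos[g$e]) <= window &
    abs(en$M[g$e] - st$pos[g$s]) <= window
  g <- g[which(ok), , drop = FALSE]
  if (nrow(g) == 0) return(empty)
  comb <- st$support[g$s] + en$support[g$e]
  g <- g[order(-comb), , drop = FALSE]
  used_s <- logical(nrow(st)); used_e <- logical(nrow(en))
  out <- list()
  for (i in seq_len(nrow(g))) {
    s <- g$s[i]; e <- g$e[i]
    if (used_s[s] || used_e[e]) next
    used_s[s] <- TRUE; used_e[e] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      chrom = st$chrom[s], pos = st$pos[s],
      mate_chrom = en$chrom[e], mate_pos = en$pos[e],
      support = st$support[s] + en$support[e],
      p_bc = max(st$p_bc[s], en$p_bc[e]), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Call small indels from within-read evidence clusters
#'
#' Deletion clusters (length < 50) are start/end matched with a 2-base
#' window, the resolution at which short indels are benchmarked; insertion
#' clusters are single-locus calls at their base.
#'
#' @param clusters significant indel clusters (types DEL/INS, length < 50).
#' @param model an [insert_model()].
#' @return data.frame of indel calls.
#' @export
call_small_indels <- function(clusters, model) {
  del <- clusters[clusters$type == "DEL", , drop = FALSE]
  calls <- match_breakpoints(del[del$side == "start", , drop = FALSE],
                             del[del$side == "end", , drop = FALSE],
                             model, window = 2)
  ins <- clusters[clusters$type == "INS", , drop = FALSE]
  if (nrow(ins)) {
    calls <- rbind(calls, data.frame(
      chrom = ins$chrom, pos = ins$pos, end = ins$pos, type = "INS",
      len = round(ins$L_bc), support = ins$support, p_bc = ins$p_bc,
      anchored = ins$anchored, stringsAsFactors = FALSE))
  }
  calls
}
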