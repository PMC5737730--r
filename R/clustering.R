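#' Adaptive cluster length tolerance
#'
#' Maximum allowed difference between a candidate read's implied variant
#' length and a breakpoint cluster's running mean length:
#' `(i_max - i_min + i_median - 2*L_r) * (1 + 1/x_bc)`, where `x_bc` is the
#' cluster's current (weighted) support. A cluster with one supporting read
#' is a poor length estimate, so the tolerance is twice the base term; as
#' support grows the tolerance tightens towards the base term.
#'
#' @param model an [insert_model()].
#' @param x_bc weighted support of the cluster (> 0); vectorised.
#' @return tolerance in bases.
#' @examples
#' m <- insert_model(250, 500, 550, 150)
#' cluster_tolerance(m, 1)   # 1000
#' @export
cluster_tolerance <- function(model, x_bc) {
  stopifnot(all(x_bc > 0))
  base <- cluster_base_term(model)
  if (base <= 0) stop("non-positive cluster base term; inconsistent insert model")
  base * (1 + 1 / x_bc)
}

#' Assign one breakpoint candidate to a cluster set
#'
#' Greedy rule for candidates sharing a (position, side, type): the candidate
#' joins the eligible cluster (length within [cluster_tolerance()] at the
#' cluster's current support) with the largest support; ties are broken by
#' smallest length difference, then lowest cluster index. With no eligible
#' cluster a new singleton is created. A cluster never gains the same read
#' twice: eligible clusters already containing the read are skipped, and if
#' the chosen outcome would duplicate the read the candidate is dropped.
#'
#' @param clusters list of clusters, each a list with `L_bc`, `x_bc`, `ids`.
#' @param length candidate implied variant length `L_disc`.
#' @param weight candidate weight (0.5 or 1.0).
#' @param id opaque read identifier.
#' @param model an [insert_model()].
#' @return updated cluster list.
#' @export
assign_read <- function(clusters, length, weight, id, model) {
  if (length(clusters) > 0) {
    xs <- vapply(clusters, `[[`, numeric(1), "x_bc")
    Ls <- vapply(clusters, `[[`, numeric(1), "L_bc")
    diffs <- abs(Ls - length)
    has_id <- vapply(clusters, function(cl) id %in% cl$ids, logical(1))
    elig <- which(diffs <= cluster_tolerance(model, xs) & !has_id)
    if (length(elig) > 0) {
      j <- elig[order(-xs[elig], diffs[elig], elig)][1]
      cl <- clusters[[j]]
      cl$L_bc <- (cl$L_bc * cl$x_bc + length * weight) / (cl$x_bc + weight)
      cl$x_bc <- cl$x_bc + weight
      cl$ids <- c(cl$ids, id)
      clusters[[j]] <- cl
      return(clusters)
    }
    if (any(vapply(clusters, function(cl) id %in% cl$ids, logical(1)) &
            diffs <= cluster_tolerance(model, xs))) {
      # only clusters already holding this read were in tolerance: skip
      return(clusters)
    }
  }
  c(clusters, list(list(L_bc = length, x_bc = weight, ids = id)))
}

#' Cluster all candidates at one (position, side, type)
#'
#' Runs [assign_read()] over the candidates in order. Greedy clustering is
#' order-sensitive; the pipeline feeds candidates sorted with exact
#' (CIGAR/split, weight 1) evidence before windowed discordant evidence.
#'
#' @param lengths,weights,ids parallel candidate vectors.
#' @param model an [insert_model()].
#' @return list of clusters (`L_bc`, `x_bc`, `ids`).
#' @export
cluster_position <- function(lengths, weights, ids, model) {
  clusters <- list()
  for (i in seq_along(lengths)) {
    clusters <- assign_read(clusters, lengths[i], weights[i], ids[i], model)
  }
  clusters
}

# Fast equivalent of cluster_position when every candidate joins one cluster.
# If the length spread never exceeds the base term, each arriving candidate
# is within the base term of any running mean of previous lengths (a convex
# combination), hence within tolerance; only one cluster can exist, so the
# greedy result is the weighted mean over first-occurrence reads.
.cluster_group_fast <- function(lengths, weights, ids) {
  keep <- !duplicated(ids)
  w <- weights[keep]
  list(list(L_bc = sum(lengths[keep] * w) / sum(w), x_bc = sum(w),
            ids = ids[keep]))
}

#' Cluster a whole candidate table
#'
#' Groups candidates by (chrom, pos, side, type[, mate chrom]) and clusters
#' each group. Within a group candidates are processed exact-first
#' (CIGAR/split/clip sources before discordant windows), then in input
#' order. For translocation candidates the clustered quantity is the implied
#' mate-junction position; its cluster mean is reported as `M`.
#'
#' @param cands data.frame with columns `chrom`, `pos`, `side`, `type`,
#'   `length`, `weight`, `read`, `source`, and optionally `mate_chrom`, `M`.
#' @param model an [insert_model()].
#' @return data.frame of clusters: `chrom`, `pos`, `side`, `type`, `L_bc`,
#'   `support`, `n_members`, `anchored`, `mate_chrom`, `M`, plus a
#'   `members` list-column of read ids.
#' @export
cluster_candidates <- function(cands, model) {
  empty <- data.frame(
    chrom = character(0), pos = numeric(0), side = character(0),
    type = character(0), L_bc = numeric(0), support = numeric(0),
    n_members = integer(0), anchored = logical(0),
    mate_chrom = character(0), M = numeric(0), stringsAsFactors = FALSE)
  empty$members <- list()
  if (is.null(cands) || nrow(cands) == 0) return(empty)
  if (is.null(cands$mate_chrom)) cands$mate_chrom <- NA_character_
  if (is.null(cands$M)) cands$M <- NA_real_
  is_tra <- cands$type == "TRA"
  cl_len <- ifelse(is_tra, cands$M, cands$length)
  exact <- cands$source %in% c("cigar", "split", "clip")
  ord <- order(!exact, seq_len(nrow(cands)))
  cands <- cands[ord, , drop = FALSE]
  cl_len <- cl_len[ord]

  key <- paste(cands$chrom, cands$pos, cands$side, cands$type,
               cands$mate_chrom, sep = "\r")
  grp <- split(seq_len(nrow(cands)), factor(key, levels = unique(key)))
  base <- cluster_base_term(model)
  exact_src <- cands$source %in% c("cigar", "split", "clip")

  res <- lapply(grp, function(idx) {
    L <- cl_len[idx]; w <- cands$weight[idx]; id <- cands$read[idx]
    cls <- if (max(L) - min(L) <= base) {
      .cluster_group_fast(L, w, id)
    } else {
      cluster_position(L, w, id, model)
    }
    ex <- id[exact_src[idx]]
    list(first = idx[1],
         L = vapply(cls, `[[`, numeric(1), "L_bc"),
         x = vapply(cls, `[[`, numeric(1), "x_bc"),
         members = lapply(cls, `[[`, "ids"),
         anch = vapply(cls, function(cl) any(cl$ids %in% ex), logical(1)))
  })
  ncl <- vapply(res, function(r) length(r$L), integer(1))
  first <- rep.int(vapply(res, `[[`, integer(1), "first"), ncl)
  members <- do.call(c, lapply(res, `[[`, "members"))
  out <- data.frame(
    chrom = cands$chrom[first], pos = cands$pos[first],
    side = cands$side[first], type = cands$type[first],
    L_bc = unlist(lapply(res, `[[`, "L"), use.names = FALSE),
    support = unlist(lapply(res, `[[`, "x"), use.names = FALSE),
    n_members = lengths(members),
    anchored = unlist(lapply(res, `[[`, "anch"), use.names = FALSE),
    mate_chrom = cands$mate_chrom[first],
    M = NA_real_, stringsAsFactors = FALSE)
  out$members <- members
  rownames(out) <- NULL
  # for TRA clusters the clustered quantity was the mate position
  tra <- out$type == "TRA"
  out$M[tra] <- out$L_bc[tra]
  out$L_bc[tra] <- NA_real_
  out
}
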