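#' Binomial mismapping tail probability
#'
#' Probability that at least `x` of `n` fragments at a position are mapping
#' errors, under a per-read mismapping probability `p` derived from the
#' mapping-quality threshold (`p = 10^(-m/10)`). This is the score attached
#' to every SNV and breakpoint cluster: a small value means the observed
#' support is unlikely to consist entirely of mismapped reads.
#'
#' The upper tail is summed directly in log space,
#' `sum_{k=x}^{n} C(n,k) p^k q^(n-k)` with `q = 1 - p`, which is stable for
#' the very small tails that drive calling decisions (the complementary form
#' `1 - sum_{k<x}` loses all precision below ~1e-16).
#'
#' @param n integer vector, fragment depth (number of trials).
#' @param x integer vector, weighted support rounded to an integer.
#' @param p per-read mismapping probability, in (0, 1).
#' @return numeric vector of tail probabilities `Pr(X >= x)`.
#' @examples
#' tail_probability(30, 5, 0.01)
#' tail_probability(10, 0, 0.01)  # always 1
#' @export
tail_probability <- function(n, x, p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    stop("mismapping probability p must lie strictly in (0, 1)")
  }
  if (any(n < 0) || any(x < 0)) stop("n and x must be non-negative")
  ans <- mapply(function(ni, xi) {
    if (xi == 0) return(1)
    if (xi > ni) return(0)
    k <- xi:ni
    sum(exp(lchoose(ni, k) + k * log(p) + (ni - k) * log1p(-p)))
  }, as.numeric(n), as.numeric(x))
  pmin(pmax(ans, 0), 1)
}

#' Build (or load from cache) a binomial tail-probability table
#'
#' Tables are keyed by the mapping-quality threshold `m` and the maximum
#' depth `n_max`; `table[[n]][x + 1]` holds `Pr(X >= x)` for
#' `Binomial(n, 10^(-m/10))`. Non-default `m` values trigger a rebuild.
#' Cached files carry a header (m, n_max, format version, checksum) and are
#' rebuilt with a warning when corrupt.
#'
#' @param m mapping-quality threshold (phred); `p = 10^(-m/10)`.
#' @param n_max largest depth stored; deeper positions fall through to
#'   [tail_probability()].
#' @param cache_dir directory for the cache file, or `NULL` to skip caching.
#' @return object of class `significance_table`.
#' @export
build_tables <- function(m = 20, n_max = 1000, cache_dir = NULL) {
  stopifnot(n_max >= 1)
  p <- 10^(-m / 10)
  if (!is.null(cache_dir)) {
    path <- file.path(cache_dir, sprintf("binom_tail_m%s_n%d.rds", m, n_max))
    if (file.exists(path)) {
      tab <- tryCatch(readRDS(path), error = function(e) NULL)
      if (!is.null(tab) && .table_valid(tab, m, n_max)) return(tab)
      warning("corrupt significance table cache; rebuilding")
    }
  }
  rows <- lapply(seq_len(n_max), function(n) {
    # Pr(X >= x) for x = 0..n: cumulative upper sums of the pmf, accumulated
    # from the top term down so small tails keep full relative precision
    k <- 0:n
    pmf <- exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
    rev(cumsum(rev(pmf)))
  })
  tab <- structure(
    list(m = m, p = p, n_max = n_max, rows = rows, version = 1L,
         checksum = sum(unlist(rows))),
    class = "significance_table"
  )
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(tab, path)
  }
  tab
}

.table_valid <- function(tab, m, n_max) {
  is.list(tab) && identical(class(tab), "significance_table") &&
    isTRUE(tab$m == m) && isTRUE(tab$n_max == n_max) &&
    length(tab$rows) == n_max &&
    isTRUE(abs(sum(unlist(tab$rows)) - tab$checksum) < 1e-8)
}

#' Look up a tail probability, using the table when possible
#'
#' Vectorised over `n` and `x`. Depths beyond `n_max` (and `x = 0`, `x > n`)
#' are computed directly; the two routes agree to numerical precision.
#'
#' @param tab a `significance_table` from [build_tables()].
#' @inheritParams tail_probability
#' @return numeric vector of `Pr(X >= x)`.
#' @export
lookup_tail <- function(tab, n, x) {
  n <- as.integer(n); x <- as.integer(x)
  out <- numeric(length(n))
  in_tab <- n >= 1 & n <= tab$n_max & x >= 0 & x <= n
  if (any(in_tab)) {
    out[in_tab] <- mapply(function(ni, xi) tab$rows[[ni]][xi + 1L],
                          n[in_tab], x[in_tab])
  }
  if (any(!in_tab)) {
    idx <- which(!in_tab)
    out[idx] <- tail_probability(n[idx], x[idx], tab$p)
  }
  out
}

#' Round half-up to an integer (fractional cluster support)
#' @param x numeric vector.
#' @return integer vector; 0.5 rounds to 1.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Score breakpoint clusters with the binomial mismapping model
#'
#' Attaches `p_bc = Pr(X >= round(x_bc))` under `Binomial(n, p)` to each
#' cluster, where `n` is the physical depth at the cluster position. Support
#' exceeding depth (a depth-accounting pathology) is clamped with a warning.
#'
#' @param clusters data.frame with at least `support` (weighted `x_bc`) and
#'   `depth` (`n`) columns.
#' @param tab a `significance_table`.
#' @return `clusters` with a `p_bc` column added.
#' @export
score_clusters <- function(clusters, tab) {
  if (nrow(clusters) == 0) {
    clusters$p_bc <- numeric(0)
    return(clusters)
  }
  x <- round_half_up(clusters$support)
  n <- as.integer(clusters$depth)
  if (any(bad <- x > n)) {
    warning(sum(bad), " cluster(s) with support exceeding depth; clamped")
    x[bad] <- n[bad]
  }
  clusters$p_bc <- lookup_tail(tab, n, x)
  clusters
}
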