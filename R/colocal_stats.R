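# Enrichment statistics in log10 space, emergent-region logic across
# time points, percentage reporting, and signal matrices (average
# profiles, ranked heat maps) around element centers.
#
# Several reported p-values (1E-300 and below) underflow binary doubles,
# so every tail here is computed by log-gamma summation and returned as
# log10(p); linear-scale convenience values are derived from that.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log10 upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` (or `P(X > k)` with `strict = TRUE`) for the number of
#' marked elements in a size-`n` sample drawn without replacement from a
#' population of `N` containing `K` marked elements. Computed by
#' log-gamma summation of the exact pmf terms, so results are accurate
#' far below double-precision underflow.
#'
#' The strict variant exists because enrichment p-values in this pipeline
#' (see [dependence_enrichment()]) are reported as the probability of
#' exceeding the observed overlap by chance.
#'
#' @param N population size.
#' @param K marked elements in the population.
#' @param n sample size.
#' @param k observed marked elements in the sample.
#' @param strict if `TRUE`, compute `P(X > k)` instead of `P(X >= k)`.
#' @return log10 of the tail probability (0 when the tail includes the
#'   whole support).
#' @export
log10_hypergeom_tail <- function(N, K, n, k, strict = FALSE) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (k < 0 || k > n || n > N || K < 0 || K > N || k > K)
    stop("invalid hypergeometric input: need 0 <= k <= n <= N, 0 <= K <= N, k <= K")
  if (strict) k <- k + 1
  hi <- min(K, n)
  lo <- max(0, n - (N - K))
  if (k <= lo) return(0)
  if (k > hi) return(-Inf)
  i <- k:hi
  lterm <- lgamma(K + 1) - lgamma(i + 1) - lgamma(K - i + 1) +
    lgamma(N - K + 1) - lgamma(n - i + 1) - lgamma(N - K - n + i + 1) -
    (lgamma(N + 1) - lgamma(n + 1) - lgamma(N - n + 1))
  min(log_sum_exp(lterm) / log(10), 0)
}

#' Log10 upper tail of the binomial distribution
#'
#' `P(X >= k)` for `n` trials with success probability `p0`, by log-gamma
#' summation of the exact pmf terms.
#'
#' @param n number of trials.
#' @param k observed successes.
#' @param p0 background success probability, in (0, 1).
#' @return log10 of the upper-tail probability.
#' @export
log10_binomial_tail <- function(n, k, p0) {
  stopifnot(length(n) == 1, length(k) == 1, length(p0) == 1)
  if (k < 0 || k > n) stop("invalid binomial input: need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
  if (k == 0) return(0)
  i <- k:n
  lterm <- lgamma(n + 1) - lgamma(i + 1) - lgamma(n - i + 1) +
    i * log(p0) + (n - i) * log1p(-p0)
  min(log_sum_exp(lterm) / log(10), 0)
}

#' Percentage to one decimal
#'
#' `100 * k / n` rounded half-away-from-zero to one decimal, the
#' convention used for every reported percentage.
#'
#' @param k numerator (vectorized).
#' @param n denominator (> 0).
#' @return numeric vector of percentages.
#' @export
percent <- function(k, n) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  floor(1000 * k / n + 0.5) / 10
}

#' Emergent regions across ordered time points
#'
#' Given island sets ordered in time, the emergent set at time t contains
#' the members overlapping (>= 1 bp) no member of any earlier set; the
#' time-0 set is emergent in full.
#'
#' @param sets list of interval data.frames, ordered by time, each
#'   internally non-overlapping.
#' @return list of data.frames, the emergent set per time point.
#' @export
emergent_regions <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  earlier <- NULL
  for (t in seq_along(sets)) {
    s <- validate_intervals(sets[[t]], paste0("set ", t))
    if (has_internal_overlap(s)) stop("set ", t, " has internally overlapping members")
    if (is.null(earlier) || !nrow(earlier)) {
      out[[t]] <- s
    } else {
      out[[t]] <- s[!overlaps_any(s, earlier), , drop = FALSE]
    }
    earlier <- rbind_intervals(earlier, s)
  }
  out
}

#' Top-n islands ranked by FDR
#'
#' Ranking is ascending FDR (log10 when available), ties broken by
#' descending score, then by coordinate.
#'
#' @param islands island data.frame with `log10_fdr` (or `fdr`) and
#'   `score` columns.
#' @param n number of islands to keep.
#' @return the top `n` rows.
#' @export
top_islands <- function(islands, n = 2000L) {
  if (!nrow(islands)) return(islands)
  fdr <- if ("log10_fdr" %in% names(islands)) islands$log10_fdr else islands$fdr
  score <- if ("score" %in% names(islands)) islands$score else rep(0, nrow(islands))
  o <- order(fdr, -score, islands$chrom, islands$start)
  out <- islands[utils::head(o, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# signal matrix: rows = centers, cols = bins of `bin` bp spanning
# [-halfwidth, halfwidth); values = tag counts scaled to reads-per-million
signal_matrix <- function(tags, centers, halfwidth, bin) {
  stopifnot(inherits(tags, "tag_library"), nrow(centers) >= 1,
            halfwidth %% bin == 0)
  nbin <- as.integer(2 * halfwidth / bin)
  mat <- matrix(0, nrow = nrow(centers), ncol = nbin)
  scale <- if (tags$total_count > 0) 1e6 / tags$total_count else 0
  dt <- tags$tags
  for (i in seq_len(nrow(centers))) {
    ch <- centers$chrom[i]
    c0 <- centers$center[i]
    sub <- dt[chrom == ch & pos >= c0 - halfwidth & pos < c0 + halfwidth]
    if (nrow(sub)) {
      b <- (sub$pos - (c0 - halfwidth)) %/% bin + 1L
      tb <- tabulate(b, nbins = nbin)
      mat[i, ] <- tb * scale
    }
  }
  mat
}

#' Average signal profile around element centers
#'
#' Mean reads-per-million per bin across centers, in `bin`-bp bins from
#' `-halfwidth` to `+halfwidth` (left to right in genome coordinates;
#' profiles are not strand-oriented).
#'
#' @param tags a `tag_library`.
#' @param centers data.frame with `chrom` and `center` (bp).
#' @param halfwidth window half-width in bp (default 10,000).
#' @param bin bin width in bp (default 5); must divide `halfwidth`.
#' @return list with `offset` (bin start offsets relative to center),
#'   `profile` (mean RPM per bin) and the full `matrix`.
#' @export
average_profile <- function(tags, centers, halfwidth = 10000L, bin = 5L) {
  mat <- signal_matrix(tags, centers, halfwidth, bin)
  list(offset = seq(-halfwidth, halfwidth - bin, by = bin),
       profile = colMeans(mat), matrix = mat)
}

#' Ranked signal heat-map matrix
#'
#' Bins `tags` around each center at `resolution` bp over
#' `+/- halfwidth`, then orders rows by descending ranking signal — the
#' tag count of `rank_tags` (default: `tags`) within the central
#' `rank_window` bp. Row order is deterministic: ties break by the
#' original center order after sorting centers by coordinate.
#'
#' @param tags a `tag_library` providing the displayed signal.
#' @param centers data.frame with `chrom` and `center`.
#' @param halfwidth half-width in bp (default 10,000).
#' @param resolution bin width in bp (default 50).
#' @param rank_tags `tag_library` supplying the ranking signal.
#' @param rank_window width (bp) of the central ranking window
#'   (default 400); a multiple of `resolution`.
#' @return list with `matrix` (rows in ranked order), `order` (row
#'   indices into the coordinate-sorted centers) and `rank_signal`.
#' @export
heatmap_matrix <- function(tags, centers, halfwidth = 10000L,
                           resolution = 50L, rank_tags = tags,
                           rank_window = 400L) {
  stopifnot(rank_window %% resolution == 0)
  centers <- centers[order(centers$chrom, centers$center), , drop = FALSE]
  mat <- signal_matrix(tags, centers, halfwidth, resolution)
  half <- rank_window %/% 2L
  rk <- vapply(seq_len(nrow(centers)), function(i) {
    sum(rank_tags$tags[chrom == centers$chrom[i] &
                         pos >= centers$center[i] - half &
                         pos < centers$center[i] + half, .N])
  }, numeric(1))
  o <- order(-rk, seq_len(nrow(centers)))
  list(matrix = mat[o, , drop = FALSE], order = o, rank_signal = rk[o])
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum comparison via [stats::wilcox.test()]: exact
#' enumeration when the smaller group has <= 8 observations and the data
#' are tie-free, the normal approximation with midrank tie correction
#' otherwise.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `two_sided`, `greater` (`a` shifted above `b`) and
#'   `less` p-values.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- min(length(a), length(b)) <= 8 && !anyDuplicated(c(a, b))
  p_of <- function(alt) {
    suppressWarnings(stats::wilcox.test(a, b, alternative = alt,
                                        exact = exact, correct = !exact)$p.value)
  }
  list(two_sided = p_of("two.sided"), greater = p_of("greater"),
       less = p_of("less"))
}
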