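# Independent brute-force reference implementations used to pin down the
# optimized code paths. These deliberately share no code with the
# package internals beyond trivial arithmetic.

# O(n^2) all-pairs overlap partition
oracle_overlap_partition <- function(a, b) {
  hit1 <- function(x, y) x$chrom == y$chrom && x$start < y$end && y$start < x$end
  a_hits <- rep(FALSE, nrow(a))
  b_hits <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (hit1(a[i, ], b[j, ])) a_hits[i] <- b_hits[j] <- TRUE
  }
  list(n_both = sum(a_hits), n_a_only = sum(!a_hits), n_b_only = sum(!b_hits))
}

# exhaustive window-by-window island finder: enumerate every window,
# test eligibility, and merge runs one step at a time
oracle_candidate_islands <- function(tags, chrom_lengths, params) {
  w <- params$window_size
  lambda <- tags$total_count * w /
    (sum(chrom_lengths) * params$effective_genome_fraction)
  out <- NULL
  for (ch in sort(unique(tags$tags$chrom))) {
    pos <- sort(tags$tags$pos[tags$tags$chrom == ch])
    nwin <- floor(chrom_lengths[[ch]] / w)
    counts <- integer(nwin)
    for (p in pos) {
      wi <- p %/% w + 1L
      if (wi <= nwin) counts[wi] <- counts[wi] + 1L
    }
    eligible <- vapply(counts, function(cc) {
      cc > 0 && sum(dpois(0:(cc - 1), lambda)) > 1 - params$eligibility_p
    }, logical(1))
    # walk eligible windows, merging across gaps <= g ineligible windows
    idx <- which(eligible)
    while (length(idx)) {
      run <- idx[1]
      idx <- idx[-1]
      while (length(idx) && idx[1] - run[length(run)] - 1 <= params$gap_windows) {
        run <- c(run, idx[1])
        idx <- idx[-1]
      }
      first <- run[1]; last <- run[length(run)]
      score <- sum(vapply(run, function(wi) -dpois(counts[wi], lambda, log = TRUE),
                          numeric(1)))
      out <- rbind(out, data.frame(
        chrom = ch, start = (first - 1L) * w, end = last * w,
        chip_count = sum(counts[first:last]), n_eligible = length(run),
        score = score))
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      chip_count = integer(0), n_eligible = integer(0),
                      score = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# exact hypergeometric upper tail by direct combinatorial summation
oracle_hypergeom_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  i <- i[i >= max(0, n - (N - K))]
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exact binomial upper tail by direct summation
oracle_binomial_tail <- function(n, k, p0) {
  if (k <= 0) return(1)
  i <- k:n
  sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
}

# emergent sets by explicit pairwise scanning against all earlier sets
oracle_emergent <- function(sets) {
  hit1 <- function(x, y) x$chrom == y$chrom && x$start < y$end && y$start < x$end
  out <- vector("list", length(sets))
  for (t in seq_along(sets)) {
    s <- sets[[t]]
    keep <- rep(TRUE, nrow(s))
    if (t > 1) {
      earlier <- do.call(rbind, lapply(sets[seq_len(t - 1)],
                                       function(x) x[, c("chrom", "start", "end")]))
      for (i in seq_len(nrow(s))) {
        for (j in seq_len(nrow(earlier))) {
          if (hit1(s[i, ], earlier[j, ])) { keep[i] <- FALSE; break }
        }
      }
    }
    out[[t]] <- s[keep, , drop = FALSE]
  }
  out
}

# rule-by-rule element classification, evaluated per TSS / per island
# with scalar overlap checks only
oracle_classify <- function(me1, me3, k27ac, tss, radius) {
  hit_any <- function(iv, set) {
    if (!nrow(set)) return(FALSE)
    any(vapply(seq_len(nrow(set)), function(j) {
      iv$chrom == set$chrom[j] && iv$start < set$end[j] && set$start[j] < iv$end
    }, logical(1)))
  }
  rows <- list()
  for (i in seq_len(nrow(tss))) {
    win <- list(chrom = tss$chrom[i], start = max(0, tss$tss[i] - radius),
                end = tss$tss[i] + radius)
    if (hit_any(win, me3)) {
      cls <- if (hit_any(win, k27ac)) "active_promoter" else "silent_promoter"
      rows[[length(rows) + 1]] <- data.frame(chrom = win$chrom, start = win$start,
                                             end = win$end, center = tss$tss[i],
                                             element_class = cls)
    }
  }
  for (i in seq_len(nrow(me1))) {
    iv <- list(chrom = me1$chrom[i], start = me1$start[i], end = me1$end[i])
    ctr <- floor((me1$start[i] + me1$end[i]) / 2)
    d <- abs(tss$tss[tss$chrom == iv$chrom] - ctr)
    distal <- !length(d) || min(d) > radius
    if (distal && !hit_any(iv, me3)) {
      cls <- if (hit_any(iv, k27ac)) "active_enhancer" else "silent_enhancer"
      rows[[length(rows) + 1]] <- data.frame(chrom = iv$chrom, start = iv$start,
                                             end = iv$end, center = ctr,
                                             element_class = cls)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# n disjoint random intervals on [0, L) built on a slot grid
gen_disjoint_intervals <- function(n, L, slot = NULL, chrom = "chr1") {
  if (is.null(slot)) slot <- L %/% n
  stopifnot(slot >= 4, n * slot <= L)
  starts <- (sample(L %/% slot, n) - 1L) * slot
  widths <- sample(seq_len(slot - 1L), n, replace = TRUE)
  out <- data.frame(chrom = chrom, start = starts, end = starts + widths)
  out[order(out$start), , drop = FALSE]
}

# small tag library straight from positions
tags_from_positions <- function(pos, chrom = "chr1", strand = "+") {
  tag_library(data.frame(chrom = chrom, pos = as.integer(pos),
                         strand = strand))
}
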