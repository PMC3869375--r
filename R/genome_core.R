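# Coordinate conventions and interval plumbing shared by every stage.
# All intervals are 0-based half-open (BED convention) and travel as plain
# data.frames with columns chrom/start/end (+ optional name/score/strand);
# conversion to IRanges/GenomicRanges (1-based closed) happens internally.

#' Validate a table of genomic intervals
#'
#' Checks the interval invariants: `chrom` is a non-empty whitespace-free
#' token, `0 <= start < end`. Coordinates are 0-based half-open.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param context label used in error messages.
#' @return `x`, invisibly, with integer-coerced coordinates.
#' @export
validate_intervals <- function(x, context = "intervals") {
  if (!is.data.frame(x)) stop(context, ": expected a data.frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(context, ": missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)) || any(grepl("\\s", x$chrom)))
      stop(context, ": chrom must be a non-empty token without whitespace")
    if (any(is.na(x$start)) || any(is.na(x$end)))
      stop(context, ": NA coordinates")
    if (any(x$start < 0)) stop(context, ": negative start")
    if (any(x$start >= x$end)) stop(context, ": start must be < end")
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  invisible(x)
}

#' Convert an interval table to GRanges
#'
#' @param x validated interval data.frame (0-based half-open).
#' @return a [GenomicRanges::GRanges] (1-based closed).
#' @export
intervals_to_granges <- function(x) {
  strand <- if ("strand" %in% names(x) && nrow(x)) x$strand else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end),
                         strand = strand)
}

#' Interval midpoint
#'
#' Center of a 0-based half-open interval, `floor((start + end)/2)`.
#'
#' @param start,end integer vectors.
#' @return integer vector of centers.
#' @export
interval_center <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

#' Do two intervals overlap by at least 1 bp?
#'
#' Co-localization rule used throughout: same chromosome and
#' `a.start < b.end && b.start < a.end` (half-open arithmetic, so
#' adjacent intervals do not overlap).
#'
#' @param a,b single-row interval data.frames or lists with
#'   `chrom`, `start`, `end`.
#' @return logical scalar.
#' @export
overlaps <- function(a, b) {
  isTRUE(a$chrom == b$chrom && a$start < b$end && b$start < a$end)
}

# logical vector: which rows of x overlap >=1 row of y (>=1 bp rule)
overlaps_any <- function(x, y) {
  if (!nrow(x)) return(logical(0))
  if (!nrow(y)) return(rep(FALSE, nrow(x)))
  IRanges::overlapsAny(intervals_to_granges(x), intervals_to_granges(y),
                       ignore.strand = TRUE)
}

has_internal_overlap <- function(x) {
  if (nrow(x) < 2) return(FALSE)
  gr <- intervals_to_granges(x)
  any(IRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1L)
}

#' Partition two interval sets by mutual overlap
#'
#' Venn-style bookkeeping over two internally non-overlapping interval
#' sets: how many members of A overlap at least one member of B (>=1 bp),
#' how many are A-only / B-only, and which B members each A member hits.
#' Within-set overlaps are rejected: counts would otherwise be ambiguous,
#' so callers must merge first.
#'
#' @param a,b interval data.frames, each internally non-overlapping.
#' @return list with `n_both` (A members overlapping B), `n_a_only`,
#'   `n_b_only`, and `a_to_b`, a list mapping each A row index to the B
#'   row indices it overlaps.
#' @export
overlap_partition <- function(a, b) {
  a <- validate_intervals(a, "setA")
  b <- validate_intervals(b, "setB")
  if (has_internal_overlap(a)) stop("setA has internally overlapping members; merge first")
  if (has_internal_overlap(b)) stop("setB has internally overlapping members; merge first")
  if (!nrow(a)) {
    return(list(n_both = 0L, n_a_only = 0L, n_b_only = nrow(b),
                a_to_b = list()))
  }
  if (!nrow(b)) {
    return(list(n_both = 0L, n_a_only = nrow(a), n_b_only = 0L,
                a_to_b = rep(list(integer(0)), nrow(a))))
  }
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(a), intervals_to_granges(b),
                                      ignore.strand = TRUE)
  a_to_b <- split(S4Vectors::subjectHits(hits), factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(a))))
  a_to_b <- lapply(a_to_b, as.integer)
  a_hit <- lengths(a_to_b) > 0
  b_hit <- seq_len(nrow(b)) %in% S4Vectors::subjectHits(hits)
  list(n_both = sum(a_hit), n_a_only = sum(!a_hit), n_b_only = sum(!b_hit),
       a_to_b = unname(a_to_b))
}

#' Nearest transcription start site
#'
#' Finds the TSS minimizing `|tss - pos|` on the same chromosome.
#' Distance ties are broken by the lexicographically smaller `gene_id`.
#' Returns `NULL` when the minimum distance exceeds `max_dist`
#' (default 1,000 kb, the assignment cutoff used throughout).
#'
#' @param chrom chromosome of the query position.
#' @param pos query position (bp).
#' @param tss data.frame with `gene_id`, `chrom`, `tss` (and optionally
#'   `strand`).
#' @param max_dist maximum assignment distance in bp.
#' @return `NULL`, or list with `gene_id` and `distance` (signed,
#'   `tss - pos`).
#' @export
nearest_tss <- function(chrom, pos, tss, max_dist = 1e6) {
  stopifnot(nrow(tss) > 0, max_dist > 0)
  cand <- tss[tss$chrom == chrom, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  d <- abs(cand$tss - pos)
  dmin <- min(d)
  if (dmin > max_dist) return(NULL)
  hit <- cand[d == dmin, , drop = FALSE]
  hit <- hit[order(hit$gene_id), , drop = FALSE]
  list(gene_id = hit$gene_id[1], distance = hit$tss[1] - pos)
}

#' Read a BED file (3-6 columns)
#'
#' Coordinates are kept 0-based half-open exactly as stored. Malformed
#' lines (wrong column count, non-numeric or negative coordinates,
#' start >= end) raise an error naming the offending line number.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) > 1L || ncols[1] < 3L || ncols[1] > 6L) {
    bad <- which(ncols != ncols[1] | ncols < 3L | ncols > 6L)[1]
    stop("malformed BED line ", bad, " in ", path, ": expected 3-6 tab-separated columns")
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": coordinates must satisfy 0 <= start < end")
  }
  out <- data.frame(chrom = m[, 1], start = start, end = end)
  if (ncol(m) >= 4) out$name <- m[, 4]
  if (ncol(m) >= 5) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (ncol(m) >= 6) out$strand <- m[, 6]
  validate_intervals(out, path)
  out
}

#' Write intervals as BED
#'
#' Emits as many of the columns `chrom,start,end,name,score,strand` as are
#' present; round-trips with [read_bed()].
#'
#' @param x interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x, "write_bed")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  # BED columns are positional: truncate at the first absent one
  keep <- character(0)
  for (col in c("chrom", "start", "end", "name", "score", "strand")) {
    if (col %in% cols) keep <- c(keep, col) else break
  }
  data.table::fwrite(x[, keep, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSS/exon annotation table
#'
#' Tab-separated columns: `gene_id`, `chrom`, `strand`, `tss`,
#' `exon_starts`, `exon_ends` (the last two comma-separated, 0-based
#' half-open).
#'
#' @param path annotation file path.
#' @return list with `tss` (one row per gene) and `exons`
#'   (one row per exon: `gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
read_annotation <- function(path) {
  # exon lists are comma-separated; force character so fread never
  # mistakes the comma for a decimal separator
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           dec = ".",
                           colClasses = list(character = c("exon_starts", "exon_ends")))
  need <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("annotation ", path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (any(tab$tss < 0)) stop("annotation ", path, ": tss must be >= 0")
  if (anyDuplicated(paste(tab$gene_id, tab$tss))) stop("annotation ", path, ": duplicate (gene_id, tss)")
  starts <- lapply(strsplit(as.character(tab$exon_starts), ","), as.integer)
  ends <- lapply(strsplit(as.character(tab$exon_ends), ","), as.integer)
  n <- lengths(starts)
  if (any(n != lengths(ends))) stop("annotation ", path, ": exon_starts/exon_ends length mismatch")
  exons <- data.frame(gene_id = rep(tab$gene_id, n),
                      chrom = rep(tab$chrom, n),
                      start = unlist(starts), end = unlist(ends),
                      strand = rep(tab$strand, n))
  validate_intervals(exons, "annotation exons")
  list(tss = tab[, c("gene_id", "chrom", "strand", "tss")], exons = exons)
}

#' Exonic length per gene (union of exons)
#'
#' @param exons exon table from [read_annotation()].
#' @return named integer vector, bp of the exon union per gene.
#' @export
exonic_lengths <- function(exons) {
  gr <- intervals_to_granges(exons)
  by_gene <- S4Vectors::split(gr, exons$gene_id)
  len <- sum(IRanges::width(IRanges::reduce(by_gene, ignore.strand = TRUE)))
  out <- as.integer(len)
  names(out) <- names(len)
  if (any(out <= 0)) stop("gene with non-positive exonic length")
  out
}

#' Construct a tag library
#'
#' A tag library is the unit of ChIP/RNA signal: single-bp tag positions
#' (shifted read 5' ends) with strand, plus the retained tag count and
#' the fragment size used for shifting.
#'
#' @param tags data.frame with `chrom`, `pos`, `strand`.
#' @param fragment_size fragment length (bp) assumed when shifting.
#' @return object of class `tag_library`.
#' @export
tag_library <- function(tags, fragment_size = 150) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tags)))
  tags <- data.table::as.data.table(tags)[, c("chrom", "pos", "strand"), with = FALSE]
  tags[, pos := as.integer(pos)]
  data.table::setkey(tags, chrom, pos)
  structure(list(tags = tags, total_count = nrow(tags),
                 fragment_size = as.integer(fragment_size)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library:", x$total_count, "tags on",
      length(unique(x$tags$chrom)), "chromosome(s); fragment_size =",
      x$fragment_size, "bp\n")
  invisible(x)
}

#' Binned, depth-normalized coverage track
#'
#' Counts tags per fixed-width bin and scales by reads-per-million
#' (`1e6 / total_count`). Bins with zero tags are omitted, so the output
#' is ready for bedGraph/WIG export.
#'
#' @param tags a `tag_library`.
#' @param bin bin width in bp (>= 1).
#' @return data.frame `chrom`, `start`, `end`, `value` (RPM per bin).
#' @export
coverage_track <- function(tags, bin = 10) {
  stopifnot(inherits(tags, "tag_library"), bin >= 1)
  if (tags$total_count == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  }
  bin <- as.integer(bin)
  dt <- tags$tags[, .(count = .N), by = .(chrom, b = pos %/% bin)]
  data.table::setorder(dt, chrom, b)
  data.frame(chrom = dt$chrom, start = dt$b * bin, end = (dt$b + 1L) * bin,
             value = dt$count * 1e6 / tags$total_count)
}

#' Write a coverage track as bedGraph
#'
#' @param track data.frame from [coverage_track()].
#' @param path output path.
#' @param name track name for the header line.
#' @export
write_bedgraph <- function(track, path, name = "coverage") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  if (nrow(track)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", track$chrom, track$start,
                       track$end, track$value), con)
  }
  invisible(path)
}

#' Write a coverage track as variable-step WIG
#'
#' One `variableStep` block per chromosome; positions are 1-based per the
#' WIG convention, values are the binned RPM.
#'
#' @param track data.frame from [coverage_track()]; bins must share one width.
#' @param path output path.
#' @param name track name.
#' @export
write_wig <- function(track, path, name = "coverage") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
  if (nrow(track)) {
    span <- unique(track$end - track$start)
    if (length(span) != 1L) stop("write_wig requires a single bin width")
    for (ch in unique(track$chrom)) {
      sub <- track[track$chrom == ch, , drop = FALSE]
      writeLines(sprintf("variableStep chrom=%s span=%d", ch, span), con)
      writeLines(sprintf("%d\t%.6g", sub$start + 1L, sub$value), con)
    }
  }
  invisible(path)
}
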