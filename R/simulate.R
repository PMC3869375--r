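# Seeded synthetic-data generator. Emulates the statistical structure
# the pipeline assumes: a genome annotated with TSSs/gene models and
# non-overlapping regulatory elements; ChIP tag libraries with planted
# enrichment islands over uniform background for histone marks, TFs and
# MLL4 in control and knockout conditions (plus antibody-artifact sites
# present in both genotypes); and per-gene exonic counts with planted
# fold changes linked to the planted enhancer-gene assignments. Ground
# truth is carried alongside so parameter-recovery tests never re-derive
# it.

#' Simulation configuration
#'
#' Defaults define the standard study conditions used throughout the
#' test-suite and vignette: one 10-Mb chromosome, 500 genes, 600
#' enhancers, 200,000 tags per library at 50-fold peak enrichment.
#'
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_genes number of genes (TSSs placed uniformly).
#' @param n_active_promoters,n_silent_promoters promoter class counts
#'   (the remaining genes carry no promoter marks).
#' @param n_active_enhancers,n_silent_enhancers enhancer class counts.
#' @param p_cebp,p_pparg,p_both marginal and joint TF-occupancy
#'   probabilities per active enhancer.
#' @param p_cebpa,p_cebpb probability that a C/EBP-occupied enhancer is
#'   bound by each paralog (at least one is forced).
#' @param mll4_given_tf probability a TF-occupied active enhancer is
#'   MLL4+.
#' @param n_artifact_sites MLL4 antibody-artifact sites (signal in both
#'   genotypes).
#' @param tags_per_library tags per ChIP/RNA library.
#' @param enrichment_fold peak-to-background tag density ratio.
#' @param peak_width planted peak width in bp.
#' @param fragment_size,read_length read geometry in bp.
#' @param ko_effect fractional retention of knockout-dependent ChIP
#'   signal in deficient cells.
#' @param expr_effect fold induction at "day 2" of genes assigned to
#'   MLL4+ double-positive enhancers.
#' @param ko_expr_fold fold reduction of that induction in knockout
#'   cells (control/deficient expression ratio at day 2).
#' @param expr_dispersion negative-binomial size parameter for count
#'   noise.
#' @param expr_baseline_meanlog,expr_baseline_sdlog log-normal baseline
#'   expression parameters.
#' @param promoter_radius promoter territory half-width (bp), matching
#'   [classifier_params()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       chrom_lengths = c(chr1 = 1e7),
                       n_genes = 500L,
                       n_active_promoters = 300L, n_silent_promoters = 150L,
                       n_active_enhancers = 400L, n_silent_enhancers = 200L,
                       p_cebp = 0.6, p_pparg = 0.25, p_both = 0.15,
                       p_cebpa = 0.7, p_cebpb = 0.7,
                       mll4_given_tf = 0.6,
                       n_artifact_sites = 50L,
                       tags_per_library = 2e5,
                       enrichment_fold = 50,
                       peak_width = 600L,
                       fragment_size = 150L, read_length = 50L,
                       ko_effect = 0.1,
                       expr_effect = 4,
                       ko_expr_fold = 8,
                       expr_dispersion = 50,
                       expr_baseline_meanlog = log(20),
                       expr_baseline_sdlog = 0.8,
                       promoter_radius = 2500L) {
  stopifnot(seed == as.integer(seed),
            all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
            n_active_promoters + n_silent_promoters <= n_genes,
            p_both <= p_cebp, p_both <= p_pparg,
            p_cebp + p_pparg - p_both <= 1,
            mll4_given_tf >= 0, mll4_given_tf <= 1,
            enrichment_fold >= 1, ko_effect >= 0, ko_effect <= 1,
            expr_effect >= 1, ko_expr_fold >= 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed per simulation stream, kept below 2^31
sim_seed <- function(config, stream) {
  (config$seed * 1000L + stream) %% .Machine$integer.max
}

#' Simulate the genome annotation and ground-truth elements
#'
#' Sites (gene TSSs, enhancers, artifact sites) are placed on an evenly
#' spaced slot grid with bounded jitter and randomly permuted slot
#' assignment, which guarantees by construction that elements never
#' overlap and that every enhancer center lies further than
#' `promoter_radius` from every TSS. TF and MLL4 occupancy labels are
#' sampled per active enhancer; the planted knockout-dependent genes are
#' the nearest-TSS assignments of the MLL4+ C/EBP+PPARG+ enhancers.
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_annotation` with `tss`, `exons`, `genes`,
#'   `elements` (ground truth with occupancy flags), and `config`.
#' @export
simulate_annotation <- function(config = sim_config()) {
  set.seed(sim_seed(config, 1L))
  n_enh <- config$n_active_enhancers + config$n_silent_enhancers
  n_sites <- config$n_genes + n_enh + config$n_artifact_sites
  # single-chromosome placement keeps the packing argument simple;
  # multiple chromosomes get sites proportional to length
  chrom_of <- rep(names(config$chrom_lengths),
                  round(n_sites * config$chrom_lengths / sum(config$chrom_lengths)))
  chrom_of <- chrom_of[seq_len(min(length(chrom_of), n_sites))]
  if (length(chrom_of) < n_sites)
    chrom_of <- c(chrom_of, rep(names(config$chrom_lengths)[1], n_sites - length(chrom_of)))
  pos <- integer(n_sites)
  gene_body <- 2300L
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    slot_w <- floor(config$chrom_lengths[[ch]] / length(idx))
    jitter <- min(1000L, slot_w %/% 8L)
    min_gap <- slot_w - 2L * jitter
    if (min_gap <= config$promoter_radius + config$peak_width %/% 2L ||
        slot_w %/% 2L <= gene_body + jitter)
      stop("infeasible packing: too many elements for chromosome ", ch)
    pos[idx] <- as.integer((seq_along(idx) - 1L) * slot_w + slot_w %/% 2L +
                             sample(-jitter:jitter, length(idx), replace = TRUE))
  }
  role <- sample(rep(c("gene", "active_enhancer", "silent_enhancer", "artifact"),
                     c(config$n_genes, config$n_active_enhancers,
                       config$n_silent_enhancers, config$n_artifact_sites)))

  # genes: TSS at the site position, three exons downstream of the TSS
  gi <- which(role == "gene")
  strand <- sample(c("+", "-"), length(gi), replace = TRUE)
  gene_id <- sprintf("gene%04d", seq_along(gi))
  tss <- data.frame(gene_id = gene_id, chrom = chrom_of[gi],
                    strand = strand, tss = pos[gi])
  off_s <- c(0L, 1000L, 1800L); off_e <- c(500L, 1400L, 2300L)
  exons <- do.call(rbind, lapply(seq_along(gi), function(j) {
    t0 <- pos[gi[j]]
    if (strand[j] == "+") {
      data.frame(gene_id = gene_id[j], chrom = chrom_of[gi[j]],
                 start = t0 + off_s, end = t0 + off_e, strand = "+")
    } else {
      data.frame(gene_id = gene_id[j], chrom = chrom_of[gi[j]],
                 start = t0 + 1L - off_e, end = t0 + 1L - off_s, strand = "-")
    }
  }))
  prom_class <- sample(rep(c("active_promoter", "silent_promoter", "unmarked"),
                           c(config$n_active_promoters, config$n_silent_promoters,
                             config$n_genes - config$n_active_promoters -
                               config$n_silent_promoters)))
  genes <- cbind(tss, promoter_class = prom_class)

  # enhancers + artifacts as ground-truth elements
  ei <- which(role != "gene")
  w2 <- config$peak_width %/% 2L
  el <- data.frame(element_id = sprintf("el%04d", seq_along(ei)),
                   chrom = chrom_of[ei],
                   start = pos[ei] - w2, end = pos[ei] + w2,
                   center = pos[ei], class = role[ei],
                   stringsAsFactors = FALSE)
  n_act <- sum(el$class == "active_enhancer")
  occ <- sample(c("both", "cebp_only", "pparg_only", "none"), n_act, replace = TRUE,
                prob = c(config$p_both, config$p_cebp - config$p_both,
                         config$p_pparg - config$p_both,
                         1 - config$p_cebp - config$p_pparg + config$p_both))
  el$has_cebp <- el$has_pparg <- FALSE
  act <- el$class == "active_enhancer"
  el$has_cebp[act] <- occ %in% c("both", "cebp_only")
  el$has_pparg[act] <- occ %in% c("both", "pparg_only")
  el$has_cebpa <- el$has_cebpb <- FALSE
  cb <- which(el$has_cebp)
  el$has_cebpa[cb] <- stats::runif(length(cb)) < config$p_cebpa
  el$has_cebpb[cb] <- stats::runif(length(cb)) < config$p_cebpb
  neither <- cb[!el$has_cebpa[cb] & !el$has_cebpb[cb]]
  el$has_cebpb[neither] <- TRUE
  el$has_mll4 <- (el$has_cebp | el$has_pparg) &
    stats::runif(nrow(el)) < config$mll4_given_tf
  el$is_artifact <- el$class == "artifact"
  el$has_mll4[el$is_artifact] <- FALSE

  # planted knockout-dependent genes: nearest TSS of MLL4+ double positives
  dp <- el[el$has_mll4 & el$has_cebp & el$has_pparg, , drop = FALSE]
  planted <- unique(unlist(lapply(seq_len(nrow(dp)), function(i) {
    hit <- nearest_tss(dp$chrom[i], dp$center[i], tss, max_dist = 1e6)
    if (is.null(hit)) character(0) else hit$gene_id
  })))
  genes$planted_dependent <- genes$gene_id %in% planted

  structure(list(tss = tss, exons = exons, genes = genes, elements = el,
                 config = config),
            class = "sim_annotation")
}

# retention factor per element for a (target, condition) pair; NULL rows
# mean the element carries no signal for that target
target_sites <- function(ann, target, condition) {
  el <- ann$elements
  g <- ann$genes
  cfg <- ann$config
  prom <- function(classes) {
    data.frame(chrom = g$chrom[g$promoter_class %in% classes],
               center = g$tss[g$promoter_class %in% classes],
               retention = 1)
  }
  enh <- function(sel, dep = FALSE) {
    r <- rep(1, sum(sel))
    if (dep && condition == "ko") r <- ifelse(el$has_mll4[sel], cfg$ko_effect, 1)
    data.frame(chrom = el$chrom[sel], center = el$center[sel], retention = r)
  }
  is_enh <- el$class %in% c("active_enhancer", "silent_enhancer")
  switch(target,
    MLL4 = {
      sel <- el$has_mll4 | el$is_artifact
      r <- rep(1, sum(sel))
      if (condition == "ko") r <- ifelse(el$is_artifact[sel], 1, cfg$ko_effect)
      data.frame(chrom = el$chrom[sel], center = el$center[sel], retention = r)
    },
    H3K4ME1 = enh(is_enh, dep = TRUE),
    H3K4ME2 = enh(is_enh, dep = TRUE),
    H3K4ME3 = prom(c("active_promoter", "silent_promoter")),
    H3K27AC = rbind(enh(el$class == "active_enhancer", dep = TRUE),
                    prom("active_promoter")),
    CEBPA = enh(el$has_cebpa),
    CEBPB = enh(el$has_cebpb),
    PPARG = enh(el$has_pparg),
    POL2 = prom("active_promoter"),
    INPUT = data.frame(chrom = character(0), center = integer(0), retention = numeric(0)),
    stop("unknown target: ", target)
  )
}

#' Simulate a ChIP tag library as mapped reads
#'
#' Background reads are uniform over the genome; peak reads are uniform
#' within `peak_width` around the target's element centers at
#' `enrichment_fold` times the background density (scaled by the
#' knockout retention factor in the `ko` condition). Tag-count
#' allocation is multinomial at `tags_per_library` total. Each read is
#' emitted on a random strand with its 5' end offset by
#' `fragment_size/2`, so [preprocess_tags()] re-centers tags onto the
#' planted positions.
#'
#' @param ann a [simulate_annotation()] result.
#' @param target one of `MLL4`, `CEBPA`, `CEBPB`, `PPARG`, `H3K4ME1`,
#'   `H3K4ME2`, `H3K4ME3`, `H3K27AC`, `POL2`, `INPUT`.
#' @param condition `control` or `ko`.
#' @param config a [sim_config()]; defaults to the one inside `ann`.
#' @return data.frame of reads (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`), BED6-ready.
#' @export
simulate_chip_tags <- function(ann, target, condition = "control",
                               config = ann$config) {
  stopifnot(inherits(ann, "sim_annotation"),
            condition %in% c("control", "ko"))
  targets <- c("MLL4", "CEBPA", "CEBPB", "PPARG", "H3K4ME1", "H3K4ME2",
               "H3K4ME3", "H3K27AC", "POL2", "INPUT")
  stream <- 10L + match(target, targets) * 2L +
    match(condition, c("control", "ko"))
  set.seed(sim_seed(config, stream))
  sites <- target_sites(ann, target, condition)
  L <- config$chrom_lengths
  w <- config$peak_width
  weights <- c(as.numeric(L),
               config$enrichment_fold * w * sites$retention)
  counts <- as.integer(stats::rmultinom(1, config$tags_per_library,
                                        weights / sum(weights)))
  nbg <- length(L)
  # background tag centers, uniform per chromosome
  bg <- do.call(rbind, lapply(seq_len(nbg), function(i) {
    if (counts[i] == 0) return(NULL)
    data.frame(chrom = names(L)[i],
               t = sample.int(as.integer(L[[i]]), counts[i], replace = TRUE) - 1L)
  }))
  pk <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    n <- counts[nbg + i]
    if (n == 0) return(NULL)
    data.frame(chrom = sites$chrom[i],
               t = sites$center[i] - w %/% 2L +
                 sample.int(w, n, replace = TRUE) - 1L)
  }))
  tags <- rbind(bg, pk)
  if (is.null(tags) || !nrow(tags)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0), strand = character(0)))
  }
  shift <- config$fragment_size %/% 2L
  rl <- config$read_length
  strand <- sample(c("+", "-"), nrow(tags), replace = TRUE)
  five_p <- ifelse(strand == "+", tags$t - shift, tags$t + shift)
  start <- ifelse(strand == "+", five_p, five_p - rl + 1L)
  end <- start + rl
  keep <- start >= 0 & end <= as.numeric(L[tags$chrom])
  data.frame(chrom = tags$chrom[keep], start = as.integer(start[keep]),
             end = as.integer(end[keep]), name = ".", score = 0,
             strand = strand[keep])[order(tags$chrom[keep], start[keep]), ]
}

#' Simulate per-gene exonic counts across conditions
#'
#' Baseline expression is log-normal; planted knockout-dependent genes
#' (nearest-TSS targets of MLL4+ double-positive enhancers) are induced
#' `expr_effect`-fold at day 2 in control cells and that induction is
#' reduced `ko_expr_fold`-fold in knockout cells. Counts are
#' negative-binomial around library-scaled means. Samples:
#' `ctrl_D0`, `ctrl_D2`, `ko_D0`, `ko_D2`.
#'
#' @param ann a [simulate_annotation()] result.
#' @param config a [sim_config()]; defaults to the one inside `ann`.
#' @return list with `counts` (gene x sample matrix), `exonic_length`,
#'   `truth` (planted dependent gene ids) and `samples`.
#' @export
simulate_expression <- function(ann, config = ann$config) {
  stopifnot(inherits(ann, "sim_annotation"))
  set.seed(sim_seed(config, 99L))
  g <- ann$genes
  len <- exonic_lengths(ann$exons)[g$gene_id]
  n <- nrow(g)
  base <- stats::rlnorm(n, config$expr_baseline_meanlog, config$expr_baseline_sdlog)
  expr <- cbind(ctrl_D0 = base, ctrl_D2 = base, ko_D0 = base, ko_D2 = base)
  pl <- g$planted_dependent
  expr[pl, "ctrl_D2"] <- base[pl] * config$expr_effect
  expr[pl, "ko_D2"] <- base[pl] * config$expr_effect / config$ko_expr_fold
  counts <- sapply(colnames(expr), function(s) {
    mu <- expr[, s] * len / 1000
    mu <- mu / sum(mu) * config$tags_per_library
    stats::rnbinom(n, mu = mu, size = config$expr_dispersion)
  })
  rownames(counts) <- g$gene_id
  list(counts = counts, exonic_length = len,
       truth = g$gene_id[pl], samples = colnames(expr))
}

#' Write a complete simulated dataset to disk
#'
#' Produces the plain-text fixture layout the pipeline consumes:
#' `chrom.sizes`, `annotation.tsv` (gene/TSS/exon table),
#' `reads_<target>_<condition>.bed` for every role the pipeline needs,
#' `expression_counts.tsv`, and ground-truth tables
#' `truth_elements.tsv` / `truth_genes.tsv`.
#'
#' @param config a [sim_config()] object.
#' @param dir output directory (created if needed).
#' @return list with the annotation object, expression simulation, and a
#'   `files` manifest of written paths.
#' @export
simulate_dataset <- function(config = sim_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  files <- list()
  files$chrom_sizes <- file.path(dir, "chrom.sizes")
  utils::write.table(data.frame(names(config$chrom_lengths),
                                as.integer(config$chrom_lengths)),
                     files$chrom_sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ex <- ann$exons
  agg_s <- tapply(ex$start, ex$gene_id, function(v) paste(v, collapse = ","))
  agg_e <- tapply(ex$end, ex$gene_id, function(v) paste(v, collapse = ","))
  tss <- ann$tss
  anno <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                     strand = tss$strand, tss = tss$tss,
                     exon_starts = as.character(agg_s[tss$gene_id]),
                     exon_ends = as.character(agg_e[tss$gene_id]))
  files$annotation <- file.path(dir, "annotation.tsv")
  data.table::fwrite(anno, files$annotation, sep = "\t", quote = FALSE)

  roles <- list(mll4_control = c("MLL4", "control"),
                mll4_ko = c("MLL4", "ko"),
                input = c("INPUT", "control"),
                me1 = c("H3K4ME1", "control"),
                me3 = c("H3K4ME3", "control"),
                k27ac = c("H3K27AC", "control"),
                cebpa = c("CEBPA", "control"),
                cebpb = c("CEBPB", "control"),
                pparg = c("PPARG", "control"))
  for (role in names(roles)) {
    reads <- simulate_chip_tags(ann, roles[[role]][1], roles[[role]][2])
    files[[paste0("reads_", role)]] <- file.path(dir, paste0("reads_", role, ".bed"))
    write_bed(reads, files[[paste0("reads_", role)]])
  }

  expr <- simulate_expression(ann)
  files$expression <- file.path(dir, "expression_counts.tsv")
  data.table::fwrite(data.frame(gene_id = rownames(expr$counts), expr$counts),
                     files$expression, sep = "\t", quote = FALSE)

  files$truth_elements <- file.path(dir, "truth_elements.tsv")
  data.table::fwrite(ann$elements, files$truth_elements, sep = "\t", quote = FALSE)
  files$truth_genes <- file.path(dir, "truth_genes.tsv")
  data.table::fwrite(ann$genes, files$truth_genes, sep = "\t", quote = FALSE)

  list(annotation = ann, expression = expr, files = files)
}
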