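# End-to-end orchestration: manifest-driven island calling, specificity
# filtering, chromatin-state classification, co-localization statistics,
# expression calls and enhancer-to-gene assignment, writing plain
# TSV/BED outputs plus one machine-readable JSON summary. Every stage is
# a pure function of the inputs and configuration, so re-running a
# config reproduces identical outputs.

required_roles <- c("mll4_control", "mll4_ko", "input", "me1", "me3",
                    "k27ac", "cebpa", "cebpb", "pparg")

#' Build a pipeline configuration
#'
#' @param samples named list mapping roles (`mll4_control`, `mll4_ko`,
#'   `input`, `me1`, `me3`, `k27ac`, `cebpa`, `cebpb`, `pparg`) to read
#'   BED paths.
#' @param chrom_sizes path to a two-column chrom/length table, or a
#'   named numeric vector.
#' @param annotation path to the gene annotation table
#'   (see [read_annotation()]).
#' @param expression_counts path to a TSV of per-gene exonic counts with
#'   columns `gene_id`, `ctrl_D0`, `ctrl_D2`, `ko_D0`, `ko_D2`.
#' @param out_dir output directory.
#' @param histone_fdr,factor_fdr,specificity_fdr island/filter FDR
#'   thresholds.
#' @param promoter_radius promoter territory half-width (bp).
#' @param fragment_size assumed fragment length (bp).
#' @param top_n_emergent rank cutoff used when emergent sets are
#'   computed (kept in the config for reproducibility of reports).
#' @param max_assign_dist enhancer-to-gene assignment cutoff (bp).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, chrom_sizes, annotation,
                            expression_counts, out_dir,
                            histone_fdr = 1e-3, factor_fdr = 1e-15,
                            specificity_fdr = 1e-15,
                            promoter_radius = 2500L, fragment_size = 150L,
                            top_n_emergent = 2000L, max_assign_dist = 1e6) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

read_chrom_sizes <- function(x) {
  if (is.numeric(x)) return(x)
  tab <- data.table::fread(x, header = FALSE, data.table = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: read and preprocess every ChIP library;
#' call islands against the input library (window 200 bp / histone FDR
#' for marks, window 50 bp / factor FDR for MLL4 and TFs); apply the
#' knockout specificity filter to MLL4; classify regulatory elements;
#' distribute MLL4 peaks over element classes with a binomial
#' length-fraction enrichment test; group lineage enhancers and test
#' MLL4 co-localization enrichment (hypergeometric); compute RPKM,
#' regulation (day 2 vs day 0), knockout dependence and its enrichment
#' among up-regulated genes; assign enhancers to genes and summarize
#' fold changes per category. All tables are written under
#' `config$out_dir` together with `summary.json` and a run log.
#'
#' Fails before any stage runs if a required sample role is missing.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  miss <- setdiff(required_roles, names(config$samples))
  if (length(miss)) {
    stop("missing required sample role(s): ", paste(miss, collapse = ", "))
  }
  for (role in required_roles) {
    if (!file.exists(config$samples[[role]]))
      stop("sample file for role ", role, " not found: ", config$samples[[role]])
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("pipeline run: %d sample roles", length(config$samples)))
  chrom_lengths <- read_chrom_sizes(config$chrom_sizes)
  anno <- read_annotation(config$annotation)

  histone_params <- island_params(window_size = 200L,
                                  fdr_threshold = config$histone_fdr,
                                  fragment_size = config$fragment_size)
  factor_params <- island_params(window_size = 50L,
                                 fdr_threshold = config$factor_fdr,
                                 fragment_size = config$fragment_size)
  role_params <- list(mll4_control = factor_params, mll4_ko = factor_params,
                      me1 = histone_params, me3 = histone_params,
                      k27ac = histone_params, cebpa = factor_params,
                      cebpb = factor_params, pparg = factor_params)

  libs <- lapply(required_roles, function(role) {
    p <- if (is.null(role_params[[role]])) factor_params else role_params[[role]]
    preprocess_tags(read_bed(config$samples[[role]]), p)
  })
  names(libs) <- required_roles

  islands <- list()
  for (role in setdiff(required_roles, c("input", "mll4_ko"))) {
    p <- role_params[[role]]
    islands[[role]] <- call_islands(libs[[role]], libs$input, chrom_lengths, p)
    write_islands(islands[[role]],
                  file.path(config$out_dir, paste0("islands_", role, ".bed")),
                  file.path(config$out_dir, paste0("islands_", role, ".tsv")))
    log_lines <- c(log_lines, sprintf("islands %s: %d (W=%d, FDR<%g)", role,
                                      nrow(islands[[role]]), p$window_size,
                                      p$fdr_threshold))
  }
  mll4 <- specificity_filter(islands$mll4_control, libs$mll4_control,
                             libs$mll4_ko, fdr = config$specificity_fdr)
  write_islands(mll4, file.path(config$out_dir, "islands_mll4_filtered.bed"),
                file.path(config$out_dir, "islands_mll4_filtered.tsv"))
  log_lines <- c(log_lines, sprintf("MLL4 islands after specificity filter: %d", nrow(mll4)))

  cls_params <- classifier_params(config$promoter_radius)
  elements <- classify_elements(islands$me1, islands$me3, islands$k27ac,
                                anno$tss, cls_params)
  el_bed <- data.frame(chrom = elements$chrom, start = elements$start,
                       end = elements$end, name = elements$element_class,
                       score = 0, strand = ".")
  write_bed(el_bed, file.path(config$out_dir, "elements.bed"))
  class_counts <- table(factor(elements$element_class, element_class_levels))

  dist <- distribute_peaks(mll4[, c("chrom", "start", "end")], elements)
  data.table::fwrite(dist, file.path(config$out_dir, "mll4_distribution.tsv"),
                     sep = "\t", quote = FALSE)

  # binomial enrichment of MLL4 on active enhancers, background = active
  # enhancer fraction of total element length
  el_len <- tapply(elements$end - elements$start, elements$element_class, sum)
  p0 <- unname(el_len["active_enhancer"] / sum(el_len))
  on_elements <- dist$count[match(element_class_levels, dist$class)]
  n_on <- sum(on_elements, na.rm = TRUE)
  k_ae <- dist$count[dist$class == "active_enhancer"]
  binom_lp <- if (n_on > 0 && p0 > 0 && p0 < 1) log10_binomial_tail(n_on, k_ae, p0) else NA_real_

  active_enh <- elements[elements$element_class == "active_enhancer", , drop = FALSE]
  grouped <- group_lineage_enhancers(active_enh, islands$cebpa, islands$cebpb,
                                     islands$pparg, mll4)
  data.table::fwrite(grouped, file.path(config$out_dir, "lineage_enhancers.tsv"),
                     sep = "\t", quote = FALSE)
  group_counts <- table(grouped$group, useNA = "no")
  n_bound <- sum(!is.na(grouped$group))
  mll4_on_bound <- sum(grouped$has_mll4 & !is.na(grouped$group))

  # expression calls
  expr_tab <- data.table::fread(config$expression_counts, data.table = FALSE)
  len <- exonic_lengths(anno$exons)[expr_tab$gene_id]
  samples <- c("ctrl_D0", "ctrl_D2", "ko_D0", "ko_D2")
  rpkm <- sapply(samples, function(s) {
    compute_rpkm(expr_tab[[s]], len, sum(expr_tab[[s]]))
  })
  rownames(rpkm) <- expr_tab$gene_id
  ep <- expression_params()
  expressed <- rownames(rpkm)[rpkm[, "ctrl_D0"] > ep$expressed_rpkm |
                                rpkm[, "ctrl_D2"] > ep$expressed_rpkm]
  reg <- classify_regulation(rpkm[expressed, "ctrl_D0"], rpkm[expressed, "ctrl_D2"], ep)
  dep <- classify_dependence(rpkm[expressed, "ctrl_D2"], rpkm[expressed, "ko_D2"], ep)
  upregulated <- expressed[reg == "up"]
  dependent <- expressed[dep]
  enr <- dependence_enrichment(expressed, dependent, upregulated)

  expr_out <- data.frame(gene_id = expr_tab$gene_id, expr_tab[, samples],
                         rpkm = rpkm,
                         regulation = ifelse(expr_tab$gene_id %in% expressed,
                                             reg[match(expr_tab$gene_id, expressed)], NA),
                         dependent = expr_tab$gene_id %in% dependent)
  data.table::fwrite(expr_out, file.path(config$out_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE)

  # enhancer-to-gene assignment and fold-change summary per category
  assigned <- assign_enhancers_to_genes(grouped, anno$tss, config$max_assign_dist)
  data.table::fwrite(assigned, file.path(config$out_dir, "gene_categories.tsv"),
                     sep = "\t", quote = FALSE)
  fc_table <- data.frame(
    gene_id = expressed,
    log2_fc = log2((rpkm[expressed, "ko_D2"] + ep$pseudo_rpkm) /
                     (rpkm[expressed, "ctrl_D2"] + ep$pseudo_rpkm)),
    induced = reg == "up")
  groups <- split(assigned$gene_id, paste(assigned$category, assigned$mll4_status))
  fc_summary <- tryCatch(suppressWarnings(group_foldchange_summary(groups, fc_table)),
                         error = function(e) NULL)
  if (!is.null(fc_summary)) {
    data.table::fwrite(fc_summary$summary,
                       file.path(config$out_dir, "category_foldchange.tsv"),
                       sep = "\t", quote = FALSE)
  }

  summary <- list(
    islands = lapply(islands, nrow),
    mll4_filtered = nrow(mll4),
    element_counts = as.list(class_counts),
    mll4_distribution = stats::setNames(as.list(dist$count), dist$class),
    active_enhancer_length_fraction = p0,
    mll4_on_active_enhancer_log10_binomial_p = binom_lp,
    lineage_groups = as.list(group_counts),
    mll4_on_bound_enhancers = list(k = mll4_on_bound, n = n_bound,
                                   percent = if (n_bound) percent(mll4_on_bound, n_bound) else NA),
    expression = list(n_expressed = length(expressed),
                      n_upregulated = length(upregulated),
                      n_dependent = length(dependent),
                      enrichment = enr),
    n_genes_with_category = nrow(assigned))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(log_lines,
                 sprintf("elements: %s",
                         paste(names(class_counts), class_counts, collapse = ", ")),
                 sprintf("expressed=%d up=%d dependent=%d overlap=%d log10p=%.2f",
                         enr$N, enr$n, enr$K, enr$k, enr$log10_p))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(summary)
}
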