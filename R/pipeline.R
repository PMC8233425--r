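#' Read a pipeline configuration file
#'
#' YAML file holding input paths and thresholds. Recognised keys: `genome`,
#' `gene_table` (path or `"human_rcrs"`/`"mouse"`), `variants`, `evidence`,
#' `counts`, `condition` (sample -> ref/test map), `gmt`, `cohort`,
#' `out_dir`, `seed`, and a `thresholds` block (`grantham_min`,
#' `mutpred_min`, `alpha`, `pseudocount`, `homoplasmy_threshold`,
#' `min_identity`). Missing thresholds fall back to the documented defaults
#' and every effective value is logged, so there are no silent defaults.
#'
#' @param path YAML config path; `NULL` for an all-defaults config.
#' @param ... Overrides applied after file parsing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  th <- cfg$thresholds
  defaults <- list(grantham_min = 50, mutpred_min = 0.7, alpha = 0.01,
                   pseudocount = 0.5, homoplasmy_threshold = 0.95,
                   min_identity = 1.0)
  for (nm in names(defaults)) {
    if (is.null(th[[nm]])) th[[nm]] <- defaults[[nm]]
  }
  stopifnot(th$grantham_min > 0, th$mutpred_min >= 0, th$mutpred_min <= 1,
            th$alpha > 0, th$alpha < 1, th$pseudocount > 0,
            th$homoplasmy_threshold > 0, th$homoplasmy_threshold <= 1,
            th$min_identity >= 0, th$min_identity <= 1)
  cfg$thresholds <- th
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "pipeline_config"
  cfg
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

log_thresholds <- function(cfg) {
  th <- cfg$thresholds
  log_msg("thresholds: grantham_min=", th$grantham_min,
          " mutpred_min=", th$mutpred_min, " alpha=", th$alpha,
          " pseudocount=", th$pseudocount,
          " homoplasmy_threshold=", th$homoplasmy_threshold,
          " min_identity=", th$min_identity)
}

resolve_gene_table <- function(cfg, genome = NULL) {
  gt <- cfg$gene_table
  if (is.null(gt)) stop("config needs a gene_table", call. = FALSE)
  if (gt %in% c("human_rcrs", "mouse")) {
    builtin_gene_table(gt)
  } else {
    read_gene_table(gt, genome_length = genome$length)
  }
}

require_input <- function(path, what) {
  if (is.null(path)) {
    stop("config is missing the ", what, " input", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  path
}

write_output <- function(df, cfg, name) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$out_dir, name)
  con <- file(path, "w")
  writeLines(paste0("# mitomct4 ",
                    as.character(utils::packageVersion("mitomct4")),
                    " seed=", cfg$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Annotate variants and classify pathogenicity
#'
#' Composes genome loading, variant annotation, evidence merging, criterion
#' evaluation and rule-based classification into one table, one row per
#' variant, with a per-verdict summary in the log.
#'
#' @param cfg A [pipeline_config()] with `genome`, `gene_table`, `variants`
#'   and optionally `evidence` set (or pass pre-loaded objects).
#' @param genome,features,variants,evidence Optional pre-loaded objects
#'   overriding the config paths.
#' @return The annotated + scored data.frame, invisibly when written.
#' @export
run_annotate <- function(cfg = pipeline_config(), genome = NULL,
                         features = NULL, variants = NULL, evidence = NULL) {
  log_thresholds(cfg)
  if (is.null(genome)) {
    genome <- load_genome(require_input(cfg$genome, "genome FASTA"))
  }
  if (is.null(features)) features <- resolve_gene_table(cfg, genome)
  if (is.null(variants)) {
    variants <- read_variants(require_input(cfg$variants, "variant table"))
  }
  if (is.null(evidence) && !is.null(cfg$evidence)) {
    evidence <- read_evidence(require_input(cfg$evidence, "evidence table"))
  }
  annotated <- annotate_variants(genome, features, variants)
  if (!is.null(evidence)) annotated <- merge_evidence(annotated, evidence)
  if (nrow(annotated)) {
    annotated$plasmy <- plasmy_status(annotated$heteroplasmy,
                                      cfg$thresholds$homoplasmy_threshold)
  }
  scored <- if (nrow(annotated)) {
    score_pathogenicity(
      annotated,
      thresholds = list(grantham_min = cfg$thresholds$grantham_min,
                        mutpred_min = cfg$thresholds$mutpred_min))
  } else {
    annotated
  }
  if (nrow(scored)) {
    counts <- table(scored$verdict)
    log_msg("verdicts: ",
            paste(names(counts), counts, sep = "=", collapse = " "))
  } else {
    log_msg("no variants to annotate")
  }
  write_output(scored, cfg, "annotated_variants.tsv")
  invisible(scored)
}

#' Expression contrast and pathway enrichment
#'
#' Computes the per-gene CPM contrast (sorted by root-square deviation,
#' descending) and, when a GMT catalog is configured, Fisher
#' over-representation of the top-deviating genes plus per-pathway mean
#' log2 fold changes.
#'
#' @param cfg A [pipeline_config()] with `counts` + `condition`
#'   (+ optional `gmt`, `top_n`).
#' @param matrix,catalog Optional pre-loaded objects overriding paths.
#' @return List with `contrast`, `top` and (optionally) `enrichment`,
#'   `pathway_means`.
#' @export
run_expression <- function(cfg = pipeline_config(), matrix = NULL,
                           catalog = NULL) {
  log_thresholds(cfg)
  if (is.null(matrix)) {
    path <- require_input(cfg$counts, "count matrix")
    if (is.null(cfg$condition)) {
      stop("config is missing the condition map", call. = FALSE)
    }
    matrix <- read_count_matrix(path, unlist(cfg$condition))
  }
  records <- log_fold_change(matrix, pseudocount = cfg$thresholds$pseudocount)
  records <- records[order(-records$rsd, records$gene), , drop = FALSE]
  top_n <- if (is.null(cfg$top_n)) 5L else cfg$top_n
  out <- list(contrast = records,
              top = rank_top(records, top_n, "up"))
  log_msg("top ", top_n, " upregulated: ", paste(out$top, collapse = ", "))
  if (is.null(catalog) && !is.null(cfg$gmt)) {
    catalog <- read_gmt(require_input(cfg$gmt, "GMT catalog"))
  }
  if (!is.null(catalog)) {
    n_query <- if (is.null(cfg$query_size)) {
      max(25L, ceiling(nrow(records) * 0.05))
    } else {
      cfg$query_size
    }
    query <- rank_top(records, n_query, "deviation")
    out$enrichment <- fisher_enrichment(query, catalog,
                                        alpha = cfg$thresholds$alpha)
    out$pathway_means <- pathway_mean_logfc(records, catalog)
    log_msg(sum(out$enrichment$significant), " pathway(s) significant at p < ",
            cfg$thresholds$alpha)
  } else {
    log_msg("no pathway catalog supplied; enrichment skipped")
  }
  write_output(records, cfg, "expression_contrast.tsv")
  if (!is.null(out$enrichment)) {
    write_output(out$enrichment, cfg, "pathway_enrichment.tsv")
  }
  invisible(out)
}

#' Cohort association analysis
#'
#' Builds the mutation x strong-MCT4 2x2 table from the tissue cohort,
#' tests it with the Yates-corrected chi-square, and reports the per-tissue
#' strong-positive calls.
#'
#' @param cfg A [pipeline_config()] with `cohort` set.
#' @param cohort Optional pre-loaded cohort data.frame.
#' @param skip_bad Drop records with unresolvable IHC entries instead of
#'   aborting.
#' @return List with `cohort` (incl. `strong_positive` calls), `table` and
#'   `test` (a `contingency_result`).
#' @export
run_association <- function(cfg = pipeline_config(), cohort = NULL,
                            skip_bad = FALSE) {
  if (is.null(cohort)) {
    cohort <- read_cohort(require_input(cfg$cohort, "cohort table"))
  }
  strong <- vapply(seq_len(nrow(cohort)), function(i) {
    tryCatch(strong_positive(cohort[i, , drop = FALSE]),
             error = function(e) NA)
  }, logical(1))
  if (any(is.na(strong))) {
    bad <- cohort$id[is.na(strong)]
    if (!skip_bad) {
      stop("unresolvable IHC entries for: ", paste(bad, collapse = ", "),
           " (use skip_bad = TRUE to drop them)", call. = FALSE)
    }
    log_msg("dropping ", length(bad), " record(s) with unresolvable IHC")
    cohort <- cohort[!is.na(strong), , drop = FALSE]
    strong <- strong[!is.na(strong)]
  }
  cohort$strong_positive <- strong
  tab <- build_mutation_mct4_table(cohort)
  test <- chi2_yates(tab)
  log_msg(sprintf("2x2 [[%d,%d],[%d,%d]]; chi2 = %.3f, p = %.4g",
                  tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                  test$chi2, test$p))
  write_output(cohort, cfg, "cohort_calls.tsv")
  list(cohort = cohort, table = tab, test = test)
}

#' Generate a synthetic dataset bundle on disk
#'
#' Writes the synthetic genome (FASTA), gene table, variants, counts,
#' pathway catalog (GMT), cohort and metastasis tables plus the planted
#' truth sidecars into `cfg$out_dir`, using the same formats the pipeline
#' reads.
#'
#' @param cfg A [pipeline_config()]; `seed` drives the generators.
#' @return Invisible list of the generated objects.
#' @export
run_simulate <- function(cfg = pipeline_config()) {
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gc <- generator_config(seed = cfg$seed)
  gen <- synth_genome(gc)
  write_genome(gen$genome, file.path(out_dir, "synthetic_genome.fasta"))
  utils::write.table(gen$features, file.path(out_dir, "gene_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gen$variants, file.path(out_dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(gen$truth, file.path(out_dir, "genome_truth.json"))
  cnt <- synth_counts(gc)
  counts_df <- data.frame(gene = rownames(cnt$matrix$counts),
                          cnt$matrix$counts, check.names = FALSE)
  utils::write.table(counts_df, file.path(out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gmt_lines <- vapply(names(cnt$catalog$pathways), function(id) {
    paste(c(id, "synthetic", cnt$catalog$pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, file.path(out_dir, "pathways.gmt"))
  write_truth(cnt$truth, file.path(out_dir, "counts_truth.json"))
  coh <- synth_cohort(gc)
  utils::write.table(coh$cohort, file.path(out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(coh$truth, file.path(out_dir, "cohort_truth.json"))
  met <- synth_metastasis(gc)
  met_df <- data.frame(
    group = rep(c("group1", "group2"),
                c(length(met$group1), length(met$group2))),
    animal = c(seq_along(met$group1), seq_along(met$group2)),
    count = c(met$group1, met$group2))
  utils::write.table(met_df, file.path(out_dir, "metastasis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(met$truth, file.path(out_dir, "metastasis_truth.json"))
  log_msg("synthetic bundle written to ", out_dir)
  invisible(list(genome = gen, counts = cnt, cohort = coh, metastasis = met))
}

#' Run every configured stage
#'
#' @param cfg A [pipeline_config()].
#' @return Invisible list of the stage results that could run.
#' @export
run_all <- function(cfg = pipeline_config()) {
  out <- list()
  if (!is.null(cfg$variants)) out$annotate <- run_annotate(cfg)
  if (!is.null(cfg$counts)) out$expression <- run_expression(cfg)
  if (!is.null(cfg$cohort)) out$association <- run_association(cfg)
  invisible(out)
}
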