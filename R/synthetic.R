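#' Configuration for the synthetic-data generator
#'
#' One object parameterises all four generators. Defaults emulate the study
#' conditions the pipeline was built around: a mouse-style 16,299-nt circular
#' genome with heavy- and light-strand protein genes; a two-condition count
#' matrix with one library per condition (a cybrid-vs-cybrid contrast),
#' log-normal gene baselines and negative-binomial counts; a 17-tissue
#' cohort with mutation prevalence 9/17 and status-specific Beta-distributed
#' IHC percentages (mutation: Beta(3, 1) scaled to \[0,100\], strong-positive
#' probability 0.875 = 8/9-like; none: Beta(1, 3), 0.125 = 1/8-like); and
#' per-mouse metastasis counts for two groups sized 6 and 7 with
#' negative-binomial means 1 and 38.
#'
#' One global `seed` drives everything; each generator draws from its own
#' sub-stream (`seed * 10 + offset`) so stages can be regenerated
#' independently.
#'
#' @param seed Integer master seed.
#' @param genome_length Genome length (nt).
#' @param gene_layout Gene feature data.frame; default the built-in
#'   mouse-style table (rescaled check against `genome_length`).
#' @param n_variants Number of random substitutions to plant.
#' @param n_insertions Number of frame-disrupting single-base insertions.
#' @param n_genes,n_samples_per_condition Count-matrix dimensions.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline expression.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param lib_size Expected library size per sample.
#' @param planted_de Named numeric vector: gene -> planted log2 fold change
#'   (test vs ref).
#' @param planted_pathway_shift List with `pathway` (symbol vector) and
#'   `mean_logfc`, or `NULL`.
#' @param n_pathways,pathway_size Random catalog shape for enrichment tests.
#' @param n_tissues,prevalence Cohort size and mutation prevalence.
#' @param ihc_beta_mutation,ihc_beta_none `c(shape1, shape2)` of the scaled
#'   Beta IHC-percent distributions per mutation status.
#' @param metastasis_n,metastasis_mu,metastasis_size Two-group per-mouse
#'   metastasis count model (group sizes, NB means, NB size parameters).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             genome_length = 16299L,
                             gene_layout = NULL,
                             n_variants = 5L,
                             n_insertions = 1L,
                             n_genes = 2000L,
                             n_samples_per_condition = 1L,
                             baseline_meanlog = 4,
                             baseline_sdlog = 1.5,
                             dispersion = 0.05,
                             lib_size = 2e6,
                             planted_de = numeric(0),
                             planted_pathway_shift = NULL,
                             n_pathways = 50L,
                             pathway_size = 40L,
                             n_tissues = 17L,
                             prevalence = 9 / 17,
                             ihc_beta_mutation = c(3, 1),
                             ihc_beta_none = c(1, 3),
                             metastasis_n = c(6L, 7L),
                             metastasis_mu = c(1, 38),
                             metastasis_size = c(0.7, 5)) {
  stopifnot(genome_length > 0, n_genes > 0, n_samples_per_condition >= 1,
            dispersion > 0, lib_size > 0, n_tissues > 0,
            prevalence > 0, prevalence < 1,
            all(metastasis_n > 0), all(metastasis_mu > 0),
            all(metastasis_size > 0))
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              gene_layout = gene_layout, n_variants = n_variants,
              n_insertions = n_insertions, n_genes = n_genes,
              n_samples_per_condition = n_samples_per_condition,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, dispersion = dispersion,
              lib_size = lib_size, planted_de = planted_de,
              planted_pathway_shift = planted_pathway_shift,
              n_pathways = n_pathways, pathway_size = pathway_size,
              n_tissues = n_tissues, prevalence = prevalence,
              ihc_beta_mutation = ihc_beta_mutation,
              ihc_beta_none = ihc_beta_none,
              metastasis_n = metastasis_n, metastasis_mu = metastasis_mu,
              metastasis_size = metastasis_size)
  class(cfg) <- "generator_config"
  cfg
}

# per-stream sub-seed, kept well below 2^31
stream_seed <- function(cfg, offset) {
  (abs(cfg$seed) %% 100000000L) * 10L + offset
}

with_stream <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(cfg, offset))
  expr
}

#' Synthetic mitochondrial genome with planted variants
#'
#' Generates a random circular genome over the configured gene layout and
#' plants random substitutions inside protein genes plus frame-disrupting
#' single-base insertions. The true coding effect of every planted variant
#' is derived at generation time by direct codon arithmetic (independent of
#' the annotator) and recorded in the returned truth table.
#'
#' @param config A [generator_config()].
#' @return List: `genome` (a `mito_genome`), `features`, `variants`
#'   (data.frame) and `truth` (data.frame of expected coding effects).
#' @export
synth_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  features <- config$gene_layout
  if (is.null(features)) features <- builtin_gene_table("mouse")
  features <- validate_gene_features(features)
  if (max(features$end) > config$genome_length) {
    stop("gene layout does not fit in genome_length", call. = FALSE)
  }
  code <- mito_genetic_code()
  with_stream(config, 1L, {
    seq <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                        replace = TRUE), collapse = "")
    genome <- mito_genome(seq, accession = "synthetic_mito",
                          species = "synthetic")
    prot <- features[features$kind == "protein", , drop = FALSE]
    variants <- list(); truth <- list()
    for (i in seq_len(config$n_variants)) {
      # redraw until the site lies in exactly one protein gene, so the
      # planted truth is unambiguous under first-match annotation
      repeat {
        gi <- sample(nrow(prot), 1L)
        feat <- prot[gi, , drop = FALSE]
        n_codons <- (feat$end - feat$start + 1L) %/% 3L
        codon_index <- sample(n_codons, 1L)
        pos_in_codon <- sample(3L, 1L)
        offset <- (codon_index - 1L) * 3L + (pos_in_codon - 1L)
        pos <- if (feat$strand == "L") feat$end - offset else
               feat$start + offset
        if (sum(pos >= prot$start & pos <= prot$end) == 1L) break
      }
      ref <- substr(genome$sequence, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      # expected effect by direct codon arithmetic on the coding strand
      cds <- extract_cds(genome, feat)
      codon_start <- (codon_index - 1L) * 3L + 1L
      ref_codon <- substr(cds, codon_start, codon_start + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, pos_in_codon, pos_in_codon) <-
        if (feat$strand == "L") complement_base(alt) else alt
      ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
      cls <- if (ref_aa == alt_aa) "synonymous" else
             if (alt_aa == "*") "nonsense" else "missense"
      variants[[length(variants) + 1L]] <-
        variant(pos, ref, alt, sample = sprintf("synth%02d", i))
      truth[[length(truth) + 1L]] <-
        data.frame(sample = sprintf("synth%02d", i), position = pos,
                   gene = feat$name, codon_index = codon_index,
                   ref_aa = ref_aa, alt_aa = alt_aa, effect_class = cls,
                   stringsAsFactors = FALSE)
    }
    for (i in seq_len(config$n_insertions)) {
      repeat {
        gi <- sample(nrow(prot), 1L)
        feat <- prot[gi, , drop = FALSE]
        pos <- sample(seq.int(feat$start, feat$end - 1L), 1L)
        if (sum(pos >= prot$start & pos < prot$end) == 1L) break
      }
      base <- sample(c("A", "C", "G", "T"), 1L)
      sample_id <- sprintf("synthins%02d", i)
      variants[[length(variants) + 1L]] <-
        variant(pos, "", base, kind = "insertion", sample = sample_id)
      offset <- if (feat$strand == "L") feat$end - pos else pos - feat$start
      truth[[length(truth) + 1L]] <-
        data.frame(sample = sample_id, position = pos, gene = feat$name,
                   codon_index = offset %/% 3L + 1L,
                   ref_aa = NA_character_, alt_aa = NA_character_,
                   effect_class = "frameshift", stringsAsFactors = FALSE)
    }
    list(genome = genome, features = features,
         variants = do.call(rbind, variants), truth = do.call(rbind, truth))
  })
}

#' Synthetic two-condition count matrix with planted effects
#'
#' Gene baselines are log-normal; counts are negative-binomial around
#' library-size-scaled baselines. Planted differentially-expressed genes are
#' shifted by their specified log2 fold change in the test condition;
#' a planted pathway shift moves every member by the pathway mean. A random
#' pathway catalog over the gene universe is generated alongside for
#' enrichment testing.
#'
#' @param config A [generator_config()].
#' @return List: `matrix` (a `count_matrix`), `catalog`
#'   (a `pathway_catalog`), `truth` (planted log2 fold changes and pathway
#'   shift).
#' @export
synth_counts <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_stream(config, 2L, {
    genes <- sprintf("gene%05d", seq_len(config$n_genes))
    baseline <- stats::rlnorm(config$n_genes,
                              meanlog = config$baseline_meanlog,
                              sdlog = config$baseline_sdlog)
    names(baseline) <- genes
    lfc <- stats::setNames(numeric(config$n_genes), genes)
    planted <- config$planted_de
    if (length(planted)) {
      bad <- setdiff(names(planted), genes)
      if (length(bad)) {
        stop("planted_de names outside the gene universe: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      lfc[names(planted)] <- planted
    }
    shift <- config$planted_pathway_shift
    if (!is.null(shift)) {
      lfc[intersect(shift$pathway, genes)] <-
        lfc[intersect(shift$pathway, genes)] + shift$mean_logfc
    }
    k <- config$n_samples_per_condition
    condition <- stats::setNames(rep(c("ref", "test"), each = k),
                                 c(sprintf("ref_%d", seq_len(k)),
                                   sprintf("test_%d", seq_len(k))))
    size <- 1 / config$dispersion
    counts <- vapply(names(condition), function(s) {
      lam <- baseline * if (condition[[s]] == "test") 2^lfc else 1
      mu <- lam / sum(lam) * config$lib_size
      stats::rnbinom(config$n_genes, mu = mu, size = size)
    }, numeric(config$n_genes))
    rownames(counts) <- genes
    catalog <- local({
      sets <- lapply(seq_len(config$n_pathways), function(i) {
        sample(genes, min(config$pathway_size, config$n_genes))
      })
      names(sets) <- sprintf("path%03d", seq_len(config$n_pathways))
      if (!is.null(shift)) sets[["planted_shift"]] <- shift$pathway
      pathway_catalog(sets, universe = genes)
    })
    list(matrix = count_matrix(counts, condition), catalog = catalog,
         truth = list(logfc = lfc[lfc != 0],
                      pathway_shift = shift))
  })
}

#' Synthetic tissue cohort
#'
#' Mutation status drawn at the configured prevalence (mutation-bearing
#' tissues split between homoplasmy and heteroplasmy/heterogeneous); IHC
#' percentages drawn from status-specific Beta distributions scaled to
#' \[0, 100\], and scores derived via [ihc_score_from_percent()].
#'
#' @param config A [generator_config()].
#' @return List: `cohort` (data.frame) and `truth` (planted prevalence and
#'   per-status strong-positive probabilities).
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_stream(config, 3L, {
    n <- config$n_tissues
    has_mut <- stats::runif(n) < config$prevalence
    status <- ifelse(has_mut,
                     ifelse(stats::runif(n) < 0.5, "homoplasmy",
                            "heteroplasmy_or_heterogeneous"),
                     "none")
    ab_mut <- config$ihc_beta_mutation
    ab_none <- config$ihc_beta_none
    percent <- ifelse(has_mut,
                      100 * stats::rbeta(n, ab_mut[1], ab_mut[2]),
                      100 * stats::rbeta(n, ab_none[1], ab_none[2]))
    score <- ihc_score_from_percent(percent)
    cohort <- data.frame(
      id = sprintf("tissue%03d", seq_len(n)),
      histology = "synthetic", site = sample(c("P", "M"), n, replace = TRUE),
      mutation_status = status, ihc_percent = percent,
      ihc_score = as.character(score), stringsAsFactors = FALSE)
    p_strong <- function(ab) stats::pbeta(0.5, ab[1], ab[2],
                                          lower.tail = FALSE)
    list(cohort = cohort,
         truth = list(prevalence = config$prevalence,
                      p_strong_mutation = p_strong(ab_mut),
                      p_strong_none = p_strong(ab_none)))
  })
}

#' Synthetic per-mouse metastasis counts
#'
#' Two groups of negative-binomial counts (e.g. a wild-type-mtDNA cybrid
#' group versus a frameshift-mutant group).
#'
#' @param config A [generator_config()].
#' @return List: `group1`, `group2` (integer vectors) and `truth` (the NB
#'   parameters used).
#' @export
synth_metastasis <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_stream(config, 4L, {
    g1 <- stats::rnbinom(config$metastasis_n[1],
                         mu = config$metastasis_mu[1],
                         size = config$metastasis_size[1])
    g2 <- stats::rnbinom(config$metastasis_n[2],
                         mu = config$metastasis_mu[2],
                         size = config$metastasis_size[2])
    list(group1 = g1, group2 = g2,
         truth = list(mu = config$metastasis_mu,
                      size = config$metastasis_size,
                      n = config$metastasis_n))
  })
}

#' Write planted truth alongside a generated dataset
#'
#' @param truth Truth object from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Deterministic rCRS-coordinate stand-in genome (synthetic)
#'
#' A 16,569-nt stand-in for the human rCRS reference: the gene coordinates
#' are the real NC_012920 coordinates (see
#' `builtin_gene_table("human_rcrs")`), the background sequence is
#' deterministic pseudo-random (a fixed linear congruential stream, so the
#' same bytes on every platform without touching R's RNG), and the true
#' reference codons are planted at the documented NSCLC variant sites so
#' that m.3394T>C, m.3497C>T, m.3709G>A, m.4216T>C, m.11453G>A, m.12813C>A,
#' m.13103G>A and m.13708G>A all reproduce their reported amino-acid
#' consequences. It is NOT the rCRS sequence; only coordinate arithmetic and
#' the planted codons are faithful.
#'
#' @return A `mito_genome` of length 16,569.
#' @export
synthetic_rcrs_genome <- function() {
  n <- 16569L
  # fixed LCG (Numerical Recipes constants), independent of R's RNG state
  state <- 20210625
  bases <- character(n)
  lcg <- function(s) (1664525 * s + 1013904223) %% 4294967296
  for (i in seq_len(n)) {
    state <- lcg(state)
    bases[i] <- c("A", "C", "G", "T")[state %% 4 + 1]
  }
  # planted reference codons (1-based genome positions of codon starts)
  plant <- list(
    list(at = 3394L, codon = "TAC"),  # ND1 codon 30:  Tyr (T3394C -> His)
    list(at = 3496L, codon = "GCC"),  # ND1 codon 64:  Ala (C3497T -> Val)
    list(at = 3709L, codon = "GCA"),  # ND1 codon 135: Ala (G3709A -> Thr)
    list(at = 4216L, codon = "TAC"),  # ND1 codon 304: Tyr (T4216C -> His)
    list(at = 11453L, codon = "GCC"), # ND4 codon 232: Ala (G11453A -> Thr)
    list(at = 12811L, codon = "TAC"), # ND5 codon 159: Tyr (C12813A -> stop)
    list(at = 13102L, codon = "GGA"), # ND5 codon 256: Gly (G13103A -> Glu)
    list(at = 13708L, codon = "GCC")  # ND5 codon 458: Ala (G13708A -> Thr)
  )
  for (p in plant) {
    bases[p$at + 0:2] <- strsplit(p$codon, "")[[1L]]
  }
  mito_genome(paste(bases, collapse = ""),
              accession = "synthetic_rCRS_standin",
              species = "Homo sapiens (synthetic stand-in)")
}
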