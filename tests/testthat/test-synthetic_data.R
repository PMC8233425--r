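test_that("generator_config validates its parameters", {
  cfg <- generator_config(seed = 7)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n_tissues, 17L)
  expect_equal(cfg$prevalence, 9 / 17)
  expect_error(generator_config(dispersion = 0), "dispersion")
  expect_error(generator_config(prevalence = 1.2), "prevalence")
})

test_that("generators are deterministic in the seed and leave the RNG alone", {
  cfg <- generator_config(seed = 123)
  a <- synth_genome(cfg)
  b <- synth_genome(cfg)
  expect_identical(a, b)
  expect_identical(synth_counts(cfg)$matrix$counts,
                   synth_counts(cfg)$matrix$counts)
  expect_identical(synth_cohort(cfg), synth_cohort(cfg))
  expect_identical(synth_metastasis(cfg), synth_metastasis(cfg))
  # different seeds give different data
  expect_false(identical(
    a$genome$sequence, synth_genome(generator_config(seed = 124))$genome$sequence))
  # the ambient RNG stream is untouched by generation
  set.seed(99)
  before <- .Random.seed
  invisible(synth_genome(cfg))
  expect_identical(.Random.seed, before)
})

test_that("annotation reproduces the planted genome truth exactly", {
  for (seed in c(1, 7, 2024)) {
    cfg <- generator_config(seed = seed, n_variants = 25L, n_insertions = 3L)
    gen <- synth_genome(cfg)
    ann <- suppressWarnings(
      annotate_variants(gen$genome, gen$features, gen$variants))
    merged <- merge(gen$truth, ann, by = c("sample", "position"),
                    suffixes = c(".truth", ".obs"))
    expect_equal(nrow(merged), nrow(gen$truth))
    expect_equal(merged$effect_class.obs, merged$effect_class.truth)
    expect_equal(merged$gene.obs, merged$gene.truth)
    expect_equal(merged$codon_index.obs, merged$codon_index.truth)
    sub <- merged$effect_class.truth %in% c("missense", "nonsense")
    expect_equal(merged$ref_aa.obs[sub], merged$ref_aa.truth[sub])
    expect_equal(merged$alt_aa.obs[sub], merged$alt_aa.truth[sub])
  }
})

test_that("planted insertions are frameshifts by construction", {
  cfg <- generator_config(seed = 5, n_variants = 0L, n_insertions = 5L)
  gen <- synth_genome(cfg)
  expect_equal(gen$truth$effect_class, rep("frameshift", 5))
  ann <- annotate_variants(gen$genome, gen$features, gen$variants)
  expect_equal(ann$effect_class, rep("frameshift", 5))
})

test_that("synthetic counts reflect the planted fold changes", {
  cfg <- generator_config(seed = 11, n_genes = 500,
                          n_samples_per_condition = 6,
                          planted_de = c(gene00010 = 3, gene00020 = -3))
  sim <- synth_counts(cfg)
  rec <- log_fold_change(sim$matrix)
  expect_equal(rec$logfc[rec$gene == "gene00010"], 3, tolerance = 0.5)
  expect_equal(rec$logfc[rec$gene == "gene00020"], -3, tolerance = 0.5)
  expect_equal(sort(names(sim$truth$logfc)), c("gene00010", "gene00020"))
  expect_error(
    synth_counts(generator_config(planted_de = c(nosuch = 2))),
    "outside the gene universe")
})

test_that("a planted pathway shift is detectable in the catalog", {
  members <- sprintf("gene%05d", 1:30)
  cfg <- generator_config(seed = 21, n_genes = 400,
                          n_samples_per_condition = 4,
                          planted_pathway_shift = list(pathway = members,
                                                       mean_logfc = 2))
  sim <- synth_counts(cfg)
  expect_true("planted_shift" %in% names(sim$catalog$pathways))
  means <- pathway_mean_logfc(log_fold_change(sim$matrix), sim$catalog)
  planted_mean <- means$mean_logfc[means$pathway == "planted_shift"]
  expect_equal(planted_mean, 2, tolerance = 0.5)
  other <- means$mean_logfc[means$pathway != "planted_shift"]
  expect_true(all(planted_mean > other))
})

test_that("the synthetic cohort matches its truth parameters in distribution", {
  cfg <- generator_config(seed = 31, n_tissues = 2000)
  out <- synth_cohort(cfg)
  coh <- out$cohort
  expect_equal(nrow(coh), 2000L)
  prev_hat <- mean(coh$mutation_status != "none")
  expect_equal(prev_hat, out$truth$prevalence, tolerance = 0.05)
  strong <- vapply(seq_len(nrow(coh)), function(i) {
    strong_positive(coh[i, , drop = FALSE])
  }, logical(1))
  has_mut <- coh$mutation_status != "none"
  expect_lt(abs(mean(strong[has_mut]) - out$truth$p_strong_mutation), 0.05)
  expect_lt(abs(mean(strong[!has_mut]) - out$truth$p_strong_none), 0.05)
  # scores always consistent with the percent column
  expect_equal(coh$ihc_score,
               as.character(ihc_score_from_percent(coh$ihc_percent)))
})

test_that("study-sized synthetic cohorts usually separate the groups", {
  # at the default 17-tissue, 0.875-vs-0.125 configuration the Yates
  # chi-square at alpha = 0.05 should reject in most replicates
  rejections <- vapply(1:40, function(s) {
    coh <- synth_cohort(generator_config(seed = 1000 + s))$cohort
    tab <- build_mutation_mct4_table(coh)
    ok <- tryCatch(chi2_yates(tab)$p < 0.05, error = function(e) NA)
    ok
  }, logical(1))
  expect_gt(mean(rejections, na.rm = TRUE), 0.5)
})

test_that("synthetic metastasis counts feed the exact test sensibly", {
  cfg <- generator_config(seed = 8)
  met <- synth_metastasis(cfg)
  expect_length(met$group1, 6L)
  expect_length(met$group2, 7L)
  expect_true(all(met$group1 >= 0), all(met$group2 >= 0))
  res <- mann_whitney_exact(met$group1, met$group2)
  expect_equal(res$method, "exact_enumeration")
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("write_truth round-trips through JSON", {
  cfg <- generator_config(seed = 4, n_variants = 3L, n_insertions = 0L)
  gen <- synth_genome(cfg)
  path <- tempfile(fileext = ".json")
  write_truth(gen$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$position, gen$truth$position)
  expect_equal(back$effect_class, gen$truth$effect_class)
})

test_that("the rCRS-coordinate stand-in genome reproduces documented variants", {
  g <- synthetic_rcrs_genome()
  expect_equal(g$length, 16569L)
  expect_identical(g$sequence, synthetic_rcrs_genome()$sequence)
  ft <- builtin_gene_table("human_rcrs")
  code <- mito_genetic_code()
  check <- function(pos, ref, alt, gene, codon, ref_aa, alt_aa, cls) {
    eff <- annotate_variant(g, ft, code, variant(pos, ref, alt))
    expect_equal(eff$gene, gene, info = pos)
    expect_equal(eff$codon_index, codon, info = pos)
    expect_equal(eff$ref_aa, ref_aa, info = pos)
    expect_equal(eff$alt_aa, alt_aa, info = pos)
    expect_equal(eff$effect_class, cls, info = pos)
  }
  check(3394, "T", "C", "ND1", 30L, "Y", "H", "missense")
  check(3497, "C", "T", "ND1", 64L, "A", "V", "missense")
  check(3709, "G", "A", "ND1", 135L, "A", "T", "missense")
  check(4216, "T", "C", "ND1", 304L, "Y", "H", "missense")
  check(11453, "G", "A", "ND4", 232L, "A", "T", "missense")
  check(12813, "C", "A", "ND5", 159L, "Y", "*", "nonsense")
  check(13103, "G", "A", "ND5", 256L, "G", "E", "missense")
  check(13708, "G", "A", "ND5", 458L, "A", "T", "missense")
})
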