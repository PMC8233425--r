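test_that("Grantham distances match an independently computed table", {
  for (i in seq_len(nrow(grantham_oracle))) {
    expect_equal(
      grantham_distance(grantham_oracle$aa1[i], grantham_oracle$aa2[i]),
      grantham_oracle$d[i],
      info = paste(grantham_oracle$aa1[i], grantham_oracle$aa2[i]))
  }
})

test_that("Grantham distance has the expected spot values and symmetry", {
  expect_equal(grantham_distance("A", "T"), 58)
  expect_equal(grantham_distance("Y", "H"), 83)
  expect_equal(grantham_distance("G", "E"), 98)
  m <- grantham_matrix()
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m == t(m)))
  expect_error(grantham_distance("A", "B"), "standard amino acid")
  expect_error(grantham_distance("A", "*"), "standard amino acid")
})

test_that("conservation calls respect min_identity and gaps", {
  unanimous <- stats::setNames(rep("A", 8), paste0("sp", 1:8))
  expect_true(conservation_call(unanimous, "sp1"))
  seven <- unanimous
  seven[["sp8"]] <- "S"
  expect_false(conservation_call(seven, "sp1"))
  expect_true(conservation_call(seven, "sp1", min_identity = 0.8))
  gappy <- c(ref = "A", a = "-", b = ".", c = "A")
  expect_true(conservation_call(gappy, "ref"))
  expect_true(is.na(conservation_call(c(ref = "-", a = "A"), "ref")))
  expect_error(conservation_call(unanimous, "absent"), "not present")
})

test_that("conservation_from_msa reads an aligned FASTA column", {
  fa <- write_fasta(c(">human", "MAY", ">mouse", "MSY", ">rat", "MAY"))
  expect_true(conservation_from_msa(fa, 1, "human"))
  expect_false(conservation_from_msa(fa, 2, "human"))
  expect_true(conservation_from_msa(fa, 2, "human", min_identity = 0.6))
  expect_error(conservation_from_msa(fa, 9, "human"), "out of range")
  ragged <- write_fasta(c(">a", "MA", ">b", "MAY"))
  expect_error(conservation_from_msa(ragged, 1, "a"), "unequal")
})

test_that("criteria use strict thresholds at the published cutoffs", {
  eff <- list(effect_class = "missense", ref_aa = "A", alt_aa = "T")
  # A->T Grantham 58 > 50 satisfied; mutpred exactly at cutoff is NOT
  fl <- evaluate_criteria(eff, list(mutpred = 0.70))
  expect_true(fl[["grantham"]])
  expect_false(fl[["mutpred"]])
  fl <- evaluate_criteria(eff, list(mutpred = 0.783))
  expect_true(fl[["mutpred"]])
  # Grantham exactly at cutoff is NOT satisfied
  eff50 <- list(effect_class = "missense", ref_aa = "A", alt_aa = "T")
  fl <- evaluate_criteria(eff50, thresholds = list(grantham_min = 58,
                                                   mutpred_min = 0.7))
  expect_false(fl[["grantham"]])
  expect_equal(attr(fl, "grantham_value"), 58)
  # missing evidence propagates as NA, never invented
  fl <- evaluate_criteria(eff, list())
  expect_true(is.na(fl[["mutpred"]]))
  expect_true(is.na(fl[["conservation"]]))
  expect_true(is.na(fl[["conformational_change"]]))
  expect_false(fl[["protein_truncating"]])
  # a supplied grantham value overrides recomputation
  fl <- evaluate_criteria(eff, list(grantham = 10))
  expect_false(fl[["grantham"]])
})

test_that("truncating effects set the surrogate flag and bypass missense criteria", {
  eff <- list(effect_class = "nonsense", ref_aa = "Y", alt_aa = "*")
  fl <- evaluate_criteria(eff, list(mutpred = 0.99))
  expect_true(fl[["protein_truncating"]])
  expect_true(is.na(fl[["grantham"]])) # not a missense change
  expect_true(is.na(fl[["mutpred"]]))
  eff <- list(effect_class = "frameshift", ref_aa = NA, alt_aa = NA)
  expect_true(evaluate_criteria(eff)[["protein_truncating"]])
})

test_that("the default rule reproduces the three adjudicated verdicts", {
  mk <- function(...) {
    base <- stats::setNames(rep(NA, length(criterion_names)), criterion_names)
    base <- c(base, protein_truncating = FALSE)
    over <- list(...)
    base[names(over)] <- unlist(over)
    base
  }
  # high Grantham + conformational change + disease association -> in
  expect_equal(classify(mk(grantham = TRUE, conformational_change = TRUE,
                           disease_associated = TRUE))$verdict,
               "predicted_pathogenic")
  # high MutPred + conservation alone -> in
  expect_equal(classify(mk(grantham = TRUE, mutpred = TRUE,
                           conservation = TRUE))$verdict,
               "predicted_pathogenic")
  # disease-associated and high Grantham but no conformational change -> out
  expect_equal(classify(mk(grantham = TRUE,
                           disease_associated = TRUE))$verdict,
               "not_predicted")
  # truncating always in
  expect_equal(classify(mk(protein_truncating = TRUE))$verdict,
               "predicted_pathogenic")
  # nothing consulted available -> indeterminate
  expect_equal(classify(mk())$verdict, "indeterminate")
  expect_equal(classify(mk(disease_associated = TRUE))$verdict,
               "indeterminate")
})

test_that("verdicts are monotone in the criterion flags", {
  # turning any FALSE/NA flag to TRUE can never retract a pathogenic call
  rule <- default_rule()
  vars <- c(criterion_names, "protein_truncating")
  set.seed(23)
  for (i in 1:200) {
    base <- stats::setNames(
      sample(c(TRUE, FALSE, NA), length(vars), TRUE), vars)
    base[["protein_truncating"]] <- sample(c(TRUE, FALSE), 1)
    v1 <- classify(base, rule)$verdict
    j <- sample(length(vars), 1)
    upgraded <- base
    upgraded[[j]] <- TRUE
    v2 <- classify(upgraded, rule)$verdict
    if (v1 == "predicted_pathogenic") {
      expect_equal(v2, "predicted_pathogenic")
    }
  }
})

test_that("custom rules are validated and applied", {
  expect_error(pathogenicity_rule("x", quote(grantham & bogus_flag)),
               "unknown criterion")
  strict <- pathogenicity_rule("strict",
                               quote(grantham & conservation & mutpred))
  fl <- stats::setNames(rep(TRUE, length(criterion_names)), criterion_names)
  fl <- c(fl, protein_truncating = FALSE)
  out <- classify(fl, strict)
  expect_equal(out$verdict, "predicted_pathogenic")
  expect_equal(out$rule_id, "strict")
})

test_that("score_pathogenicity reproduces the cell-line adjudications", {
  g <- synthetic_rcrs_genome()
  ft <- builtin_gene_table("human_rcrs")
  variants <- read_variants(
    system.file("extdata", "cellline_variants.tsv", package = "mitomct4"))
  ann <- annotate_variants(g, ft, variants)
  ev <- read_evidence(
    system.file("extdata", "cellline_evidence.tsv", package = "mitomct4"))
  scored <- score_pathogenicity(merge_evidence(ann, ev))
  verdict_of <- function(pos) scored$verdict[scored$position == pos]
  expect_equal(verdict_of(13708), "predicted_pathogenic") # ND5 A458T
  expect_equal(verdict_of(11453), "predicted_pathogenic") # ND4 A232T
  expect_equal(verdict_of(4216), "not_predicted")         # ND1 Y304H
  expect_equal(scored$grantham_value[scored$position == 4216],
               grantham_distance("Y", "H"))
})

test_that("non-coding rows pass through unscored", {
  ann <- data.frame(sample = "s", position = 5L, alt = "A",
                    effect_class = "non_coding", ref_aa = NA, alt_aa = NA,
                    stringsAsFactors = FALSE)
  scored <- score_pathogenicity(ann)
  expect_equal(scored$verdict, "not_predicted")
  expect_equal(scored$criteria_met, "")
  expect_true(is.na(scored$grantham_value))
})

test_that("read_evidence validates keys and score ranges", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tposition", "s\t1"), bad)
  expect_error(read_evidence(bad), "merge key")
  oob <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tposition\talt\tmutpred", "s\t1\tA\t1.5"), oob)
  expect_error(read_evidence(oob), "\\[0, 1\\]")
})
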