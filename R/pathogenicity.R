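criterion_names <- c("grantham", "mutpred", "conservation",
                     "conformational_change", "disease_associated",
                     "mtros_overproduction")

#' Evolutionary conservation of the reference residue
#'
#' Decides whether the reference species' residue at an alignment column is
#' conserved: the fraction of species carrying that residue must reach
#' `min_identity` (default 1.0, i.e. unanimity). Gap characters are dropped;
#' a gap-only column is indeterminate (`NA`), not `FALSE`.
#'
#' @param residues_by_species Named character vector of one-letter residues
#'   (names = species labels); `"-"` and `"."` are gaps.
#' @param ref_species Name of the reference species (must be present).
#' @param min_identity Minimum conserved fraction in `[0, 1]`.
#' @return `TRUE`, `FALSE`, or `NA` when indeterminate.
#' @examples
#' col <- c(human = "A", chimp = "A", mouse = "A", rat = "S")
#' conservation_call(col, "human")                     # FALSE
#' conservation_call(col, "human", min_identity = 0.7) # TRUE (3/4)
#' @export
conservation_call <- function(residues_by_species, ref_species,
                              min_identity = 1.0) {
  stopifnot(length(residues_by_species) >= 2L,
            min_identity >= 0, min_identity <= 1)
  if (!ref_species %in% names(residues_by_species)) {
    stop("reference species '", ref_species, "' not present", call. = FALSE)
  }
  res <- toupper(residues_by_species)
  res <- res[!res %in% c("-", ".")]
  if (!length(res) || !ref_species %in% names(res)) {
    return(NA)
  }
  mean(res == res[[ref_species]]) >= min_identity
}

#' Conservation of a residue column from a protein alignment
#'
#' Convenience wrapper reading an aligned FASTA of orthologous protein
#' sequences and applying [conservation_call()] to one alignment column.
#'
#' @param msa_fasta Path to an aligned protein FASTA (equal lengths).
#' @param column 1-based alignment column.
#' @inheritParams conservation_call
#' @export
conservation_from_msa <- function(msa_fasta, column, ref_species,
                                  min_identity = 1.0) {
  aln <- Biostrings::readAAStringSet(msa_fasta)
  if (length(unique(Biostrings::width(aln))) != 1L) {
    stop("alignment sequences have unequal lengths", call. = FALSE)
  }
  if (column < 1L || column > Biostrings::width(aln)[1L]) {
    stop("alignment column out of range", call. = FALSE)
  }
  col <- vapply(seq_along(aln), function(i) {
    substr(as.character(aln[[i]]), column, column)
  }, character(1))
  names(col) <- names(aln)
  conservation_call(col, ref_species, min_identity)
}

#' Read an external evidence table
#'
#' Per-variant evidence consumed as input (never recomputed): `mutpred`
#' (score in `[0,1]`), `conserved`, `conformational_change`,
#' `disease_associated`, `mtros_overproduction` (logical), merged onto
#' annotated variants by (`sample`, `position`, `alt`). A precomputed
#' `grantham` column is honoured when present, otherwise the distance is
#' derived from the annotated residues.
#'
#' @param path Evidence TSV.
#' @return Evidence data.frame.
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("sample", "position", "alt"), names(ev))
  if (length(miss)) {
    stop("evidence TSV is missing merge key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (nm in c("conserved", "conformational_change", "disease_associated",
               "mtros_overproduction")) {
    if (!is.null(ev[[nm]])) {
      x <- trimws(as.character(ev[[nm]]))
      x[!nzchar(x)] <- NA
      ev[[nm]] <- as.logical(x)
    }
  }
  if (!is.null(ev$mutpred)) {
    ev$mutpred <- suppressWarnings(as.numeric(ev$mutpred))
    if (any(!is.na(ev$mutpred) & (ev$mutpred < 0 | ev$mutpred > 1))) {
      stop("MutPred scores must lie in [0, 1]", call. = FALSE)
    }
  }
  ev
}

#' Merge evidence onto annotated variants
#'
#' @param annotated Output of [annotate_variants()].
#' @param evidence Output of [read_evidence()].
#' @return `annotated` with the evidence columns joined by
#'   (`sample`, `position`, `alt`); unmatched variants get missing evidence.
#' @export
merge_evidence <- function(annotated, evidence) {
  merge(annotated, evidence, by = c("sample", "position", "alt"),
        all.x = TRUE, sort = FALSE)
}

#' Evaluate the six pathogenicity criteria for one coding effect
#'
#' The criteria are: Grantham distance > `grantham_min` (strict), MutPred
#' score > `mutpred_min` (strict), evolutionary conservation of the original
#' residue, predicted conformational change of the protein, reported
#' association with mitochondrial disease, and mitochondrial ROS
#' overproduction. The Grantham criterion is computed in-repo from the
#' annotated residue change; the others come from the evidence record and
#' missing evidence propagates as `NA` (never invented). Nonsense and
#' frameshift effects bypass the missense-oriented criteria and instead set
#' a separate `protein_truncating` surrogate flag.
#'
#' @param effect One-row coding effect (see [annotate_variant()]).
#' @param evidence List or one-row data.frame with any of `grantham`,
#'   `mutpred`, `conserved`, `conformational_change`, `disease_associated`,
#'   `mtros_overproduction`.
#' @param thresholds List with `grantham_min` (default 50) and `mutpred_min`
#'   (default 0.7).
#' @return Named logical vector (with `NA` for missing) over the six
#'   criteria plus `protein_truncating`; attribute `grantham_value` carries
#'   the numeric distance for reporting.
#' @export
evaluate_criteria <- function(effect, evidence = list(),
                              thresholds = list(grantham_min = 50,
                                                mutpred_min = 0.7)) {
  stopifnot(effect$effect_class %in%
              c("missense", "nonsense", "frameshift", "inframe_indel"))
  ev <- as.list(evidence)
  pick <- function(name) {
    x <- ev[[name]]
    if (is.null(x) || !length(x)) NA else x[[1L]]
  }
  flags <- stats::setNames(rep(NA, length(criterion_names)), criterion_names)
  truncating <- effect$effect_class %in% c("nonsense", "frameshift")
  g_val <- NA_real_
  if (identical(effect$effect_class, "missense")) {
    g_val <- pick("grantham")
    if (is.na(g_val) && !is.na(effect$ref_aa) && !is.na(effect$alt_aa)) {
      g_val <- grantham_distance(effect$ref_aa, effect$alt_aa)
    }
    if (!is.na(g_val)) flags[["grantham"]] <- g_val > thresholds$grantham_min
    mp <- pick("mutpred")
    if (!is.na(mp)) flags[["mutpred"]] <- mp > thresholds$mutpred_min
    cons <- pick("conserved")
    if (!is.na(cons)) flags[["conservation"]] <- isTRUE(as.logical(cons))
  }
  for (nm in c("conformational_change", "disease_associated",
               "mtros_overproduction")) {
    x <- pick(nm)
    if (!is.na(x)) flags[[nm]] <- isTRUE(as.logical(x))
  }
  flags <- c(flags, protein_truncating = truncating)
  attr(flags, "grantham_value") <- g_val
  flags
}

#' Pathogenicity aggregation rules
#'
#' The default rule, `"mutpred_or_grantham_conformational"`, calls a variant
#' predicted pathogenic iff its MutPred criterion is satisfied OR both the
#' Grantham and conformational-change criteria are satisfied; a
#' protein-truncating effect (nonsense/frameshift) in an ND gene context is
#' always predicted pathogenic. This is the minimal rule consistent with the
#' three adjudicated NSCLC cell-line variants (G13708A in, G11453A in,
#' T4216C out). The verdict is `"indeterminate"` when every flag the rule
#' consults is missing. mtROS overproduction is carried as evidence but not
#' consulted (it is a cell-level, not per-variant, measurement).
#'
#' Custom rules are R expressions over the criterion names (logical values
#' with `NA` for missing) plus `protein_truncating`, e.g.
#' `pathogenicity_rule("strict", quote(grantham & conservation & mutpred))`.
#'
#' @param id Rule identifier recorded in every call.
#' @param expr Quoted logical expression over the criterion flags.
#' @return A `pathogenicity_rule` object.
#' @export
pathogenicity_rule <- function(id, expr) {
  bad <- setdiff(all.vars(expr), c(criterion_names, "protein_truncating"))
  if (length(bad)) {
    stop("rule references unknown criterion(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, expr = expr), class = "pathogenicity_rule")
}

#' @rdname pathogenicity_rule
#' @export
default_rule <- function() {
  pathogenicity_rule(
    "mutpred_or_grantham_conformational",
    quote(protein_truncating | mutpred | (grantham & conformational_change))
  )
}

#' Aggregate criterion flags into a pathogenicity verdict
#'
#' @param flags Output of [evaluate_criteria()].
#' @param rule A [pathogenicity_rule()]; default [default_rule()].
#' @return A one-row data.frame: `verdict`
#'   (`predicted_pathogenic`/`not_predicted`/`indeterminate`),
#'   `criteria_met` (comma-joined names of satisfied criteria) and `rule_id`.
#' @examples
#' fl <- stats::setNames(c(TRUE, NA, NA, TRUE, TRUE, TRUE, FALSE),
#'   c("grantham", "mutpred", "conservation", "conformational_change",
#'     "disease_associated", "mtros_overproduction", "protein_truncating"))
#' classify(fl)  # predicted_pathogenic (grantham AND conformational change)
#' @export
classify <- function(flags, rule = default_rule()) {
  stopifnot(inherits(rule, "pathogenicity_rule"))
  env <- as.list(flags)
  consulted <- setdiff(all.vars(rule$expr), "protein_truncating")
  value <- eval(rule$expr, envir = env)
  verdict <- if (isTRUE(value)) {
    "predicted_pathogenic"
  } else if (length(consulted) &&
             all(is.na(unlist(env[consulted])))) {
    "indeterminate"
  } else {
    "not_predicted"
  }
  met <- names(flags)[vapply(flags, isTRUE, logical(1))]
  data.frame(verdict = verdict,
             criteria_met = paste(met, collapse = ","),
             rule_id = rule$id, stringsAsFactors = FALSE)
}

#' Score annotated variants against the pathogenicity criteria
#'
#' Row-wise evaluation + classification over a table of annotated variants
#' with merged evidence. Non-coding and synonymous rows are passed through
#' with verdict `"not_predicted"` and no criteria evaluated.
#'
#' @param annotated Output of [annotate_variants()] (optionally after
#'   [merge_evidence()]).
#' @param rule A [pathogenicity_rule()].
#' @param thresholds See [evaluate_criteria()].
#' @return `annotated` with columns `grantham_value`, one logical column per
#'   criterion, `protein_truncating`, `verdict`, `criteria_met`, `rule_id`.
#' @export
score_pathogenicity <- function(annotated, rule = default_rule(),
                                thresholds = list(grantham_min = 50,
                                                  mutpred_min = 0.7)) {
  scoreable <- c("missense", "nonsense", "frameshift", "inframe_indel")
  out <- lapply(seq_len(nrow(annotated)), function(i) {
    row <- annotated[i, , drop = FALSE]
    if (!row$effect_class %in% scoreable) {
      fl <- stats::setNames(rep(NA, length(criterion_names)), criterion_names)
      fl <- c(fl, protein_truncating = FALSE)
      cl <- data.frame(verdict = "not_predicted", criteria_met = "",
                       rule_id = rule$id, stringsAsFactors = FALSE)
      g <- NA_real_
    } else {
      fl <- evaluate_criteria(row, row, thresholds = thresholds)
      cl <- classify(fl, rule)
      g <- attr(fl, "grantham_value")
    }
    cbind(data.frame(grantham_value = as.numeric(g)),
          as.data.frame(as.list(fl)), cl)
  })
  cbind(annotated, do.call(rbind, out))
}
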