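#' Construct a validated variant table
#'
#' A variant is a nucleotide change on the reference (heavy-strand) frame:
#' `substitution` (one base to another at `position`), `insertion`
#' (`alt` inserted immediately *after* `position`, the community `NinsX`
#' convention, with empty `ref`) or `deletion` (`ref` bases removed starting
#' at `position`, empty `alt`).
#'
#' @param position 1-based genome coordinate(s).
#' @param ref,alt Allele strings (may be `""` per kind).
#' @param kind `"substitution"`, `"insertion"` or `"deletion"`; inferred from
#'   the alleles when `NULL`.
#' @param heteroplasmy Fraction of mutant mtDNA copies in `[0, 1]`, or `NA`
#'   when unknown.
#' @param sample Sample label(s).
#' @return A data.frame with one row per variant.
#' @export
variant <- function(position, ref, alt, kind = NULL, heteroplasmy = NA_real_,
                    sample = NA_character_) {
  position <- as.integer(position)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  ref[is.na(ref)] <- ""
  alt[is.na(alt)] <- ""
  if (is.null(kind)) {
    kind <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "substitution",
            ifelse(nchar(ref) == 0L & nchar(alt) >= 1L, "insertion",
            ifelse(nchar(alt) == 0L & nchar(ref) >= 1L, "deletion",
                   NA_character_)))
  }
  v <- data.frame(sample = as.character(sample), position = position,
                  ref = ref, alt = alt, kind = as.character(kind),
                  heteroplasmy = as.numeric(heteroplasmy),
                  stringsAsFactors = FALSE)
  validate_variants(v)
}

validate_variants <- function(v, genome = NULL) {
  if (any(is.na(v$position) | v$position < 1L)) {
    stop("variant positions must be positive integers", call. = FALSE)
  }
  if (!all(v$kind %in% c("substitution", "insertion", "deletion"))) {
    stop("variant kind must be substitution/insertion/deletion", call. = FALSE)
  }
  sub <- v$kind == "substitution"
  if (any(sub & (nchar(v$ref) != 1L | nchar(v$alt) != 1L))) {
    stop("substitutions must have single-base ref and alt", call. = FALSE)
  }
  if (any(sub & v$ref == v$alt)) {
    stop("substitution ref and alt alleles must differ", call. = FALSE)
  }
  if (any(v$kind == "insertion" & nchar(v$alt) == 0L)) {
    stop("insertions must have a non-empty alt allele", call. = FALSE)
  }
  if (any(v$kind == "deletion" & nchar(v$ref) == 0L)) {
    stop("deletions must have a non-empty ref allele", call. = FALSE)
  }
  hp <- v$heteroplasmy
  if (any(!is.na(hp) & (hp < 0 | hp > 1))) {
    stop("heteroplasmy fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(genome)) {
    if (any(v$position > genome$length)) {
      bad <- v$position[v$position > genome$length]
      stop("variant position(s) beyond genome end: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  v
}

#' Read variants from TSV or minimal VCF
#'
#' TSV input needs columns `sample`, `position`, `ref`, `alt`, `kind`
#' (optional; inferred from alleles) and `heteroplasmy` (optional, defaults
#' to unknown); extra columns such as external evidence are passed through.
#' Files whose first data line starts with `#` or whose name ends in `.vcf`
#' are parsed as a minimal VCF 4.x subset using only CHROM/POS/REF/ALT
#' (VCF-style anchored indels are converted: `REF=G, ALT=GC` becomes an
#' insertion of `C` after POS).
#'
#' @param path Input file.
#' @return Validated variant data.frame preserving input order.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.vcf$", path, ignore.case = TRUE) || startsWith(first, "##")) {
    return(read_minimal_vcf(path))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "")
  required <- c("sample", "position", "ref", "alt")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("variant TSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$ref[is.na(tab$ref)] <- ""
  tab$alt[is.na(tab$alt)] <- ""
  if (is.null(tab$kind)) tab$kind <- NA_character_
  if (is.null(tab$heteroplasmy)) tab$heteroplasmy <- NA_real_
  for (i in seq_len(nrow(tab))) {
    row_ok <- tryCatch({
      v <- variant(tab$position[i], tab$ref[i], tab$alt[i],
                   kind = if (is.na(tab$kind[i])) NULL else tab$kind[i],
                   heteroplasmy = tab$heteroplasmy[i], sample = tab$sample[i])
      tab$kind[i] <- v$kind
      TRUE
    }, error = function(e) e)
    if (!isTRUE(row_ok)) {
      stop("malformed variant at line ", i + 1L, " of ", path, ": ",
           conditionMessage(row_ok), call. = FALSE)
    }
  }
  tab$position <- as.integer(tab$position)
  tab$ref <- toupper(tab$ref)
  tab$alt <- toupper(tab$alt)
  tab
}

read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(variant(integer(0), character(0), character(0)))
  }
  fields <- strsplit(lines, "\t| +")
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 5L) {
      stop("malformed VCF record at data line ", i, " of ", path,
           call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(f[2L]))
    ref <- toupper(f[4L]); alt <- toupper(f[5L])
    if (is.na(pos)) {
      stop("malformed VCF POS at data line ", i, " of ", path, call. = FALSE)
    }
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      variant(pos, ref, alt, sample = f[1L])
    } else if (nchar(alt) > nchar(ref) && startsWith(alt, ref)) {
      # anchored insertion: inserted bases follow the shared prefix
      variant(pos + nchar(ref) - 1L, "", substring(alt, nchar(ref) + 1L),
              kind = "insertion", sample = f[1L])
    } else if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) {
      variant(pos + nchar(alt), substring(ref, nchar(alt) + 1L), "",
              kind = "deletion", sample = f[1L])
    } else {
      stop("unsupported multi-nucleotide VCF record at data line ", i,
           " of ", path, call. = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Classify homoplasmy from a heteroplasmy fraction
#'
#' Tissue-sequencing reports conflate heteroplasmy with tumour heterogeneity
#' (a mixture of mutation-bearing and wild-type cells), so everything below
#' the threshold is labelled `"heteroplasmy_or_heterogeneous"`.
#'
#' @param heteroplasmy Fraction(s) in `[0,1]` or `NA`.
#' @param threshold Homoplasmy declared at or above this fraction
#'   (default 0.95); unknown fractions default to `"homoplasmy"`.
#' @return Character vector of status labels.
#' @export
plasmy_status <- function(heteroplasmy, threshold = 0.95) {
  ifelse(is.na(heteroplasmy) | heteroplasmy >= threshold,
         "homoplasmy", "heteroplasmy_or_heterogeneous")
}

empty_effect <- function(effect_class = "non_coding", gene = NA_character_) {
  data.frame(gene = gene, codon_index = NA_integer_,
             ref_aa = NA_character_, alt_aa = NA_character_,
             effect_class = effect_class, stringsAsFactors = FALSE)
}

#' Annotate a variant with its coding consequence
#'
#' Locates the variant within the protein-gene model and derives gene, codon
#' index, reference/alternate residues and an effect class. For light-strand
#' genes the alleles are complemented and the coding offset is measured from
#' the gene end, so codon arithmetic always happens on the coding strand.
#' Insertions or deletions whose length is not a multiple of three inside a
#' protein gene are frameshifts; in-frame indels are classed
#' `"inframe_indel"`. Variants outside protein features are `"non_coding"`
#' (with the feature name when they fall in a tRNA/rRNA/control feature).
#'
#' @param genome A `mito_genome`.
#' @param features Gene feature data.frame (see [read_gene_table()]).
#' @param code Genetic code, from [mito_genetic_code()].
#' @param v A single-row variant (see [variant()]).
#' @return One-row data.frame: `gene`, `codon_index`, `ref_aa`, `alt_aa`,
#'   `effect_class` in
#'   synonymous/missense/nonsense/frameshift/inframe_indel/non_coding.
#' @examples
#' g <- mito_genome("ATGAAATAA")
#' feats <- data.frame(name = "toy", start = 1, end = 9,
#'                     strand = "H", kind = "protein")
#' annotate_variant(g, feats, mito_genetic_code(),
#'                  variant(4, "A", "G"))  # codon 2, K -> E
#' @export
annotate_variant <- function(genome, features, code = mito_genetic_code(), v) {
  stopifnot(inherits(genome, "mito_genome"), nrow(v) == 1L)
  validate_variants(v, genome = genome)
  features <- validate_gene_features(features, genome_length = genome$length)

  pos <- v$position
  if (v$kind == "substitution") {
    ref_base <- substr(genome$sequence, pos, pos)
    if (ref_base != v$ref) {
      stop("reference allele mismatch at position ", pos, ": genome has '",
           ref_base, "', variant states '", v$ref, "'", call. = FALSE)
    }
  } else if (v$kind == "deletion") {
    ref_span <- substr(genome$sequence, pos, pos + nchar(v$ref) - 1L)
    if (ref_span != v$ref) {
      stop("reference allele mismatch at position ", pos, ": genome has '",
           ref_span, "', variant states '", v$ref, "'", call. = FALSE)
    }
  }

  prot <- features[features$kind == "protein", , drop = FALSE]
  # insertions take effect after `pos`, so they sit inside a gene only when
  # pos is strictly before the gene end
  if (v$kind == "insertion") {
    hit <- which(pos >= prot$start & pos < prot$end)
  } else {
    hit <- which(pos >= prot$start & pos <= prot$end)
  }
  if (length(hit) > 1L) {
    warning("position ", pos, " overlaps multiple protein genes (",
            paste(prot$name[hit], collapse = ", "), "); using first match")
    hit <- hit[1L]
  }
  if (!length(hit)) {
    other <- features[features$kind != "protein", , drop = FALSE]
    in_other <- which(pos >= other$start & pos <= other$end)
    gene <- if (length(in_other)) other$name[in_other[1L]] else NA_character_
    return(empty_effect(gene = gene))
  }

  feat <- prot[hit, , drop = FALSE]
  if (v$kind %in% c("insertion", "deletion")) {
    len <- if (v$kind == "insertion") nchar(v$alt) else nchar(v$ref)
    offset <- if (feat$strand == "L") feat$end - pos else pos - feat$start
    cls <- if (len %% 3L == 0L) "inframe_indel" else "frameshift"
    return(data.frame(gene = feat$name,
                      codon_index = offset %/% 3L + 1L,
                      ref_aa = NA_character_, alt_aa = NA_character_,
                      effect_class = cls, stringsAsFactors = FALSE))
  }

  # substitution within a protein gene: codon arithmetic on the coding strand
  if (feat$strand == "L") {
    offset <- feat$end - pos
    ref_cod_allele <- complement_base(v$ref)
    alt_cod_allele <- complement_base(v$alt)
  } else {
    offset <- pos - feat$start
    ref_cod_allele <- v$ref
    alt_cod_allele <- v$alt
  }
  codon_index <- offset %/% 3L + 1L
  pos_in_codon <- offset %% 3L + 1L
  cds <- extract_cds(genome, feat)
  if (codon_index > nchar(cds) %/% 3L) {
    # incomplete terminal codon (completed by polyadenylation in vivo)
    warning("variant at position ", pos, " falls in the incomplete terminal ",
            "codon of ", feat$name, "; no residue change derived")
    return(empty_effect(gene = feat$name))
  }
  codon_start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_cod_allele
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  cls <- if (identical(ref_aa, alt_aa)) {
    "synonymous"
  } else if (identical(alt_aa, "*")) {
    "nonsense"
  } else if (identical(ref_aa, "*")) {
    warning("stop-loss (readthrough) substitution at position ", pos,
            " in ", feat$name, "; reported as missense")
    "missense"
  } else {
    "missense"
  }
  data.frame(gene = feat$name, codon_index = codon_index,
             ref_aa = ref_aa, alt_aa = alt_aa, effect_class = cls,
             stringsAsFactors = FALSE)
}

#' Annotate a table of variants
#'
#' Row-wise wrapper around [annotate_variant()]; the coding-effect columns
#' are appended to the input table.
#'
#' @inheritParams annotate_variant
#' @param variants Variant data.frame (see [read_variants()]).
#' @return The input with columns `gene`, `codon_index`, `ref_aa`, `alt_aa`,
#'   `effect_class` appended.
#' @export
annotate_variants <- function(genome, features, variants,
                              code = mito_genetic_code()) {
  if (!nrow(variants)) {
    return(cbind(variants, empty_effect()[0, , drop = FALSE]))
  }
  effects <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    annotate_variant(genome, features, code, variants[i, , drop = FALSE])
  }))
  cbind(variants, effects)
}
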