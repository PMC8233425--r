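#' Load a mitochondrial genome from a single-record FASTA file
#'
#' Reads one FASTA record and validates it as a circular mitochondrial
#' reference. The first whitespace-delimited token of the header becomes the
#' accession; the remainder (if any) the species label.
#'
#' @param fasta_source Path to a FASTA file containing exactly one record.
#' @param species Optional species label overriding the header remainder.
#' @return A `mito_genome` object: a list with elements `accession`,
#'   `species`, `sequence` (upper-case character scalar over A/C/G/T/N),
#'   `length` and `circular` (always `TRUE`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy", "ATGAAATAAGGGTTTC"), fa)
#' g <- load_genome(fa)
#' g$length
#' @export
load_genome <- function(fasta_source, species = NA_character_) {
  set <- Biostrings::readDNAStringSet(fasta_source)
  if (length(set) != 1L) {
    stop("expected a single-record FASTA, found ", length(set), " records",
         call. = FALSE)
  }
  header <- names(set)[1L]
  tokens <- strsplit(trimws(header), "\\s+")[[1L]]
  accession <- tokens[1L]
  if (is.na(species) && length(tokens) > 1L) {
    species <- paste(tokens[-1L], collapse = " ")
  }
  mito_genome(as.character(set[[1L]]), accession = accession, species = species)
}

#' Construct a validated circular mitochondrial genome
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive).
#' @param accession Identifier string.
#' @param species Species label.
#' @return A `mito_genome` object.
#' @export
mito_genome <- function(sequence, accession = "unknown", species = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("genome sequence is empty", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome sequence contains characters outside A/C/G/T/N",
         call. = FALSE)
  }
  structure(
    list(accession = accession, species = species, sequence = sequence,
         length = nchar(sequence), circular = TRUE),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("Circular mitochondrial genome ", x$accession,
      if (!is.na(x$species)) paste0(" (", x$species, ")"), ": ",
      x$length, " bp\n", sep = "")
  invisible(x)
}

#' Read a gene coordinate table
#'
#' Tab-separated table with columns `name`, `start`, `end`, `strand`
#' (`H` = heavy/reference orientation, `L` = reverse complement) and `kind`
#' (`protein`, `tRNA`, `rRNA`, `control`). Lines starting with `#` are
#' comments. Coordinates are 1-based inclusive; origin-spanning features are
#' rejected.
#'
#' @param path Path to the TSV file.
#' @param genome_length Optional genome length for bounds validation.
#' @return A data.frame of gene features.
#' @seealso [builtin_gene_table()] for the tables shipped with the package.
#' @export
read_gene_table <- function(path, genome_length = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "strand", "kind")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("gene table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_gene_features(tab, genome_length = genome_length)
}

#' Built-in gene coordinate tables
#'
#' Two tables ship with the package: `"human_rcrs"` (rCRS-style human
#' coordinates, NC_012920 frame) and `"mouse"` (mouse-style coordinates,
#' NC_005089-like frame). Users may supply their own TSV via
#' [read_gene_table()].
#'
#' @param which `"human_rcrs"` or `"mouse"`.
#' @return A validated gene feature data.frame.
#' @export
builtin_gene_table <- function(which = c("human_rcrs", "mouse")) {
  which <- match.arg(which)
  file <- switch(which,
    human_rcrs = "gene_table_human_rcrs.tsv",
    mouse = "gene_table_mouse.tsv"
  )
  path <- system.file("extdata", file, package = "mitomct4", mustWork = TRUE)
  read_gene_table(path)
}

validate_gene_features <- function(features, genome_length = NULL) {
  stopifnot(is.data.frame(features))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(is.na(features$start)) || any(is.na(features$end))) {
    stop("gene table has non-integer coordinates", call. = FALSE)
  }
  if (any(features$start < 1L)) {
    stop("gene coordinates must be >= 1", call. = FALSE)
  }
  if (any(features$start > features$end)) {
    bad <- features$name[features$start > features$end]
    stop("origin-spanning (wrap-around) features are not supported: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(genome_length) && any(features$end > genome_length)) {
    bad <- features$name[features$end > genome_length]
    stop("feature(s) extend beyond the genome: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(features$strand %in% c("H", "L"))) {
    stop("strand must be 'H' or 'L'", call. = FALSE)
  }
  if (!all(features$kind %in% c("protein", "tRNA", "rRNA", "control"))) {
    stop("kind must be one of protein/tRNA/rRNA/control", call. = FALSE)
  }
  prot <- features$kind == "protein"
  if (any(features$end[prot] - features$start[prot] + 1L < 3L)) {
    stop("protein features must span at least one codon", call. = FALSE)
  }
  features
}

#' The vertebrate mitochondrial genetic code
#'
#' Returns the 64-codon translation table used by vertebrate mitochondria
#' (NCBI translation table 2): relative to the standard code, AGA and AGG are
#' stop codons, TGA encodes tryptophan and ATA encodes methionine. Stops are
#' rendered as `"*"`.
#'
#' @return Named character vector of length 64 mapping codons to one-letter
#'   residues, with attribute `id = "vertebrate mitochondrial"`.
#' @export
mito_genetic_code <- function() {
  code <- Biostrings::getGeneticCode("2")
  code <- stats::setNames(as.character(code), names(code))
  attr(code, "id") <- "vertebrate mitochondrial"
  code
}

#' Reverse complement of a nucleotide string
#'
#' @param s Character scalar over A/C/G/T/N.
#' @return The reverse complement, same length.
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

#' Extract the coding-strand sequence of a protein gene
#'
#' For heavy-strand (`H`) genes this is the reference slice
#' `[start, end]`; for light-strand (`L`) genes it is the reverse complement
#' of that slice, so the returned string always reads 5' to 3' on the coding
#' strand. Length is preserved.
#'
#' @param genome A `mito_genome`.
#' @param feature A single-row gene feature (data.frame row or list with
#'   `start`, `end`, `strand`, `kind`).
#' @return Nucleotide string of length `end - start + 1`.
#' @export
extract_cds <- function(genome, feature) {
  stopifnot(inherits(genome, "mito_genome"))
  if (feature$kind != "protein") {
    stop("extract_cds() requires a protein feature, got kind '",
         feature$kind, "'", call. = FALSE)
  }
  slice <- substr(genome$sequence, feature$start, feature$end)
  if (feature$strand == "L") reverse_complement(slice) else slice
}

#' Translate a coding sequence with the vertebrate mitochondrial code
#'
#' Translates codon by codon. Stops are rendered `"*"`; codons containing a
#' non-ACGT symbol translate to `"X"` with a warning. Mitochondrial protein
#' genes commonly end in an incomplete codon completed by polyadenylation:
#' a trailing 1-2 nt remainder is flagged (attribute `incomplete_tail`,
#' plus a warning) rather than treated as an error.
#'
#' @param cds Nucleotide string (coding strand, 5' to 3').
#' @param code Genetic code from [mito_genetic_code()].
#' @param truncate_at_stop If `TRUE`, translation stops at the first stop
#'   codon (which is included as `"*"`).
#' @return Amino-acid string; attribute `incomplete_tail` gives the number of
#'   untranslated trailing nucleotides (0, 1 or 2).
#' @export
translate_cds <- function(cds, code = mito_genetic_code(),
                          truncate_at_stop = FALSE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  tail_len <- n %% 3L
  if (tail_len != 0L) {
    warning("trailing ", tail_len,
            " nt form an incomplete terminal codon; left untranslated")
  }
  n_codons <- n %/% 3L
  if (n_codons == 0L) {
    out <- ""
    attr(out, "incomplete_tail") <- tail_len
    return(out)
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(code[codons])
  bad <- is.na(aa)
  if (any(bad)) {
    warning(sum(bad), " codon(s) with non-ACGT symbols translated as 'X'")
    aa[bad] <- "X"
  }
  if (truncate_at_stop) {
    first_stop <- match("*", aa)
    if (!is.na(first_stop)) aa <- aa[seq_len(first_stop)]
  }
  out <- paste(aa, collapse = "")
  attr(out, "incomplete_tail") <- tail_len
  out
}

#' Write a genome to FASTA
#'
#' @param genome A `mito_genome`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "mito_genome"))
  seq <- Biostrings::DNAStringSet(genome$sequence)
  names(seq) <- if (is.na(genome$species)) genome$accession else {
    paste(genome$accession, genome$species)
  }
  Biostrings::writeXStringSet(seq, filepath = path, width = width)
  invisible(path)
}
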