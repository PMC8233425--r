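# shared fixtures and independent oracles used across test files

toy_genome <- function(seq = "ATGAAATAA") mito_genome(seq)

toy_feature <- function(start, end, strand = "H", name = "toy",
                        kind = "protein") {
  data.frame(name = name, start = start, end = end, strand = strand,
             kind = kind, stringsAsFactors = FALSE)
}

write_fasta <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}

# brute-force substitution oracle: mutate the genome string, re-extract and
# re-translate the whole gene, and diff the two protein strings
oracle_substitution <- function(genome, feature, code, pos, alt) {
  mutated_seq <- genome$sequence
  substr(mutated_seq, pos, pos) <- alt
  mutated <- mito_genome(mutated_seq)
  p_ref <- suppressWarnings(translate_cds(extract_cds(genome, feature), code))
  p_alt <- suppressWarnings(translate_cds(extract_cds(mutated, feature), code))
  ref_chars <- strsplit(p_ref, "")[[1]]
  alt_chars <- strsplit(p_alt, "")[[1]]
  diff <- which(ref_chars != alt_chars)
  if (!length(diff)) {
    list(codon_index = NA_integer_, ref_aa = NA_character_,
         alt_aa = NA_character_, effect_class = "synonymous")
  } else {
    i <- diff[1]
    cls <- if (alt_chars[i] == "*") "nonsense" else "missense"
    list(codon_index = i, ref_aa = ref_chars[i], alt_aa = alt_chars[i],
         effect_class = cls)
  }
}

# hypergeometric over-representation tail by direct enumeration
oracle_hyper_tail <- function(k, K, n, N) {
  sum(stats::dhyper(seq(k, min(K, n)), K, N - K, n))
}

# two-sided exact Mann-Whitney by explicit permutation of group labels
oracle_mw_exact <- function(g1, g2) {
  n1 <- length(g1)
  r <- rank(c(g1, g2))
  mu <- n1 * length(g2) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sel <- utils::combn(length(r), n1)
  u_all <- apply(sel, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
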