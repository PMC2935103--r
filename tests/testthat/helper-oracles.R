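# Shared fixtures and independent oracles for the test suite.

# 12-nt toy circle: gene X (1..9) translates MAL, gene Y (3..11) GIS;
# X and Y overlap out-of-frame over positions 3..9.
toy_seq <- "ATGGCATTAGCG"

toy_genome_xy <- function() {
  genome_annotation(toy_seq, data.frame(name = c("X", "Y"),
                                        start = c(1, 3), end = c(9, 11)))
}

toy_genome_x <- function() {
  genome_annotation(toy_seq, data.frame(name = "X", start = 1, end = 9))
}

# independent translation oracle (Biostrings' own translator, not the
# package's codon-table walk)
oracle_translate <- function(chars) {
  as.character(Biostrings::translate(Biostrings::DNAString(
    paste(chars, collapse = "")), no.init.codon = TRUE))
}

# re-translation oracle for a substitution: per covering gene, translate the
# whole reference and mutated gene and diff the proteins
oracle_map <- function(genome, position, alt) {
  mut <- genome$chars
  mut[position] <- alt
  out <- list()
  for (i in seq_len(nrow(genome$genes))) {
    pos <- genome$gene_positions[[i]]
    if (!position %in% pos) next
    ref_aa <- strsplit(oracle_translate(genome$chars[pos]), "")[[1]]
    alt_aa <- strsplit(oracle_translate(mut[pos]), "")[[1]]
    changed <- which(ref_aa != alt_aa)
    residue <- if (length(changed)) changed else
      (match(position, pos) - 1L) %/% 3L + 1L
    out[[length(out) + 1L]] <- data.frame(
      gene = genome$genes$name[i], residue = residue,
      ref_aa = ref_aa[residue], alt_aa = alt_aa[residue],
      silent = ref_aa[residue] == alt_aa[residue],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(gene = character(), residue = integer(),
                                      ref_aa = character(),
                                      alt_aa = character(), silent = logical())
  out[order(match(out$gene, genome$genes$name)), , drop = FALSE]
}

# small random annotated genome (wrap + out-of-frame overlap included)
random_small_genome <- function(seed) {
  set.seed(seed)
  cfg <- synthetic_config(
    genome_length = sample(c(120L, 150L, 201L, 300L), 1),
    n_genes = sample(2:4, 1),
    coding_density = 0.6,
    n_overlap_pairs = sample(0:1, 1),
    overlap_nt = sample(c(7L, 10L, 16L), 1),
    wrap_gene = sample(c(TRUE, FALSE), 1),
    seed = seed
  )
  generate_genome(cfg, seed = seed + 7)
}

# write a lineage table to a temp TSV and return the path
write_subs_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
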