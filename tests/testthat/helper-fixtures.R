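# Fixture builders used across the test files. All sequence content is
# constructed in code; no data files.

# reverse-translate with a fixed codon choice (first codon of the table)
# so fixtures are deterministic without touching the RNG
fixed_codons <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  vapply(aa, function(a) names(GC)[GC == a][1], character(1))
}

fixed_cds <- function(protein, stop = "TAA") {
  paste0(c(unname(fixed_codons(protein)), stop), collapse = "")
}

# a tiny genome with one plus-strand CDS embedded at a known offset
one_orf_genome <- function(protein, pad5 = "GGGG", pad3 = "GGGG") {
  cds <- fixed_cds(protein)
  list(genome = c(chr1 = paste0(pad5, cds, pad3)),
       cds_start = nchar(pad5) + 1L,
       cds_end = nchar(pad5) + nchar(cds))
}

# hand-built GSSP mapping rows (contiguous placements)
gssp_row <- function(peptide, seqid, strand, start, end, unique = TRUE,
                     blocks = NULL, spans_junction = FALSE) {
  df <- data.frame(peptide = peptide, seqid = seqid, strand = strand,
                   frame = 0L, start = start, end = end,
                   spans_junction = spans_junction,
                   source_orf = NA_character_,
                   n_placements = if (unique) 1L else 2L,
                   is_unique = unique, stringsAsFactors = FALSE)
  df$blocks <- list(if (is.null(blocks))
    matrix(c(start, end), ncol = 2,
           dimnames = list(NULL, c("start", "end"))) else blocks)
  class(df) <- c("gssp_mappings", "data.frame")
  df
}

gssp_bind <- function(...) {
  df <- do.call(rbind, list(...))
  class(df) <- c("gssp_mappings", "data.frame")
  df
}

# simple annotation: one single-exon gene per row of the input
simple_annotation <- function(genes) {
  gene_annotation(genes, genes, genes)
}

# annotation/genome pair where gene "g1" encodes a known protein with a
# fully-tryptic peptide of >= 10 residues available for variant injection
saav_fixture <- function(protein = "MAAAGGGEDDDHHHKWWYYCCFFK",
                         strand = "+") {
  cds <- fixed_cds(protein)
  pad5 <- strrep("C", 12)
  pad3 <- strrep("C", 12)
  body <- if (strand == "+") cds else revcomp(cds)
  genome <- c(chr1 = paste0(pad5, body, pad3))
  s <- nchar(pad5) + 1L
  e <- nchar(pad5) + nchar(cds)
  ann <- simple_annotation(data.frame(
    seqid = "chr1", start = s, end = e, strand = strand, gene_id = "g1",
    stringsAsFactors = FALSE))
  list(genome = genome, ann = ann, proteome = c(g1 = protein),
       cds_start = s, cds_end = e)
}

# a small synthetic configuration that keeps unit tests fast
small_config <- function(seed = 101, ...) {
  synth_config(genome_length = 40000L, n_genes = 12L, n_novel_orfs = 3L,
               n_saavs = 3L, n_as_isoforms = 2L, n_revisions = 2L,
               seed = seed, ...)
}

random_aa_protein <- function(n) {
  paste0(c("M", sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                               ""), n - 1, replace = TRUE)), collapse = "")
}
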