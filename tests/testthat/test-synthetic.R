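test_that("configuration invariants are enforced", {
  expect_error(synth_config(genome_length = 5000), ">= 10000")
  expect_error(synth_config(n_genes = -1), ">= 0")
  expect_error(synth_config(frac_incorrect_psm = 1.5), "frac_incorrect_psm")
  expect_error(synth_config(tissues = character(0)), "tissue")
  cfg <- synth_config()
  expect_equal(cfg$tissues, c("P", "Sp", "St", "C", "Cp"))
  expect_equal(cfg$genome_length, 100000L)
  expect_equal(cfg$n_genes, 50L)
})

test_that("a degenerate configuration yields an empty genome and truth", {
  cfg <- synth_config(genome_length = 10000, n_genes = 0, n_novel_orfs = 0,
                      n_saavs = 0, n_as_isoforms = 0, n_revisions = 0)
  b <- generate_genome(cfg)
  expect_equal(nchar(b$genome[["chr1"]]), 10000L)
  expect_equal(length(b$known_proteome), 0L)
  expect_equal(nrow(b$truth$novel_loci), 0L)
  expect_equal(nrow(b$truth$saav_sites), 0L)
  expect_equal(nrow(b$truth$junctions), 0L)
  expect_equal(nrow(b$truth$revisions), 0L)
})

test_that("over-subscribed genomes raise a capacity error naming the limit", {
  expect_error(generate_genome(synth_config(genome_length = 12000,
                                            n_genes = 30)),
               "capacity")
  expect_error(generate_genome(synth_config(n_genes = 3, n_saavs = 5,
                                            n_as_isoforms = 0,
                                            n_revisions = 0)),
               "n_genes")
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- small_config(seed = 55)
  d1 <- tempfile(); d2 <- tempfile()
  write_synth_bundle(simulate_dataset(cfg), d1)
  write_synth_bundle(simulate_dataset(small_config(seed = 55)), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # and a different seed changes the genome
  d3 <- tempfile()
  write_synth_bundle(simulate_dataset(small_config(seed = 56)), d3)
  expect_false(tools::md5sum(file.path(d1, "genome.fasta")) ==
                 tools::md5sum(file.path(d3, "genome.fasta")))
})

test_that("every injected SAAV is a one-base, non-synonymous codon change", {
  b <- generate_genome(synth_config(genome_length = 60000, n_genes = 20,
                                    n_novel_orfs = 2, n_saavs = 15,
                                    n_as_isoforms = 2, n_revisions = 2,
                                    seed = 77))
  tr <- b$truth$saav_sites
  expect_equal(nrow(tr), 15L)
  GC <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(tr))) {
    rc <- strsplit(tr$ref_codon[i], "")[[1]]
    ac <- strsplit(tr$alt_codon[i], "")[[1]]
    expect_equal(sum(rc != ac), 1L)
    expect_equal(unname(GC[tr$ref_codon[i]]), tr$ref_aa[i])
    expect_equal(unname(GC[tr$alt_codon[i]]), tr$alt_aa[i])
    expect_false(tr$ref_aa[i] == tr$alt_aa[i])
    # the genome carries the reference base at the recorded position
    expect_equal(substr(b$genome[[tr$seqid[i]]], tr$position[i],
                        tr$position[i]), tr$ref_base[i])
  }
})

test_that("truth consistency: novel loci translate to their recorded proteins", {
  b <- generate_genome(small_config(seed = 88))
  for (i in seq_len(nrow(b$truth$novel_loci))) {
    tr <- b$truth$novel_loci[i, ]
    s <- substr(b$genome[[tr$seqid]], tr$start, tr$end)
    if (tr$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(aa, unname(b$novel_proteins[tr$event_id]))
  }
})

test_that("every novel locus yields >= 2 unique fully-tryptic peptides >= 7 aa", {
  b <- generate_genome(small_config(seed = 99))
  others <- il_collapse(c(b$known_proteome, b$novel_proteins))
  for (id in names(b$novel_proteins)) {
    peps <- digest_proteome(b$novel_proteins[[id]], 0L, min_len = 7)
    hay <- paste(others[setdiff(names(others), id)], collapse = "*")
    uniq <- peps[!vapply(il_collapse(peps), grepl, logical(1), x = hay,
                         fixed = TRUE)]
    expect_gte(length(uniq), 2L)
  }
})

test_that("annotated gene models are internally consistent with the genome", {
  b <- generate_genome(small_config(seed = 111))
  ann <- b$annotation
  for (gid in names(b$known_proteome)) {
    cds <- ann$cds[ann$cds$gene_id == gid]
    cds <- sort(cds, ignore.strand = TRUE)
    pieces <- vapply(seq_along(cds), function(i)
      substr(b$genome[["chr1"]], GenomicRanges::start(cds)[i],
             GenomicRanges::end(cds)[i]), character(1))
    s <- paste0(pieces, collapse = "")
    if (as.character(GenomicRanges::strand(cds))[1] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(aa, paste0(b$known_proteome[[gid]], "*"),
                 info = gid)
  }
  # annotated introns carry canonical GT..AG motifs
  intr <- ann$introns
  for (i in seq_along(intr)) {
    s <- substr(b$genome[["chr1"]], GenomicRanges::start(intr)[i],
                GenomicRanges::end(intr)[i])
    if (as.character(GenomicRanges::strand(intr))[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(substr(s, 1, 2), "GT")
    expect_equal(substr(s, nchar(s) - 1, nchar(s)), "AG")
  }
})

test_that("PSM simulation: counts, labels and the incorrect fraction", {
  set.seed(1)
  tab <- data.frame(peptide = replicate(10000, random_aa_protein(9)),
                    class = "novel", tissue = "P", stringsAsFactors = FALSE)
  cfg <- synth_config(frac_incorrect_psm = 0.2)
  psms <- simulate_psms(tab, cfg)
  expect_equal(sum(!psms$is_decoy), 10000)
  expect_equal(sum(psms$is_decoy), 10000)        # one decoy per target
  frac <- mean(!psms$truth_correct[!psms$is_decoy])
  ci <- qbinom(c(0.005, 0.995), 10000, 0.2) / 10000
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  # frac 0 -> every target carries the correct label
  psms0 <- simulate_psms(tab, synth_config(frac_incorrect_psm = 0))
  expect_true(all(psms0$truth_correct[!psms0$is_decoy]))
  expect_warning(empty <- simulate_psms(tab[0, ], cfg), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("junction truth records flank a GT..AG segment absent from annotation", {
  b <- generate_genome(small_config(seed = 123))
  jt <- b$truth$junctions
  expect_gt(nrow(jt), 0)
  for (i in seq_len(nrow(jt))) {
    i1 <- jt$donor_end[i] + 1L; i2 <- jt$acceptor_start[i] - 1L
    s <- substr(b$genome[["chr1"]], i1, i2)
    if (jt$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(substr(s, 1, 2), "GT")
    expect_equal(substr(s, nchar(s) - 1, nchar(s)), "AG")
    keys <- paste(GenomicRanges::start(b$annotation$introns),
                  GenomicRanges::end(b$annotation$introns))
    expect_false(paste(i1, i2) %in% keys)
  }
})
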