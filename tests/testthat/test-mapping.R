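test_that("known/orphan partition by substring with I/L equivalence", {
  expect_equal(match_known("PEPTIDE", c(P1 = "MKPEPTIDER"))$known, "PEPTIDE")
  expect_equal(match_known("PEPTLDE", c(P1 = "MKPEPTIDER"))$known, "PEPTLDE")
  expect_equal(match_known("PEPTLDE", c(P1 = "MKPEPTIDER"),
                           il_equivalent = FALSE)$orphan, "PEPTLDE")
  expect_error(match_known("PEP", character(0)), "empty")
  expect_error(match_known(c("A", ""), c(P = "MAK")), "empty peptide")
})

test_that("partition equals a brute-force substring scan on random input", {
  set.seed(11)
  proteome <- setNames(replicate(15, random_aa_protein(80)),
                       paste0("pr", 1:15))
  peptides <- c(
    vapply(1:20, function(i) {           # true substrings
      p <- sample(proteome, 1)
      s <- sample(1:(nchar(p) - 9), 1)
      substr(p, s, s + 8)
    }, character(1)),
    replicate(20, random_aa_protein(9))) # mostly non-matching
  part <- match_known(peptides, proteome)
  truth <- oracle_known(peptides, proteome)
  expect_setequal(part$known, unique(peptides[truth]))
  expect_setequal(part$orphan, unique(peptides[!truth]))
})

test_that("contiguous placements have correct coordinate arithmetic", {
  prot <- "MAAADDDKEEEFFFK"
  fx <- one_orf_genome(prot, pad5 = "TAAGG", pad3 = "CCTAA")
  db <- build_search_db(NULL, six_frame_translate(fx$genome, min_orf_len = 5))
  g <- map_to_genome("MAAADDDK", db)
  hit <- g[g$peptide == "MAAADDDK" & !is.na(g$seqid), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$strand, "+")
  expect_equal(hit$start, fx$cds_start)
  expect_equal(hit$end, fx$cds_start + 3 * 8 - 1)
  # peptide at an interior offset
  g2 <- map_to_genome("EEEFFFK", db)
  h2 <- g2[!is.na(g2$seqid), ]
  expect_equal(h2$start, fx$cds_start + 3 * 8)
  # translate-back reproduces the peptide
  expect_equal(translate_blocks(h2$blocks[[1]], fx$genome[["chr1"]], "+"),
               "EEEFFFK")
})

test_that("minus-strand placements map onto the forward axis correctly", {
  prot <- "MWWWCCCKYYYHHHK"
  cds <- fixed_cds(prot)
  genome <- c(chr1 = paste0("GGGGG", revcomp(cds), "AACCA"))
  db <- build_search_db(NULL, six_frame_translate(genome, min_orf_len = 5))
  g <- map_to_genome("YYYHHHK", db)
  h <- g[!is.na(g$seqid), ]
  expect_equal(h$strand, "-")
  expect_equal(translate_blocks(h$blocks[[1]], genome[["chr1"]], "-"),
               "YYYHHHK")
  # minus-strand CDS occupies bases 6..(5 + len); peptide is residues 9..15
  cds_end_fwd <- 5 + nchar(cds)
  expect_equal(h$end, cds_end_fwd - 3 * 8)
})

test_that("multi-locus peptides are flagged non-unique; unplaced retained", {
  prot <- "MAAADDDKEEEFFFK"
  cds <- fixed_cds(prot)
  genome <- c(chr1 = paste0("GG", cds, "TTTTTTTTTTTT", cds, "CC"))
  db <- build_search_db(NULL, six_frame_translate(genome, min_orf_len = 5))
  g <- map_to_genome(c("MAAADDDK", "WWWWWWWW"), db)
  dd <- g[g$peptide == "MAAADDDK" & !is.na(g$seqid), ]
  expect_equal(nrow(dd), 2)
  expect_true(all(!dd$is_unique))
  un <- g[g$peptide == "WWWWWWWW", ]
  expect_equal(un$n_placements, 0L)
  expect_true(is.na(un$seqid))
})

test_that("decoy entries are never used for genomic placement", {
  # the reversed decoy of P1 contains KDDD...; searching the reversed
  # peptide must not produce a placement
  prot <- "MAAADDDKEEEFFFK"
  fx <- one_orf_genome(prot)
  db <- build_search_db(c(P1 = prot),
                        six_frame_translate(fx$genome, min_orf_len = 5))
  rev_pep <- paste(rev(strsplit("MAAADDDK", "")[[1]]), collapse = "")
  g <- map_to_genome(rev_pep, db)
  expect_equal(g$n_placements, 0L)
})

test_that("junction-spanning placement is found at engineered coordinates", {
  # gene: exon1 | 200 bp GT..AG intron | exon2; peptide straddles the join
  set.seed(12)
  protA <- "MGGGGWWK"          # exon1 codons
  protB <- "DDDHHHCCK"         # exon2 codons
  cdsA <- paste0(unname(fixed_codons(protA)), collapse = "")
  cdsB <- paste0(unname(fixed_codons(protB)), collapse = "")
  intron <- paste0("GT", paste0(sample(c("A", "C"), 196, TRUE),
                                collapse = ""), "AG")
  pad5 <- paste0(sample(c("A", "C"), 30, TRUE), collapse = "")
  pad3 <- paste0(sample(c("A", "C"), 30, TRUE), collapse = "")
  genome <- c(chr1 = paste0(pad5, cdsA, intron, cdsB, "TAA", pad3))
  pep <- "GGGGWWKDDDHHHCCK"    # 7 residues exon1 + 9 residues exon2
  cand <- find_splice_mapping(pep, genome, max_intron = 1000)
  expect_equal(nrow(cand), 1)
  expect_true(cand$spans_junction)
  donor_end <- 30 + nchar(cdsA)              # last exonic base before intron
  acceptor_start <- donor_end + nchar(intron) + 1  # first exonic base after
  b <- cand$blocks[[1]]
  expect_equal(unname(b[1, 2]), donor_end)
  expect_equal(unname(b[2, 1]), acceptor_start)
  expect_equal(translate_blocks(b, genome[["chr1"]], "+"), pep)
  # mutating the acceptor motif removes the candidate
  g2 <- genome
  substr(g2[["chr1"]], acceptor_start - 1, acceptor_start - 1) <- "C"
  expect_equal(nrow(find_splice_mapping(pep, c(chr1 = g2[["chr1"]]),
                                        max_intron = 1000)), 0)
})

test_that("codon-straddling junctions (phase 1/2) reassemble correctly", {
  # place a junction inside the codon of residue 6 of an 11-mer: phase 1
  set.seed(13)
  pep <- "MFFFWDHHHCW"
  cods <- unname(fixed_codons(pep))
  cds <- paste0(cods, collapse = "")
  b1 <- substr(cds, 1, 16)    # 5 codons + 1 nt of codon 6
  b2 <- substr(cds, 17, nchar(cds))
  intron <- paste0("GT", paste0(sample(c("A", "C"), 80, TRUE),
                                collapse = ""), "AG")
  genome <- c(chr1 = paste0("CCCCCCCCCC", b1, intron, b2, "CCCCCCCCCC"))
  cand <- find_splice_mapping(pep, genome, max_intron = 500)
  expect_gte(nrow(cand), 1)
  widths <- vapply(cand$blocks, function(b) sum(b[, 2] - b[, 1] + 1),
                   numeric(1))
  expect_true(all(widths == 3 * nchar(pep)))
  ok <- vapply(seq_len(nrow(cand)), function(i)
    translate_blocks(cand$blocks[[i]], genome[["chr1"]],
                     cand$strand[i]) == pep, logical(1))
  expect_true(all(ok))
  expect_true(any(vapply(cand$blocks, function(b)
    b[1, 2] == 10 + 16, logical(1))))
})

test_that("contiguously placeable peptides yield no junction candidates", {
  prot <- "MAAADDDKEEEFFFK"
  fx <- one_orf_genome(prot)
  expect_equal(nrow(find_splice_mapping("AAADDDKEE", fx$genome,
                                        max_intron = 1000)), 0)
})

test_that("splice search equals the splice-then-translate oracle", {
  set.seed(14)
  for (rep in 1:3) {
    pep <- random_aa_protein(10)
    cods <- unname(fixed_codons(pep))
    k <- sample(4:6, 1)
    b1 <- paste0(cods[1:k], collapse = "")
    b2 <- paste0(cods[(k + 1):10], collapse = "")
    intron <- paste0("GT", paste0(sample(c("A", "C", "G", "T"), 60, TRUE),
                                  collapse = ""), "AG")
    pad <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
    genome <- c(chr1 = paste0(pad(40), b1, intron, b2, pad(40)))
    got <- find_splice_mapping(pep, genome, max_intron = 300,
                               check_contiguous = FALSE)
    got_keys <- sort(unique(vapply(seq_len(nrow(got)), function(i) {
      j <- got$blocks[[i]]
      j <- j[order(j[, 1]), , drop = FALSE]
      paste(got$seqid[i], got$strand[i], j[1, 2] + 1, j[2, 1] - 1)
    }, character(1))))
    exp_keys <- oracle_splice_junctions(pep, genome, max_intron = 300)
    expect_equal(got_keys, exp_keys, info = paste("rep", rep))
  }
})

test_that("locus clustering groups nearby unique placements", {
  g <- gssp_bind(gssp_row("AAAAAAA", "chr1", "+", 100, 129),
                 gssp_row("CCCCCCC", "chr1", "+", 600, 629),
                 gssp_row("DDDDDDD", "chr1", "+", 5000, 5029),
                 gssp_row("EEEEEEE", "chr1", "-", 130, 159))
  cl <- cluster_gssp_loci(g, gap = 1000)
  expect_equal(length(unique(cl$locus_id)), 3)  # strand separates the last
  expect_equal(cl$locus_id[1], cl$locus_id[2])
  expect_false(cl$locus_id[1] == cl$locus_id[3])
})

test_that("BED12 output encodes spliced placements with 0-based blocks", {
  b <- matrix(c(101L, 130L, 301L, 330L), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  g <- gssp_row("SPLICEPEP", "chr1", "+", 101, 330, blocks = b,
                spans_junction = TRUE)
  f <- tempfile()
  write_gssp_bed(g, f)
  line <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(line[1:3], c("chr1", "100", "330"))
  expect_equal(line[10], "2")
  expect_equal(line[11], "30,30,")
  expect_equal(line[12], "0,200,")
})
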