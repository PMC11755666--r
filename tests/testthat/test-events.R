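ann1 <- simple_annotation(data.frame(
  seqid = "chr1", start = 5000L, end = 6000L, strand = "+",
  gene_id = "geneA", stringsAsFactors = FALSE))

test_that("novel calls need two unique GSSPs in an unannotated region", {
  one <- gssp_row("AAAAAAA", "chr1", "+", 1000, 1029)
  expect_equal(nrow(call_novel_genes(one, ann1)), 0)
  two <- gssp_bind(one, gssp_row("CCCCCCC", "chr1", "+", 1100, 1129))
  calls <- call_novel_genes(two, ann1)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "novel_gene")
  expect_equal(calls$n_peptides, 2)
  expect_equal(calls$subtype, "intergenic")
  # non-unique placements never count as evidence
  two$is_unique[2] <- FALSE
  expect_equal(nrow(call_novel_genes(two, ann1)), 0)
})

test_that("same-strand gene overlap suppresses novel calls; antisense is flagged", {
  near_gene <- gssp_bind(gssp_row("AAAAAAA", "chr1", "+", 4990, 5019),
                         gssp_row("CCCCCCC", "chr1", "+", 5100, 5129))
  expect_equal(nrow(call_novel_genes(near_gene, ann1)), 0)
  anti <- gssp_bind(gssp_row("AAAAAAA", "chr1", "-", 5100, 5129),
                    gssp_row("CCCCCCC", "chr1", "-", 5200, 5229))
  calls <- call_novel_genes(anti, ann1)
  expect_equal(calls$subtype, "antisense")
})

test_that("revisions require partial overlap with exactly one gene", {
  # extends 3' of the annotated end on the plus strand
  ext <- gssp_bind(gssp_row("AAAAAAA", "chr1", "+", 5950, 5979),
                   gssp_row("CCCCCCC", "chr1", "+", 6010, 6039))
  r <- call_revisions(ext, ann1)
  expect_equal(nrow(r), 1)
  expect_equal(r$overlapped_gene, "geneA")
  expect_equal(r$subtype, "3prime_extension")
  # the same locus is never simultaneously a novel gene
  expect_equal(nrow(call_novel_genes(ext, ann1)), 0)

  # fully inside the annotated CDS -> annotation-consistent, no call
  inside <- gssp_row("DDDDDDD", "chr1", "+", 5200, 5229)
  expect_equal(nrow(call_revisions(inside, ann1)), 0)

  # a locus overlapping two genes is reported separately as ambiguous
  ann2 <- simple_annotation(data.frame(
    seqid = "chr1", start = c(5000L, 6050L), end = c(6000L, 7000L),
    strand = "+", gene_id = c("geneA", "geneB"), stringsAsFactors = FALSE))
  wide <- gssp_bind(gssp_row("AAAAAAA", "chr1", "+", 5990, 6019),
                    gssp_row("CCCCCCC", "chr1", "+", 6040, 6069))
  r2 <- call_revisions(wide, ann2)
  expect_equal(nrow(r2), 0)
  expect_equal(nrow(attr(r2, "ambiguous")), 1)
  expect_match(attr(r2, "ambiguous")$overlapped_gene, "geneA,geneB")
})

test_that("intronic GSSPs on the gene strand are intronic revisions", {
  ann3 <- gene_annotation(
    genes = data.frame(seqid = "chr1", start = 5000L, end = 6000L,
                       strand = "+", gene_id = "geneA"),
    exons = data.frame(seqid = "chr1", start = c(5000L, 5700L),
                       end = c(5400L, 6000L), strand = "+",
                       gene_id = "geneA"),
    cds = data.frame(seqid = "chr1", start = c(5000L, 5700L),
                     end = c(5400L, 6000L), strand = "+",
                     gene_id = "geneA"))
  g <- gssp_row("AAAAAAA", "chr1", "+", 5450, 5479)
  r <- call_revisions(g, ann3)
  expect_equal(r$subtype, "intronic")
  expect_equal(r$overlapped_gene, "geneA")
})

test_that("novel junctions are called and annotated introns discarded", {
  ann3 <- gene_annotation(
    genes = data.frame(seqid = "chr1", start = 5000L, end = 6000L,
                       strand = "+", gene_id = "geneA"),
    exons = data.frame(seqid = "chr1", start = c(5000L, 5700L),
                       end = c(5400L, 6000L), strand = "+",
                       gene_id = "geneA"),
    cds = data.frame(seqid = "chr1", start = c(5000L, 5700L),
                     end = c(5400L, 6000L), strand = "+",
                     gene_id = "geneA"))
  jblocks <- function(e1, s2) matrix(c(e1 - 14L, e1, s2, s2 + 14L),
                                     ncol = 2, byrow = TRUE,
                                     dimnames = list(NULL, c("start", "end")))
  five <- do.call(gssp_bind, lapply(1:5, function(i)
    gssp_row(paste0(strrep(LETTERS[i], 7)), "chr1", "+", 1000 - i, 1400 + i,
             blocks = jblocks(1100L, 1300L), spans_junction = TRUE)))
  calls <- call_as_events(five, ann3)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "as_junction")
  expect_equal(calls$n_peptides, 5)
  expect_equal(calls$donor_end, 1100L)
  expect_equal(calls$acceptor_start, 1300L)
  # junction equal to the annotated intron (5401..5699) -> no call
  known <- gssp_row("GGGGGGG", "chr1", "+", 5380, 5720,
                    blocks = jblocks(5400L, 5700L), spans_junction = TRUE)
  expect_equal(nrow(call_as_events(known, ann3)), 0)
  # two distinct unannotated junctions -> two calls
  two <- gssp_bind(
    gssp_row("HHHHHHH", "chr1", "+", 1085, 1315,
             blocks = jblocks(1100L, 1300L), spans_junction = TRUE),
    gssp_row("MMMMMMM", "chr1", "+", 2085, 2315,
             blocks = jblocks(2100L, 2300L), spans_junction = TRUE))
  expect_equal(nrow(call_as_events(two, ann3)), 2)
})

test_that("tissue presence and specificity follow accepted supporting PSMs", {
  ev <- call_novel_genes(
    gssp_bind(gssp_row("AAAAAAA", "chr1", "+", 1000, 1029),
              gssp_row("CCCCCCC", "chr1", "+", 1100, 1129)), ann1)
  psms <- data.frame(peptide = c("AAAAAAA", "CCCCCCC", "AAAAAAA"),
                     tissue = c("Cp", "Cp", "St"),
                     accepted = c(TRUE, TRUE, FALSE),
                     is_decoy = FALSE, stringsAsFactors = FALSE)
  out <- tissue_specificity(ev, psms)
  expect_equal(out$tissues_present[[1]], "Cp")
  expect_true(out$tissue_specific)
  psms$accepted[3] <- TRUE
  out2 <- tissue_specificity(ev, psms)
  expect_setequal(out2$tissues_present[[1]], c("Cp", "St"))
  expect_false(out2$tissue_specific)
  psms$accepted <- FALSE
  expect_error(tissue_specificity(ev, psms), "zero accepted")
})

test_that("pipeline thresholds validate", {
  expect_error(pipeline_config(dep_fc = -1), "strictly positive")
  expect_error(pipeline_config(saav_max_variants = 0), "positive")
  cfg <- pipeline_config()
  expect_equal(cfg$min_gssps_per_novel, 2L)
  expect_equal(cfg$saav_min_len, 10L)
  expect_equal(cfg$fdr_threshold, 0.01)
  expect_equal(cfg$ptm_max_shift, 250)
})
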