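#' @importFrom GenomicRanges GRanges start end strand seqnames reduce
#'   findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

#' Gene-model container
#'
#' Holds the annotation the pipeline maps against: gene spans, exons and CDS
#' intervals (1-based inclusive, `GRanges` convention) plus the derived
#' annotated-intron set. One transcript per gene is assumed, which matches
#' the GFF3 the synthetic generator writes; multi-transcript GFF3 is
#' accepted and flattened per gene.
#'
#' @param genes,exons,cds data.frames with columns `seqid`, `start`, `end`,
#'   `strand`, `gene_id`.
#' @return an object of class `gene_annotation`: list of `GRanges` `genes`,
#'   `exons`, `cds`, `introns` (each carrying `gene_id` metadata).
#' @export
gene_annotation <- function(genes, exons, cds) {
  as_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0L)
      return(GenomicRanges::GRanges(gene_id = character()))
    gr <- GenomicRanges::GRanges(df$seqid,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    gr$gene_id <- df$gene_id
    gr
  }
  g <- as_gr(genes); e <- as_gr(exons); cd <- as_gr(cds)
  introns <- derive_introns(g, e)
  structure(list(genes = g, exons = e, cds = cd, introns = introns),
            class = "gene_annotation")
}

derive_introns <- function(genes, exons) {
  out <- GenomicRanges::GRanges(gene_id = character())
  for (gid in unique(genes$gene_id)) {
    ex <- exons[exons$gene_id == gid]
    if (length(ex) < 2L) next
    ex <- sort(ex, ignore.strand = TRUE)
    s <- GenomicRanges::end(ex)[-length(ex)] + 1L
    e <- GenomicRanges::start(ex)[-1L] - 1L
    keep <- s <= e
    if (!any(keep)) next
    gr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(ex))[1],
      IRanges::IRanges(s[keep], e[keep]),
      strand = as.character(GenomicRanges::strand(ex))[1])
    gr$gene_id <- gid
    out <- c(out, gr)
  }
  out
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`, `exon` and `CDS` features and resolves
#' exon/CDS parentage through the mRNA layer to gene identifiers.
#'
#' @param path GFF3 file path.
#' @return a [gene_annotation()] object.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  get_id <- function(x) as.character(x)
  ids <- get_id(md$ID)
  parent <- vapply(md$Parent, function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[[1]]),
    character(1))
  df_of <- function(idx, gene_ids) {
    data.frame(seqid = as.character(GenomicRanges::seqnames(gr))[idx],
               start = GenomicRanges::start(gr)[idx],
               end = GenomicRanges::end(gr)[idx],
               strand = as.character(GenomicRanges::strand(gr))[idx],
               gene_id = gene_ids, stringsAsFactors = FALSE)
  }
  gi <- which(type == "gene")
  mi <- which(type == "mRNA")
  tx2gene <- stats::setNames(parent[mi], ids[mi])
  feat_gene <- function(idx) {
    p <- parent[idx]
    ifelse(p %in% names(tx2gene), unname(tx2gene[p]), p)
  }
  ei <- which(type == "exon")
  ci <- which(type == "CDS")
  gene_annotation(df_of(gi, ids[gi]), df_of(ei, feat_gene(ei)),
                  df_of(ci, feat_gene(ci)))
}

#' Genomic coordinates of the codon encoding one protein residue
#'
#' Walks the CDS blocks of a gene in coding order (descending genomic
#' coordinate for minus-strand genes) and returns the three genomic base
#' positions of the codon for residue `residue_index`, in codon order.
#'
#' @param ann a `gene_annotation`.
#' @param gene_id gene identifier.
#' @param residue_index 1-based residue position in the encoded protein.
#' @return a list with `seqid`, `strand`, and `positions` (integer vector of
#'   3 forward-axis coordinates in codon order; descending on the minus
#'   strand).
#' @export
codon_genomic_coords <- function(ann, gene_id, residue_index) {
  cds <- ann$cds[ann$cds$gene_id == gene_id]
  if (length(cds) == 0L) stop("no CDS for gene ", gene_id)
  strand <- as.character(GenomicRanges::strand(cds))[1]
  cds <- sort(cds, ignore.strand = TRUE)
  pos <- unlist(lapply(seq_along(cds), function(i)
    seq(GenomicRanges::start(cds)[i], GenomicRanges::end(cds)[i])))
  if (strand == "-") pos <- rev(pos)
  i0 <- 3L * (residue_index - 1L)
  if (i0 + 3L > length(pos))
    stop("residue ", residue_index, " beyond CDS of ", gene_id)
  list(seqid = as.character(GenomicRanges::seqnames(cds))[1],
       strand = strand, positions = pos[(i0 + 1L):(i0 + 3L)])
}

#' Write gene models (or event calls) as GFF3
#'
#' @param features a data.frame with columns `seqid`, `source`, `type`,
#'   `start`, `end`, `score`, `strand`, `phase`, `attributes`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0L)
    writeLines(paste(features$seqid, features$source, features$type,
                     features$start, features$end, features$score,
                     features$strand, features$phase, features$attributes,
                     sep = "\t"), con)
  invisible(path)
}
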