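#' Pipeline thresholds
#'
#' Collects every tunable threshold of the event-calling analysis with the
#' study defaults: novel proteins need at least two unique GSSPs; SAAV
#' candidate peptides need at least 10 residues and at most two
#' non-synonymous variants; identifications are filtered at 1% class-specific
#' FDR; differential expression needs |fold change| >= 1.5 at p <= 0.05;
#' modification mass shifts are capped at 250 Da.
#'
#' @param min_gssps_per_novel minimum distinct unique GSSPs per novel locus.
#' @param saav_min_len minimum peptide length (residues) for SAAV calling.
#' @param saav_max_variants maximum non-synonymous variants per peptide.
#' @param fdr_threshold class-specific FDR acceptance threshold.
#' @param dep_fc fold-change gate for differential expression (linear scale).
#' @param dep_p p-value gate for differential expression.
#' @param ptm_max_shift maximum modification mass shift considered (Da).
#' @param ptm_tolerance delta-mass matching tolerance (Da).
#' @param start_codons recognised translation starts.
#' @param locus_gap clustering gap for GSSP loci (bases).
#' @param min_orf_len minimum ORF length (codons) for database building.
#' @param max_intron maximum intron length (bases) for splice mapping.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_gssps_per_novel = 2L, saav_min_len = 10L,
                            saav_max_variants = 2L, fdr_threshold = 0.01,
                            dep_fc = 1.5, dep_p = 0.05,
                            ptm_max_shift = 250, ptm_tolerance = 0.01,
                            start_codons = DEFAULT_START_CODONS,
                            locus_gap = 1000L, min_orf_len = 20L,
                            max_intron = 10000L) {
  cfg <- list(min_gssps_per_novel = as.integer(min_gssps_per_novel),
              saav_min_len = as.integer(saav_min_len),
              saav_max_variants = as.integer(saav_max_variants),
              fdr_threshold = fdr_threshold, dep_fc = dep_fc, dep_p = dep_p,
              ptm_max_shift = ptm_max_shift, ptm_tolerance = ptm_tolerance,
              start_codons = start_codons, locus_gap = as.integer(locus_gap),
              min_orf_len = as.integer(min_orf_len),
              max_intron = as.integer(max_intron))
  num <- c("min_gssps_per_novel", "saav_min_len", "saav_max_variants",
           "fdr_threshold", "dep_fc", "dep_p", "ptm_max_shift",
           "ptm_tolerance", "locus_gap", "min_orf_len", "max_intron")
  if (any(vapply(cfg[num], function(x) x <= 0, logical(1))))
    stop("all pipeline thresholds must be strictly positive")
  if (cfg$saav_max_variants < 1L) stop("saav_max_variants must be >= 1")
  structure(cfg, class = "pipeline_config")
}

empty_events <- function() {
  df <- data.frame(kind = character(), locus_id = character(),
                   seqid = character(), strand = character(),
                   start = integer(), end = integer(),
                   n_peptides = integer(), overlapped_gene = character(),
                   subtype = character(), donor_end = integer(),
                   acceptor_start = integer(), stringsAsFactors = FALSE)
  df$peptides <- list()
  class(df) <- c("event_calls", "data.frame")
  df
}

event_row <- function(kind, locus_id, seqid, strand, start, end, peptides,
                      overlapped_gene = NA_character_,
                      subtype = NA_character_, donor_end = NA_integer_,
                      acceptor_start = NA_integer_) {
  df <- data.frame(kind = kind, locus_id = locus_id, seqid = seqid,
                   strand = strand, start = start, end = end,
                   n_peptides = length(peptides),
                   overlapped_gene = overlapped_gene, subtype = subtype,
                   donor_end = donor_end, acceptor_start = acceptor_start,
                   stringsAsFactors = FALSE)
  df$peptides <- list(sort(unique(peptides)))
  df
}

bind_events <- function(rows) {
  df <- rbind_rows(rows)
  if (is.null(df)) return(empty_events())
  class(df) <- c("event_calls", "data.frame")
  df
}

# locus-level helper: same-strand / antisense gene overlaps of one interval
locus_gene_overlap <- function(seqid, strand, start, end, ann) {
  g <- ann$genes
  if (length(g) == 0L)
    return(list(same = character(0), anti = character(0)))
  q <- GenomicRanges::GRanges(seqid, IRanges::IRanges(start, end),
                              strand = strand)
  same <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(q, g, ignore.strand = FALSE))
  all_ <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(q, g, ignore.strand = TRUE))
  list(same = unique(g$gene_id[same]),
       anti = unique(g$gene_id[setdiff(all_, same)]))
}

#' Call novel protein-coding regions from unique GSSPs
#'
#' Clusters uniquely placed, contiguous GSSPs into candidate loci and calls
#' a novel protein-coding region for every locus that has no same-strand
#' overlap with any annotated gene span and is supported by at least
#' `min_gssps_per_novel` distinct unique peptides. Loci whose only overlap
#' is on the opposite strand are still called, flagged `"antisense"`.
#'
#' @param gssps a `gssp_mappings` data.frame; only rows with
#'   `is_unique = TRUE` and `spans_junction = FALSE` are used (callers
#'   should pass FDR-surviving peptides only).
#' @param ann a [gene_annotation()].
#' @param config a [pipeline_config()].
#' @return an `event_calls` data.frame with `kind = "novel_gene"`.
#' @export
call_novel_genes <- function(gssps, ann, config = pipeline_config()) {
  use <- gssps[!is.na(gssps$seqid) & gssps$is_unique & !gssps$spans_junction,
               , drop = FALSE]
  if (nrow(use) == 0L) return(empty_events())
  use <- cluster_gssp_loci(use, gap = config$locus_gap)
  loci <- attr(use, "loci")
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    li <- loci[i, ]
    ov <- locus_gene_overlap(li$seqid, li$strand, li$start, li$end, ann)
    if (length(ov$same) > 0L) next
    peps <- unique(use$peptide[use$locus_id == li$locus_id])
    if (length(peps) < config$min_gssps_per_novel) next
    rows[[length(rows) + 1L]] <- event_row(
      "novel_gene", li$locus_id, li$seqid, li$strand, li$start, li$end,
      peps, subtype = if (length(ov$anti) > 0L) "antisense" else "intergenic")
  }
  bind_events(rows)
}

# TRUE when every block of the placement lies inside the CDS of `gene_id`
fully_in_cds <- function(blocks, seqid, strand, gene_id, ann) {
  cds <- ann$cds[ann$cds$gene_id == gene_id]
  if (length(cds) == 0L) return(FALSE)
  q <- GenomicRanges::GRanges(rep(seqid, nrow(blocks)),
                              IRanges::IRanges(blocks[, 1], blocks[, 2]),
                              strand = strand)
  w <- GenomicRanges::findOverlaps(q, cds, type = "within",
                                   ignore.strand = FALSE)
  length(unique(S4Vectors::queryHits(w))) == nrow(blocks)
}

#' Call gene-model revisions
#'
#' A locus of unique GSSPs that partially overlaps exactly one annotated
#' same-strand gene — it is neither fully inside that gene's annotated CDS
#' nor fully outside the gene span — is called a revision of that gene.
#' Placements fully inside annotated CDS are discarded as
#' annotation-consistent. Loci overlapping two or more genes are returned
#' separately as ambiguous (attribute `"ambiguous"` on the result).
#'
#' Revision subtypes: `"5prime_extension"` / `"3prime_extension"` when the
#' locus extends beyond the gene boundary (strand-aware), `"intronic"` when
#' all supporting placements fall in annotated introns, `"internal"`
#' otherwise.
#'
#' @inheritParams call_novel_genes
#' @return an `event_calls` data.frame with `kind = "revision"`;
#'   `attr(, "ambiguous")` holds loci overlapping several genes.
#' @export
call_revisions <- function(gssps, ann, config = pipeline_config()) {
  use <- gssps[!is.na(gssps$seqid) & gssps$is_unique & !gssps$spans_junction,
               , drop = FALSE]
  if (nrow(use) == 0L) {
    out <- empty_events(); attr(out, "ambiguous") <- empty_events()
    return(out)
  }
  use <- cluster_gssp_loci(use, gap = config$locus_gap)
  loci <- attr(use, "loci")
  rows <- list(); amb <- list()
  for (i in seq_len(nrow(loci))) {
    li <- loci[i, ]
    ov <- locus_gene_overlap(li$seqid, li$strand, li$start, li$end, ann)
    if (length(ov$same) == 0L) next
    sub <- use[use$locus_id == li$locus_id, , drop = FALSE]
    if (length(ov$same) >= 2L) {
      amb[[length(amb) + 1L]] <- event_row(
        "ambiguous_revision", li$locus_id, li$seqid, li$strand, li$start,
        li$end, unique(sub$peptide),
        overlapped_gene = paste(ov$same, collapse = ","))
      next
    }
    gid <- ov$same
    consistent <- vapply(seq_len(nrow(sub)), function(j)
      fully_in_cds(sub$blocks[[j]], sub$seqid[j], sub$strand[j], gid, ann),
      logical(1))
    sub <- sub[!consistent, , drop = FALSE]
    if (nrow(sub) == 0L) next
    gene <- ann$genes[ann$genes$gene_id == gid]
    gs <- GenomicRanges::start(gene); ge <- GenomicRanges::end(gene)
    lstart <- min(sub$start); lend <- max(sub$end)
    strand <- li$strand
    subtype <- if (lstart < gs && lend <= ge) {
      if (strand == "+") "5prime_extension" else "3prime_extension"
    } else if (lend > ge && lstart >= gs) {
      if (strand == "+") "3prime_extension" else "5prime_extension"
    } else if (lstart >= gs && lend <= ge) {
      introns <- ann$introns[ann$introns$gene_id == gid]
      all_intronic <- length(introns) > 0L &&
        all(vapply(seq_len(nrow(sub)), function(j) {
          b <- sub$blocks[[j]]
          q <- GenomicRanges::GRanges(rep(sub$seqid[j], nrow(b)),
                                      IRanges::IRanges(b[, 1], b[, 2]),
                                      strand = sub$strand[j])
          w <- GenomicRanges::findOverlaps(q, introns, type = "within",
                                           ignore.strand = FALSE)
          length(unique(S4Vectors::queryHits(w))) == nrow(b)
        }, logical(1)))
      if (all_intronic) "intronic" else "internal"
    } else "internal"
    rows[[length(rows) + 1L]] <- event_row(
      "revision", li$locus_id, li$seqid, strand, lstart, lend,
      unique(sub$peptide), overlapped_gene = gid, subtype = subtype)
  }
  out <- bind_events(rows)
  attr(out, "ambiguous") <- bind_events(amb)
  out
}

# forward-axis junction coordinates of a two-block placement:
# donor_end = last exonic base before the intron, acceptor_start = first
# exonic base after it (forward axis regardless of strand)
junction_of <- function(blocks) {
  b <- blocks[order(blocks[, 1]), , drop = FALSE]
  c(donor_end = unname(b[1, 2]), acceptor_start = unname(b[2, 1]))
}

#' Call novel alternative-splicing junctions
#'
#' Groups junction-spanning GSSP placements by their exact intron
#' coordinates and calls every junction that is absent from the annotated
#' intron set; junctions matching an annotated intron are discarded as
#' known splice forms.
#'
#' @param junction_gssps a `gssp_mappings` data.frame of
#'   `spans_junction = TRUE` placements (unique placements only are used).
#' @param ann a [gene_annotation()].
#' @return an `event_calls` data.frame with `kind = "as_junction"`,
#'   carrying `donor_end` / `acceptor_start`.
#' @export
call_as_events <- function(junction_gssps, ann) {
  use <- junction_gssps[!is.na(junction_gssps$seqid) &
                          junction_gssps$spans_junction &
                          junction_gssps$is_unique, , drop = FALSE]
  if (nrow(use) == 0L) return(empty_events())
  jc <- t(vapply(use$blocks, junction_of, numeric(2)))
  use$donor_end <- as.integer(jc[, 1])
  use$acceptor_start <- as.integer(jc[, 2])
  intr <- ann$introns
  known <- rep(FALSE, nrow(use))
  if (length(intr) > 0L) {
    key_ann <- paste(as.character(GenomicRanges::seqnames(intr)),
                     as.character(GenomicRanges::strand(intr)),
                     GenomicRanges::start(intr), GenomicRanges::end(intr))
    key_use <- paste(use$seqid, use$strand, use$donor_end + 1L,
                     use$acceptor_start - 1L)
    known <- key_use %in% key_ann
  }
  use <- use[!known, , drop = FALSE]
  if (nrow(use) == 0L) return(empty_events())
  grp <- paste(use$seqid, use$strand, use$donor_end, use$acceptor_start,
               sep = "|")
  rows <- lapply(split(seq_len(nrow(use)), grp), function(idx) {
    s <- use[idx, , drop = FALSE]
    event_row("as_junction",
              paste0("junction_", s$seqid[1], "_", s$donor_end[1]),
              s$seqid[1], s$strand[1], min(s$start), max(s$end),
              unique(s$peptide), donor_end = s$donor_end[1],
              acceptor_start = s$acceptor_start[1])
  })
  bind_events(rows[order(names(rows))])
}

#' Annotate called events with tissue presence
#'
#' For every event, the set of tissues contributing at least one accepted
#' supporting PSM; an event seen in exactly one tissue is tissue-specific.
#'
#' @param events an `event_calls` data.frame.
#' @param psms a PSM data.frame with `peptide` and `tissue` columns; when an
#'   `accepted` column is present only accepted rows count.
#' @return `events` with list-column `tissues_present` and logical
#'   `tissue_specific` added.
#' @export
tissue_specificity <- function(events, psms) {
  if ("accepted" %in% names(psms))
    psms <- psms[psms$accepted, , drop = FALSE]
  if ("is_decoy" %in% names(psms))
    psms <- psms[!psms$is_decoy, , drop = FALSE]
  tp <- lapply(events$peptides, function(pp) {
    tt <- sort(unique(psms$tissue[psms$peptide %in% pp]))
    if (length(tt) == 0L)
      stop("event with zero accepted supporting PSMs")
    tt
  })
  events$tissues_present <- tp
  events$tissue_specific <- lengths(tp) == 1L
  events
}
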