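#' Run the full proteogenomic event-calling pipeline
#'
#' Executes the stages end to end: six-frame database construction,
#' class-specific target-decoy FDR filtering, known/orphan partitioning,
#' genomic anchoring of orphans (contiguous, then spliced), event
#' classification (novel genes, revisions, AS junctions, SAAVs), tissue
#' tagging, delta-mass modification annotation, and — when intensity
#' matrices are supplied — differential expression with transcript
#' correlation for every tissue pair. A run manifest records the
#' before/after counts of every filtering stage.
#'
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param annotation a [gene_annotation()] or GFF3 path.
#' @param known_proteome named character vector / `AAStringSet` / FASTA
#'   path.
#' @param psms PSM data.frame (see [simulate_psms()] for the dialect).
#' @param config a [pipeline_config()].
#' @param transcripts optional transcript FASTA / named vector for the
#'   three-frame database.
#' @param transcript_evidence optional nucleotide variant evidence for SAAV
#'   codon selection (see [call_saavs()]).
#' @param protein_matrix,transcript_matrix,sample_groups optional intensity
#'   matrices and per-column tissue labels for the expression stage.
#' @param output_dir optional directory; when given, stage outputs are
#'   written (events GFF3, junction BED12, SAAV TSV, GSSP BED12, filtered
#'   PSM TSV, manifest JSON).
#' @return a list of class `pg_run`: `fdr`, `gssps`, `junction_gssps`,
#'   `events` (novel + revision + junction calls with tissue flags),
#'   `ambiguous_revisions`, `saavs`, `ptm`, `deps`, `correlations`,
#'   `manifest`.
#' @export
run_pipeline <- function(genome, annotation, known_proteome, psms,
                         config = pipeline_config(), transcripts = NULL,
                         transcript_evidence = NULL, protein_matrix = NULL,
                         transcript_matrix = NULL, sample_groups = NULL,
                         output_dir = NULL) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  genome_seqs <- load_dna(genome)
  orfs <- six_frame_translate(genome_seqs, config$min_orf_len,
                              config$start_codons)
  tx_orfs <- if (!is.null(transcripts))
    three_frame_translate(transcripts, config$min_orf_len,
                          config$start_codons) else NULL
  db <- build_search_db(known_proteome,
                        if (is.null(tx_orfs)) orfs else rbind(orfs, tx_orfs))
  fdr <- class_specific_fdr(psms, config$fdr_threshold)
  acc <- fdr$psms[fdr$psms$accepted & !fdr$psms$is_decoy, , drop = FALSE]
  accepted_peps <- unique(acc$peptide)
  part <- match_known(accepted_peps, known_proteome)
  gssps <- map_to_genome(part$orphan, db)
  unplaced <- gssps$peptide[gssps$n_placements == 0L]
  junction_rows <- lapply(unplaced, function(p)
    find_splice_mapping(p, genome_seqs, max_intron = config$max_intron))
  junction_gssps <- do.call(rbind, junction_rows)
  if (is.null(junction_gssps)) junction_gssps <- empty_junction_result()
  class(junction_gssps) <- c("gssp_mappings", "data.frame")
  spliced_peps <- unique(junction_gssps$peptide)
  saav_input <- setdiff(unplaced, spliced_peps)
  assert_translate_back(gssps, junction_gssps, genome_seqs)
  novel <- call_novel_genes(gssps, annotation, config)
  revisions <- call_revisions(gssps, annotation, config)
  as_events <- call_as_events(junction_gssps, annotation)
  saavs <- call_saavs(saav_input, annotation, genome_seqs, known_proteome,
                      transcript_evidence, config)
  events <- bind_events(list(novel, revisions, as_events))
  if (nrow(events) > 0L) events <- tissue_specificity(events, acc)
  ptm <- if (nrow(acc) > 0L)
    annotate_delta_masses(acc, config = config) else NULL
  deps <- NULL; correlations <- NULL
  if (!is.null(protein_matrix) && !is.null(sample_groups)) {
    pm <- quantifiable_filter(protein_matrix, sample_groups)
    pairs <- utils::combn(unique(sample_groups), 2, simplify = FALSE)
    deps <- do.call(rbind, lapply(pairs, function(cp)
      call_deps(pm, sample_groups, cp, config)))
    if (!is.null(transcript_matrix)) {
      correlations <- do.call(rbind, lapply(pairs, function(cp) {
        dp <- call_deps(pm, sample_groups, cp, config)
        dg <- call_deps(transcript_matrix, sample_groups, cp, config)
        shared <- intersect(dp$feature, dg$feature)
        if (length(shared) < 3L) return(NULL)
        out <- correlate_omics(
          stats::setNames(dp$log2_fc, dp$feature)[shared],
          stats::setNames(dg$log2_fc, dg$feature)[shared],
          stats::setNames(dp$is_dep, dp$feature)[shared],
          stats::setNames(dg$is_dep, dg$feature)[shared])
        out$comparison <- paste(cp, collapse = "_vs_")
        out
      }))
    }
  }
  manifest <- list(
    config = unclass(config),
    counts = list(
      psms_in = nrow(psms),
      psms_accepted = nrow(acc),
      peptides_accepted = length(accepted_peps),
      peptides_known = length(part$known),
      peptides_orphan = length(part$orphan),
      gssp_placements = sum(!is.na(gssps$seqid)),
      gssp_unique = sum(gssps$is_unique, na.rm = TRUE),
      peptides_unplaced = length(unplaced),
      junction_placements = nrow(junction_gssps),
      events = as.list(table(events$kind)),
      saavs = nrow(saavs)))
  run <- structure(list(fdr = fdr, gssps = gssps,
                        junction_gssps = junction_gssps, events = events,
                        ambiguous_revisions = attr(revisions, "ambiguous"),
                        saavs = saavs, ptm = ptm, deps = deps,
                        correlations = correlations, manifest = manifest),
                   class = "pg_run")
  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

# standing invariant: every placement translates back to its peptide
assert_translate_back <- function(gssps, junction_gssps, genome_seqs) {
  both <- rbind(gssps, junction_gssps)
  for (i in seq_len(nrow(both))) {
    if (is.na(both$seqid[i])) next
    aa <- translate_blocks(both$blocks[[i]], genome_seqs[[both$seqid[i]]],
                           both$strand[i])
    if (il_collapse(aa) != il_collapse(both$peptide[i]))
      stop("internal error: placement of ", both$peptide[i],
           " does not translate back")
  }
  invisible(TRUE)
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- run$events
  ge <- ev[ev$kind %in% c("novel_gene", "revision"), , drop = FALSE]
  if (nrow(ge) > 0L) {
    feats <- data.frame(
      seqid = ge$seqid, source = "gssptools",
      type = ifelse(ge$kind == "novel_gene", "gene", "CDS"),
      start = ge$start, end = ge$end, score = ".", strand = ge$strand,
      phase = ".",
      attributes = paste0("ID=", ge$locus_id, ";kind=", ge$kind,
                          ";evidence=GSSP;n_peptides=", ge$n_peptides,
                          ifelse(is.na(ge$overlapped_gene), "",
                                 paste0(";revises=", ge$overlapped_gene))),
      stringsAsFactors = FALSE)
    write_gff3(feats, file.path(dir, "events.gff3"))
  }
  jx <- run$junction_gssps
  if (nrow(jx) > 0L) write_gssp_bed(jx, file.path(dir, "junctions.bed"))
  if (sum(!is.na(run$gssps$seqid)) > 0L)
    write_gssp_bed(run$gssps[!is.na(run$gssps$seqid), , drop = FALSE],
                   file.path(dir, "gssps.bed"))
  write_saav_tsv(run$saavs, file.path(dir, "saavs.tsv"))
  write_psm_table(run$fdr$psms, file.path(dir, "psms_filtered.tsv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write SAAV records as a VCF-like TSV
#'
#' Columns `CHROM`, `POS` (1-based), `REF`, `ALT` (forward-strand bases)
#' followed by the codon- and peptide-level detail columns.
#'
#' @param saavs a `saav_records` data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_saav_tsv <- function(saavs, path) {
  out <- data.frame(CHROM = saavs$seqid, POS = saavs$genomic_position,
                    REF = saavs$genomic_ref, ALT = saavs$genomic_alt,
                    gene_id = saavs$gene_id, protein_pos = saavs$protein_pos,
                    ref_codon = saavs$ref_codon,
                    candidate_alt_codons = saavs$candidate_alt_codons,
                    selected_alt_codon = saavs$selected_alt_codon,
                    ref_aa = saavs$ref_aa, alt_aa = saavs$alt_aa,
                    codon_position = saavs$codon_position,
                    peptide = saavs$peptide, flag = saavs$flag,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score event calls against the synthetic ground truth
#'
#' Per event kind, the fraction of calls matching an injected event
#' (precision) and of injected events recovered (recall). Novel loci match
#' by reciprocal overlap >= `min_reciprocal` on the same sequence and
#' strand; junctions by exact donor/acceptor coordinates; SAAVs by exact
#' genomic position, reference codon and selected alternative codon;
#' revisions by the revised gene identifier. With zero calls of a kind the
#' precision is reported as 1 with a warning.
#'
#' @param events an `event_calls` data.frame (from [run_pipeline()] or the
#'   callers directly).
#' @param saavs a `saav_records` data.frame.
#' @param truth a `synth_truth` (from [generate_genome()]).
#' @param min_reciprocal reciprocal-overlap threshold for novel loci.
#' @return a data.frame: `kind`, `n_truth`, `n_calls`, `n_matched_calls`,
#'   `precision`, `recall`.
#' @export
evaluate_against_truth <- function(events, saavs, truth,
                                   min_reciprocal = 0.9) {
  stopifnot(inherits(truth, "synth_truth"))
  res <- list()
  # novel loci
  calls <- events[events$kind == "novel_gene", , drop = FALSE]
  tr <- truth$novel_loci
  m <- match_loci(calls, tr, min_reciprocal)
  res$novel_gene <- score_kind("novel_gene", nrow(tr), m)
  # junctions
  calls <- events[events$kind == "as_junction", , drop = FALSE]
  tr <- truth$junctions
  ck <- paste(calls$seqid, calls$strand, calls$donor_end,
              calls$acceptor_start)
  tk <- paste(tr$seqid, tr$strand, tr$donor_end, tr$acceptor_start)
  res$as_junction <- score_kind("as_junction", nrow(tr),
                                list(call_hit = ck %in% tk,
                                     truth_hit = tk %in% ck))
  # SAAVs
  sa <- saavs[saavs$flag == "ok", , drop = FALSE]
  tr <- truth$saav_sites
  ck <- paste(sa$seqid, sa$genomic_position, sa$ref_codon,
              sa$selected_alt_codon)
  tk <- paste(tr$seqid, tr$position, tr$ref_codon, tr$alt_codon)
  res$saav <- score_kind("saav", nrow(tr),
                         list(call_hit = ck %in% tk, truth_hit = tk %in% ck))
  # revisions
  calls <- events[events$kind == "revision", , drop = FALSE]
  tr <- truth$revisions
  res$revision <- score_kind("revision", nrow(tr),
                             list(call_hit = calls$overlapped_gene %in%
                                    tr$gene_id,
                                  truth_hit = tr$gene_id %in%
                                    calls$overlapped_gene))
  rbind_rows(res)
}

match_loci <- function(calls, tr, min_reciprocal) {
  call_hit <- rep(FALSE, nrow(calls))
  truth_hit <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(tr))) {
      if (calls$seqid[i] != tr$seqid[j] ||
          calls$strand[i] != tr$strand[j]) next
      ov <- min(calls$end[i], tr$end[j]) - max(calls$start[i], tr$start[j]) +
        1L
      if (ov <= 0L) next
      wc <- calls$end[i] - calls$start[i] + 1L
      wt <- tr$end[j] - tr$start[j] + 1L
      if (ov / wc >= min_reciprocal && ov / wt >= min_reciprocal) {
        call_hit[i] <- TRUE; truth_hit[j] <- TRUE
      }
    }
  }
  list(call_hit = call_hit, truth_hit = truth_hit)
}

score_kind <- function(kind, n_truth, m) {
  n_calls <- length(m$call_hit)
  if (n_calls == 0L && n_truth > 0L)
    warning("no ", kind, " calls; precision reported as 1")
  precision <- if (n_calls == 0L) 1 else mean(m$call_hit)
  recall <- if (n_truth == 0L) 1 else mean(m$truth_hit)
  data.frame(kind = kind, n_truth = n_truth, n_calls = n_calls,
             n_matched_calls = sum(m$call_hit), precision = precision,
             recall = recall, stringsAsFactors = FALSE)
}
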