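#' Call single amino acid variants from unplaced orphan peptides
#'
#' An orphan peptide that cannot be placed on the genome exactly may carry a
#' single amino acid variant: it matches an annotated protein up to a small
#' number of substitutions. For each orphan of at least `saav_min_len`
#' residues, the annotated proteome is scanned (I/L-equivalent) for the
#' best-matching window with 1 to `saav_max_variants` mismatches. Each
#' mismatch is traced back through the gene model to its reference codon in
#' the genome, and every codon that encodes the observed residue and is
#' reachable by a single base change (the candidate alternative codons) is
#' enumerated. When nucleotide evidence (e.g. RNA-seq variant calls) covers
#' the site, the supported codon is selected and the substitution reported
#' as (reference base, alternative base, codon position); without evidence
#' the full candidate set is reported and no codon is guessed.
#'
#' A mismatch not explainable by any single-base codon change is flagged
#' `"multi_nucleotide"` and excluded from the default report, as are
#' peptides whose best placement is ambiguous.
#'
#' @param orphans character vector of orphan peptides with no exact genomic
#'   placement (contiguous or spliced).
#' @param ann a [gene_annotation()]; protein identifiers in
#'   `known_proteome` must match its `gene_id`s for codon lookup.
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param known_proteome named character vector / `AAStringSet` / FASTA
#'   path of annotated proteins.
#' @param transcript_evidence optional data.frame of nucleotide variant
#'   evidence with columns `seqid`, `pos` (1-based forward-axis), `alt`
#'   (forward-strand base).
#' @param config a [pipeline_config()].
#' @param include_flagged also return records flagged `multi_nucleotide` /
#'   `ambiguous_placement` / `no_gene_model` (default `FALSE`).
#' @return a data.frame of class `saav_records`, one row per explained
#'   mismatch: `peptide`, `gene_id`, `protein_pos`, `seqid`,
#'   `genomic_position`, `ref_codon`, `candidate_alt_codons`
#'   (comma-separated), `selected_alt_codon`, `ref_aa`, `alt_aa`,
#'   `ref_base`, `alt_base`, `codon_position` (all three codon-strand;
#'   `NA` when no codon is selected), `genomic_ref`, `genomic_alt`
#'   (forward-strand bases), `n_variants` (mismatches in the peptide),
#'   `flag`.
#' @export
call_saavs <- function(orphans, ann, genome, known_proteome,
                       transcript_evidence = NULL,
                       config = pipeline_config(),
                       include_flagged = FALSE) {
  prot <- load_proteome(known_proteome)
  seqs <- load_dna(genome)
  orphans <- unique(orphans)
  orphans <- orphans[nchar(orphans) >= config$saav_min_len]
  prot_il <- strsplit(il_collapse(prot), "")
  hay <- paste(il_collapse(prot), collapse = "*")
  rows <- list()
  for (pep in orphans) {
    if (grepl(il_collapse(pep), hay, fixed = TRUE)) next  # exact known match
    hits <- best_mismatch_placements(pep, prot_il, config$saav_max_variants)
    if (is.null(hits)) next
    if (nrow(hits) > 1L) {
      rows[[length(rows) + 1L]] <- saav_stub(pep, flag = "ambiguous_placement",
                                             n_variants = hits$nmis[1])
      next
    }
    gid <- hits$protein[1]; off <- hits$offset[1]
    pchars <- strsplit(prot[[gid]], "")[[1]]
    pep_chars <- strsplit(pep, "")[[1]]
    mis <- which(il_collapse(pep_chars) !=
                   il_collapse(pchars[off:(off + nchar(pep) - 1L)]))
    for (j in mis) {
      res_pos <- off + j - 1L
      obs_aa <- pep_chars[j]
      rec <- try(infer_saav_codon(ann, seqs, gid, res_pos, obs_aa,
                                  transcript_evidence), silent = TRUE)
      if (inherits(rec, "try-error")) {
        rows[[length(rows) + 1L]] <- saav_stub(pep, gid, res_pos,
                                               flag = "no_gene_model",
                                               n_variants = hits$nmis[1])
        next
      }
      rec$peptide <- pep
      rec$n_variants <- hits$nmis[1]
      rows[[length(rows) + 1L]] <- rec
    }
  }
  df <- rbind_rows(rows)
  if (is.null(df)) df <- saav_stub(character(0))
  if (!include_flagged) df <- df[df$flag == "ok", , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("saav_records", "data.frame")
  df
}

saav_stub <- function(peptide, gene_id = NA_character_,
                      protein_pos = NA_integer_, flag = "ok",
                      n_variants = NA_integer_) {
  n <- length(peptide)
  data.frame(peptide = peptide, gene_id = rep(gene_id, n),
             protein_pos = rep(protein_pos, n),
             seqid = rep(NA_character_, n),
             genomic_position = rep(NA_integer_, n),
             ref_codon = rep(NA_character_, n),
             candidate_alt_codons = rep(NA_character_, n),
             selected_alt_codon = rep(NA_character_, n),
             ref_aa = rep(NA_character_, n), alt_aa = rep(NA_character_, n),
             ref_base = rep(NA_character_, n),
             alt_base = rep(NA_character_, n),
             codon_position = rep(NA_integer_, n),
             genomic_ref = rep(NA_character_, n),
             genomic_alt = rep(NA_character_, n),
             n_variants = rep(n_variants, n), flag = rep(flag, n),
             stringsAsFactors = FALSE)
}

# all placements of `pep` within the proteome at the minimal mismatch count
# in 1..max_mis; NULL when none
best_mismatch_placements <- function(pep, prot_il_chars, max_mis) {
  q <- strsplit(il_collapse(pep), "")[[1]]
  Lq <- length(q)
  best <- max_mis + 1L
  found <- list()
  for (gid in names(prot_il_chars)) {
    p <- prot_il_chars[[gid]]
    np <- length(p)
    if (np < Lq) next
    for (s in seq_len(np - Lq + 1L)) {
      nm <- sum(q != p[s:(s + Lq - 1L)])
      if (nm >= 1L && nm <= max_mis && nm <= best) {
        if (nm < best) { found <- list(); best <- nm }
        found[[length(found) + 1L]] <- data.frame(
          protein = gid, offset = s, nmis = nm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(found) == 0L) return(NULL)
  do.call(rbind, found)
}

# codon back-inference for one mismatch
infer_saav_codon <- function(ann, seqs, gene_id, res_pos, obs_aa,
                             evidence) {
  cc <- codon_genomic_coords(ann, gene_id, res_pos)
  bases <- vapply(cc$positions, function(p)
    substr(seqs[[cc$seqid]], p, p), character(1))
  if (cc$strand == "-") bases <- unname(comp_base(bases))
  ref_codon <- paste0(bases, collapse = "")
  ref_aa <- codon_to_aa(ref_codon)
  cand <- codons_for_aa(obs_aa)
  cand <- cand[vapply(cand, function(cd)
    sum(strsplit(cd, "")[[1]] != bases) == 1L, logical(1))]
  if (length(cand) == 0L)
    return(saav_fill(gene_id, res_pos, cc, ref_codon, ref_aa, obs_aa,
                     character(0), flag = "multi_nucleotide"))
  sel <- NA_character_
  if (!is.null(evidence) && nrow(evidence) > 0L) {
    for (cd in cand) {
      jd <- which(strsplit(cd, "")[[1]] != bases)
      gpos <- cc$positions[jd]
      galt <- substr(cd, jd, jd)
      if (cc$strand == "-") galt <- unname(comp_base(galt))
      hit <- evidence$seqid == cc$seqid & evidence$pos == gpos &
        evidence$alt == galt
      if (any(hit)) { sel <- cd; break }
    }
  }
  saav_fill(gene_id, res_pos, cc, ref_codon, ref_aa, obs_aa, cand, sel)
}

saav_fill <- function(gene_id, res_pos, cc, ref_codon, ref_aa, obs_aa,
                      cand, sel = NA_character_, flag = "ok") {
  rb <- ab <- gref <- galt <- NA_character_
  cp <- gpos <- NA_integer_
  pick <- if (!is.na(sel)) sel else if (length(cand) == 1L) cand else NA
  if (!is.na(pick)) {
    jd <- which(strsplit(pick, "")[[1]] != strsplit(ref_codon, "")[[1]])
    cp <- jd
    rb <- substr(ref_codon, jd, jd)
    ab <- substr(pick, jd, jd)
    gpos <- cc$positions[jd]
    gref <- if (cc$strand == "-") unname(comp_base(rb)) else rb
    galt <- if (cc$strand == "-") unname(comp_base(ab)) else ab
  } else if (length(cand) > 1L) {
    # report the genomic position only when all candidates agree on it
    jds <- vapply(cand, function(cd)
      which(strsplit(cd, "")[[1]] != strsplit(ref_codon, "")[[1]]),
      integer(1))
    if (length(unique(jds)) == 1L) gpos <- cc$positions[jds[1]]
  }
  data.frame(peptide = NA_character_, gene_id = gene_id,
             protein_pos = res_pos, seqid = cc$seqid,
             genomic_position = gpos, ref_codon = ref_codon,
             candidate_alt_codons = if (length(cand)) paste(sort(cand),
               collapse = ",") else NA_character_,
             selected_alt_codon = sel, ref_aa = ref_aa, alt_aa = obs_aa,
             ref_base = rb, alt_base = ab, codon_position = cp,
             genomic_ref = gref, genomic_alt = galt,
             n_variants = NA_integer_, flag = flag,
             stringsAsFactors = FALSE)
}

#' Enumerate alternative codons for an observed residue
#'
#' The codon back-inference primitive in isolation: given a reference codon
#' and an observed amino acid, returns every codon encoding the observed
#' residue that differs from the reference at exactly one base, optionally
#' selecting the one supported by nucleotide evidence at a codon position.
#'
#' @param ref_codon reference codon (coding strand).
#' @param obs_aa observed amino acid (one letter).
#' @param evidence_base optional list `list(position = 1:3 codon position,
#'   base = coding-strand base)` of nucleotide evidence.
#' @return a list: `candidates` (sorted codon vector), `selected` (codon or
#'   `NA`), `substitution` (`ref_base`, `alt_base`, `codon_position`, or
#'   `NULL` when unselected).
#' @export
saav_candidate_codons <- function(ref_codon, obs_aa, evidence_base = NULL) {
  rb <- strsplit(ref_codon, "")[[1]]
  cand <- codons_for_aa(obs_aa)
  cand <- sort(cand[vapply(cand, function(cd)
    sum(strsplit(cd, "")[[1]] != rb) == 1L, logical(1))])
  sel <- NA_character_; subst <- NULL
  if (!is.null(evidence_base)) {
    for (cd in cand) {
      jd <- which(strsplit(cd, "")[[1]] != rb)
      if (jd == evidence_base$position &&
          substr(cd, jd, jd) == evidence_base$base) {
        sel <- cd
        subst <- list(ref_base = rb[jd], alt_base = substr(cd, jd, jd),
                      codon_position = jd)
        break
      }
    }
  }
  list(candidates = cand, selected = sel, substitution = subst)
}
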