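#' Simulate target/decoy PSM tables from a labelled peptide set
#'
#' Emits one target PSM per input row and one reversed-sequence decoy PSM
#' per target. Correct target PSMs draw scores from
#' `N(score_correct_mean, score_sd)`; incorrect targets and all decoys draw
#' from `N(score_incorrect_mean, score_sd)` — the two-Gaussian score model
#' that target-decoy filtering assumes (decoy scores i.i.d. with incorrect
#' targets). When the input carries no `correct` column, flags are drawn
#' Bernoulli(`1 - frac_incorrect_psm`). Precursor mass deltas are near zero
#' for unmodified PSMs; a `frac_modified` fraction receives a shift drawn
#' from the default modification table.
#'
#' @param peptide_table data.frame with columns `peptide`, `class`,
#'   `tissue` and optionally `correct` (logical).
#' @param config a [synth_config()] (score model, `frac_incorrect_psm`).
#' @param frac_modified fraction of target PSMs given a real modification
#'   mass shift.
#' @param delta_sd measurement noise on the precursor delta mass (Da).
#' @return a PSM data.frame: `peptide`, `score`, `is_decoy`, `class`,
#'   `tissue`, `precursor_delta_mass`, `truth_correct`.
#' @export
simulate_psms <- function(peptide_table, config = synth_config(),
                          frac_modified = 0.1, delta_sd = 0.002) {
  if (nrow(peptide_table) == 0L) {
    warning("empty peptide set; returning an empty PSM table")
    return(empty_psm_table())
  }
  stopifnot(all(c("peptide", "class", "tissue") %in% names(peptide_table)))
  n <- nrow(peptide_table)
  correct <- if ("correct" %in% names(peptide_table))
    peptide_table$correct else
    stats::runif(n) >= config$frac_incorrect_psm
  score <- ifelse(correct,
                  stats::rnorm(n, config$score_correct_mean, config$score_sd),
                  stats::rnorm(n, config$score_incorrect_mean,
                               config$score_sd))
  modtab <- default_modification_table()
  modded <- stats::runif(n) < frac_modified
  delta <- stats::rnorm(n, 0, delta_sd) +
    ifelse(modded, sample(modtab$delta, n, replace = TRUE), 0)
  targets <- data.frame(peptide = peptide_table$peptide, score = score,
                        is_decoy = FALSE, class = peptide_table$class,
                        tissue = peptide_table$tissue,
                        precursor_delta_mass = delta,
                        truth_correct = correct, stringsAsFactors = FALSE)
  decoys <- data.frame(peptide = reverse_string(peptide_table$peptide),
                       score = stats::rnorm(n, config$score_incorrect_mean,
                                            config$score_sd),
                       is_decoy = TRUE, class = peptide_table$class,
                       tissue = peptide_table$tissue,
                       precursor_delta_mass = stats::rnorm(n, 0, delta_sd),
                       truth_correct = FALSE, stringsAsFactors = FALSE)
  rbind(targets, decoys)
}

empty_psm_table <- function() {
  data.frame(peptide = character(), score = numeric(), is_decoy = logical(),
             class = character(), tissue = character(),
             precursor_delta_mass = numeric(), truth_correct = logical(),
             stringsAsFactors = FALSE)
}

# random tryptic-like peptides disjoint from every real peptide; stand in
# for the sequences that wrong spectrum matches point at
make_noise_peptides <- function(n, avoid_il) {
  hay <- paste(avoid_il, collapse = "*")
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 50L * n + 100L) {
    guard <- guard + 1L
    len <- 8L + sample.int(7L, 1L)
    p <- paste0(c(sample(SAFE_AA, len - 1L, replace = TRUE),
                  sample(c("K", "R"), 1L)), collapse = "")
    if (!grepl(il_collapse(p), hay, fixed = TRUE)) out <- c(out, p)
  }
  out
}

#' Generate a complete synthetic dataset: genome, truth, PSMs, matrices
#'
#' Composes [generate_genome()], in-silico digestion and [simulate_psms()]
#' into the full evaluation bundle. One target PSM is emitted per
#' (peptide, assigned tissue, biological replicate) triple, so a peptide is
#' usually observed several times; with probability `frac_incorrect_psm` a
#' target PSM is an incorrect identification and its observed sequence is
#' replaced by a random peptide matching nothing in the dataset. Protein
#' and transcript intensity matrices (three replicates per tissue,
#' log-normal with shared tissue effects so the two omics layers correlate)
#' are included for the differential-expression module.
#'
#' @param config a [synth_config()].
#' @return the [generate_genome()] bundle extended with `psms`,
#'   `protein_matrix`, `transcript_matrix`, `sample_groups`.
#' @export
simulate_dataset <- function(config = synth_config()) {
  bundle <- generate_genome(config)
  with_seed(config$seed + 1000L, {
    cat_df <- bundle$peptide_catalog
    reps <- max(1L, config$n_replicates)
    rows <- list()
    for (i in seq_len(nrow(cat_df))) {
      tis <- strsplit(cat_df$tissues[i], ",", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = cat_df$peptide[i], class = cat_df$class[i],
        event_id = cat_df$event_id[i], tissue = rep(tis, each = reps),
        stringsAsFactors = FALSE)
    }
    tab <- rbind_rows(rows)
    if (is.null(tab))
      tab <- data.frame(peptide = character(), class = character(),
                        event_id = character(), tissue = character(),
                        stringsAsFactors = FALSE)
    tab$correct <- TRUE
    if (config$frac_incorrect_psm > 0 && nrow(tab) > 0L) {
      bad <- which(stats::runif(nrow(tab)) < config$frac_incorrect_psm)
      if (length(bad) > 0L) {
        avoid <- il_collapse(c(bundle$known_proteome, bundle$novel_proteins,
                               tab$peptide))
        noise <- make_noise_peptides(length(bad), avoid)
        bad <- bad[seq_along(noise)]
        tab$peptide[bad] <- noise
        tab$correct[bad] <- FALSE
        tab$class[bad] <- "novel"   # noise matches no known protein
        tab$event_id[bad] <- NA_character_
      }
    }
    psms <- simulate_psms(tab, config)
    mats <- simulate_intensity_matrices(bundle, config)
    bundle$psms <- psms
    bundle$protein_matrix <- mats$protein
    bundle$transcript_matrix <- mats$transcript
    bundle$sample_groups <- mats$groups
  })
  bundle
}

# log-normal intensities, 3 replicates per tissue; ~10% of proteins get a
# 4-fold shift in one tissue, mirrored (attenuated) in the transcript layer
simulate_intensity_matrices <- function(bundle, config) {
  feats <- names(bundle$known_proteome)
  tissues <- config$tissues
  reps <- 3L
  samples <- paste(rep(tissues, each = reps), rep(seq_len(reps),
                                                  length(tissues)),
                   sep = "_")
  groups <- rep(tissues, each = reps)
  nf <- length(feats)
  base <- stats::rnorm(nf, 20, 2)
  eff <- matrix(0, nf, length(tissues), dimnames = list(feats, tissues))
  if (nf > 0L) {
    de <- which(stats::runif(nf) < 0.1)
    for (i in de)
      eff[i, sample.int(length(tissues), 1L)] <- sample(c(-2, 2), 1L)
  }
  make_mat <- function(scale_eff, noise_sd) {
    m <- matrix(NA_real_, nf, length(samples),
                dimnames = list(feats, samples))
    for (j in seq_along(samples)) {
      t_ <- groups[j]
      m[, j] <- 2^(base + scale_eff * eff[, t_] +
                     stats::rnorm(nf, 0, noise_sd))
    }
    miss <- matrix(stats::runif(length(m)) < 0.05, nrow = nf)
    m[miss] <- NA
    m
  }
  list(protein = make_mat(1, 0.3), transcript = make_mat(0.8, 0.3),
       groups = groups)
}

#' Write the synthetic bundle to disk
#'
#' Genome as FASTA, annotation as GFF3 (gene/mRNA/exon/CDS), known proteome
#' as FASTA, ground truth as JSON, PSMs as TSV, transcript evidence as TSV.
#' Identical configurations produce byte-identical files.
#'
#' @param bundle a `synth_bundle`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             annotation = file.path(dir, "annotation.gff3"),
             proteome = file.path(dir, "proteome.fasta"),
             truth = file.path(dir, "truth.json"),
             psms = file.path(dir, "psms.tsv"),
             evidence = file.path(dir, "transcript_evidence.tsv"))
  write_fasta(bundle$genome, paths["genome"])
  write_gff3(gff_features(bundle$annotation_gff), paths["annotation"])
  write_fasta(bundle$known_proteome, paths["proteome"])
  truth <- bundle$truth
  jsonlite::write_json(
    list(novel_loci = truth$novel_loci, saav_sites = truth$saav_sites,
         junctions = truth$junctions, revisions = truth$revisions,
         tissue_assignment = truth$tissue_assignment),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$psms)) write_psm_table(bundle$psms, paths["psms"])
  utils::write.table(bundle$transcript_evidence, paths["evidence"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

gff_features <- function(ann_df) {
  if (is.null(ann_df) || nrow(ann_df) == 0L)
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      phase = character(), attributes = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(ann_df)), function(i) {
    r <- ann_df[i, ]
    tid <- paste0(r$gene_id, ".t1")
    feat <- function(type, s, e, phase, attrs)
      data.frame(seqid = r$seqid, source = "gssptools", type = type,
                 start = s, end = e, score = ".", strand = r$strand,
                 phase = phase, attributes = attrs, stringsAsFactors = FALSE)
    rbind(
      feat("gene", r$gene_start, r$gene_end, ".",
           paste0("ID=", r$gene_id)),
      feat("mRNA", r$gene_start, r$gene_end, ".",
           paste0("ID=", tid, ";Parent=", r$gene_id)),
      feat("exon", r$ex1_start, r$ex1_end, ".",
           paste0("ID=", tid, ".e1;Parent=", tid)),
      feat("exon", r$ex2_start, r$ex2_end, ".",
           paste0("ID=", tid, ".e2;Parent=", tid)),
      feat("CDS", r$ex1_start, r$ex1_end, "0",
           paste0("ID=", tid, ".c1;Parent=", tid)),
      feat("CDS", r$ex2_start, r$ex2_end, "0",
           paste0("ID=", tid, ".c2;Parent=", tid)))
  })
  rbind_rows(rows)
}

#' Read / write the PSM TSV dialect
#'
#' Tab-separated with a header; columns `peptide`, `score`, `is_decoy`,
#' `class`, `tissue`, `precursor_delta_mass` plus any extras (`q_value`,
#' `accepted`, `truth_correct`) present.
#'
#' @param psms PSM data.frame.
#' @param path file path.
#' @return `read_psm_table()`: the data.frame; `write_psm_table()`: the
#'   path, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
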