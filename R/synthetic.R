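#' Configuration for the synthetic proteogenomic dataset
#'
#' Defines the study conditions the generator emulates: a ~100 kb annotated
#' multi-gene genome with injected proteogenomic events — intergenic novel
#' ORFs, single-nucleotide variants that change codons, unannotated spliced
#' isoforms, gene-model extensions — plus in-silico tryptic peptides and
#' target/decoy PSM score distributions with a controllable fraction of
#' incorrect identifications. The five default tissue labels mirror the
#' floral-organ design (petal, stamen petaloid, stamen, carpel, carpel
#' petaloid).
#'
#' @param genome_length total genome length in bases (>= 10000).
#' @param n_genes annotated two-exon gene models.
#' @param n_novel_orfs intergenic novel ORFs (unannotated, protein-coding).
#' @param n_saavs single amino acid variant sites inside annotated CDS.
#' @param n_as_isoforms unannotated spliced isoforms (novel GT-AG junction
#'   within an annotated exon).
#' @param n_revisions gene models whose real product extends 5' of the
#'   annotation.
#' @param tissues tissue labels.
#' @param frac_incorrect_psm fraction of target PSMs that are incorrect
#'   identifications.
#' @param score_correct_mean,score_incorrect_mean,score_sd Gaussian score
#'   model for correct vs incorrect/decoy PSMs. The default correct mean
#'   sits 5 standard deviations above the decoy mean, emulating the clear
#'   separation of confident high-resolution identifications.
#' @param n_replicates biological replicates per tissue; each peptide
#'   present in a tissue yields one PSM per replicate.
#' @param missed_cleavages_max tryptic missed cleavages for in-silico
#'   digestion.
#' @param seed RNG seed; identical configurations give byte-identical
#'   outputs.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(genome_length = 100000L, n_genes = 50L,
                         n_novel_orfs = 10L, n_saavs = 15L,
                         n_as_isoforms = 8L, n_revisions = 5L,
                         tissues = c("P", "Sp", "St", "C", "Cp"),
                         frac_incorrect_psm = 0,
                         score_correct_mean = 35, score_incorrect_mean = 10,
                         score_sd = 5, n_replicates = 3L,
                         missed_cleavages_max = 2L, seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              n_novel_orfs = as.integer(n_novel_orfs),
              n_saavs = as.integer(n_saavs),
              n_as_isoforms = as.integer(n_as_isoforms),
              n_revisions = as.integer(n_revisions), tissues = tissues,
              frac_incorrect_psm = frac_incorrect_psm,
              score_correct_mean = score_correct_mean,
              score_incorrect_mean = score_incorrect_mean,
              score_sd = score_sd, n_replicates = as.integer(n_replicates),
              missed_cleavages_max = as.integer(missed_cleavages_max),
              seed = as.integer(seed))
  if (cfg$genome_length < 10000L) stop("genome_length must be >= 10000")
  counts <- c("n_genes", "n_novel_orfs", "n_saavs", "n_as_isoforms",
              "n_revisions", "missed_cleavages_max")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (any(vapply(cfg[counts], function(x) x < 0L, logical(1))))
    stop("all counts must be >= 0")
  if (frac_incorrect_psm < 0 || frac_incorrect_psm > 1)
    stop("frac_incorrect_psm must be in [0, 1]")
  if (length(tissues) < 1L) stop("at least one tissue label required")
  structure(cfg, class = "synth_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P
#' ("Trypsin/P off"), and emits every product with 0 to
#' `missed_cleavages_max` missed cleavages whose length lies in
#' `[min_len, max_len]`.
#'
#' @param proteins character vector of amino-acid sequences (20-letter
#'   alphabet).
#' @param missed_cleavages_max maximum missed cleavage sites per peptide.
#' @param min_len,max_len peptide length bounds in residues.
#' @return sorted unique character vector of peptides.
#' @export
digest_proteome <- function(proteins, missed_cleavages_max = 2L,
                            min_len = 7L, max_len = 40L) {
  check_aa_alphabet(proteins)
  out <- unlist(lapply(proteins, function(p)
    digest_one(p, missed_cleavages_max, min_len, max_len)$peptide))
  sort(unique(out))
}

# one protein -> data.frame(peptide, start, end, missed)
digest_one <- function(protein, mc_max, min_len, max_len) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  sites <- which(ch %in% c("K", "R"))
  sites <- sites[sites < n & ch[pmin(sites + 1L, n)] != "P"]
  bounds <- c(0L, sites, n)
  bounds <- unique(bounds)
  rows <- list()
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + mc_max)) {
      s <- bounds[i] + 1L; e <- bounds[j]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substr(protein, s, e), start = s, end = e,
        missed = j - i - 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed = integer(),
                      stringsAsFactors = FALSE))
  rbind_rows(rows)
}

# ---- feature construction -------------------------------------------------

# residues excluded when building designed proteins so that cleavage sites
# sit exactly where placed
SAFE_AA <- setdiff(AA_ALPHABET20, c("K", "R", "P", "M"))

designed_protein <- function(n, kr_at) {
  aa <- sample(SAFE_AA, n, replace = TRUE)
  aa[kr_at] <- sample(c("K", "R"), length(kr_at), replace = TRUE)
  aa[1] <- "M"
  paste0(aa, collapse = "")
}

random_codons <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  vapply(seq_along(aa), function(i) {
    if (i == 1L && aa[i] == "M") return("ATG")
    cand <- codons_for_aa(aa[i])
    cand[sample.int(length(cand), 1L)]
  }, character(1))
}

random_intron <- function(len) {
  stopifnot(len >= 6L)
  paste0("GT", random_dna(len - 4L), "AG")
}

#' Generate a synthetic annotated genome with injected proteogenomic events
#'
#' Builds a genome of non-overlapping two-exon gene models on both strands
#' with at least ~1 kb of intergenic spacer around every feature, and
#' injects the configured events, each recorded in the ground-truth
#' manifest:
#' \itemize{
#'   \item novel ORFs — strictly intergenic coding regions (ATG start, TAA
#'     stop) absent from the annotation, each guaranteed to yield at least
#'     two distinct fully-tryptic peptides of >= 7 residues unique to the
#'     locus (regenerated otherwise);
#'   \item SAAV sites — a single-base, non-synonymous codon change inside an
#'     annotated CDS; the genome keeps the reference base and the variant
#'     peptide appears only in the PSM data, as it would in a real search;
#'   \item AS isoforms — an in-frame segment of an annotated exon, beginning
#'     `GT` and ending `AG`, spliced out by an unannotated isoform so that
#'     junction-spanning tryptic peptides exist;
#'   \item revisions — genes whose product extends in-frame 5' of the
#'     annotated start, yielding orphan peptides that straddle the annotated
#'     gene boundary.
#' }
#' Every event is assigned a random non-empty tissue subset; annotated genes
#' are present in all tissues.
#'
#' @param config a [synth_config()].
#' @return a list of class `synth_bundle` with elements `genome` (named
#'   character), `annotation` ([gene_annotation()]), `annotation_gff`
#'   (feature data.frame for [write_gff3()]), `known_proteome`,
#'   `novel_proteins`, `truth` (class `synth_truth`), `peptide_catalog`
#'   (peptide / class / event_id / tissues used to simulate PSMs),
#'   `transcript_evidence`, and `config`.
#' @export
generate_genome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, build_bundle(config))
}

build_bundle <- function(config) {
  n_special <- config$n_saavs + config$n_as_isoforms + config$n_revisions
  if (config$n_genes < n_special)
    stop("capacity error: n_genes = ", config$n_genes,
         " is the limiting count; need at least ", n_special,
         " genes to host n_saavs + n_as_isoforms + n_revisions events")
  roles <- c(rep("saav", config$n_saavs), rep("as", config$n_as_isoforms),
             rep("revision", config$n_revisions),
             rep("plain", config$n_genes - n_special))
  feats <- list()
  for (i in seq_len(config$n_genes))
    feats[[length(feats) + 1L]] <- c(type = "gene", role = roles[i])
  for (i in seq_len(config$n_novel_orfs))
    feats[[length(feats) + 1L]] <- c(type = "orf", role = "novel")
  if (length(feats) > 1L) feats <- feats[sample.int(length(feats))]

  gene_i <- 0L; orf_i <- 0L; saav_i <- 0L; as_i <- 0L; rev_i <- 0L
  cursor <- 0L          # bases emitted so far
  pieces <- character(0)
  ann_rows <- list()    # per-feature annotation data.frames
  proteome <- character(0)
  novel_proteins <- character(0)
  truth_novel <- list(); truth_saav <- list(); truth_junc <- list()
  truth_rev <- list(); tissue_assign <- list()
  catalog <- list()     # peptide catalogue rows
  evidence <- list()
  all_proteins_il <- character(0)  # running uniqueness check set

  rand_tissues <- function() {
    k <- sample.int(length(config$tissues), 1L)
    sort(sample(config$tissues, k))
  }
  add_catalog <- function(peptides, class, event_id, tissues) {
    if (length(peptides) == 0L) return()
    catalog[[length(catalog) + 1L]] <<- data.frame(
      peptide = peptides, class = class, event_id = event_id,
      tissues = paste(tissues, collapse = ","), stringsAsFactors = FALSE)
  }

  for (f in feats) {
    spacer <- 1050L + sample.int(200L, 1L)
    pieces <- c(pieces, random_dna(spacer))
    cursor <- cursor + spacer
    strand <- sample(c("+", "-"), 1L)
    if (f[["type"]] == "orf") {
      orf_i <- orf_i + 1L
      id <- sprintf("novel_%02d", orf_i)
      orf <- make_novel_orf(all_proteins_il)
      all_proteins_il <- c(all_proteins_il, il_collapse(orf$protein))
      novel_proteins[id] <- orf$protein
      len <- nchar(orf$seq)
      gstart <- cursor + 1L
      pieces <- c(pieces,
                  if (strand == "+") orf$seq else revcomp(orf$seq))
      cursor <- cursor + len
      # truth interval: coding residues only (stop codon excluded)
      cod <- loc2gen(1L, 3L * nchar(orf$protein), gstart, len, strand)
      tis <- rand_tissues()
      truth_novel[[id]] <- data.frame(event_id = id, seqid = "chr1",
                                      strand = strand, start = cod[1],
                                      end = cod[2], stringsAsFactors = FALSE)
      tissue_assign[[id]] <- tis
      add_catalog(orf$peptides, "novel", id, tis)
    } else {
      gene_i <- gene_i + 1L
      gid <- sprintf("gene_%02d", gene_i)
      role <- f[["role"]]
      g <- switch(role,
                  plain = make_plain_gene(all_proteins_il),
                  saav = make_saav_gene(all_proteins_il),
                  as = make_as_gene(all_proteins_il),
                  revision = make_revision_gene(all_proteins_il))
      all_proteins_il <- c(all_proteins_il, il_collapse(g$protein))
      proteome[gid] <- g$protein
      len <- nchar(g$seq)
      gstart <- cursor + 1L
      pieces <- c(pieces, if (strand == "+") g$seq else revcomp(g$seq))
      cursor <- cursor + len
      l2g <- function(l1, l2) loc2gen(l1, l2, gstart, len, strand)
      gene_span <- l2g(g$gene_local[1], g$gene_local[2])
      ex1 <- l2g(g$exon1_local[1], g$exon1_local[2])
      ex2 <- l2g(g$exon2_local[1], g$exon2_local[2])
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = gid, seqid = "chr1", strand = strand,
        gene_start = gene_span[1], gene_end = gene_span[2],
        ex1_start = ex1[1], ex1_end = ex1[2],
        ex2_start = ex2[1], ex2_end = ex2[2], stringsAsFactors = FALSE)
      add_catalog(digest_proteome(g$protein, config$missed_cleavages_max),
                  "known", gid, config$tissues)
      if (role == "saav") {
        saav_i <- saav_i + 1L
        sid <- sprintf("saav_%02d", saav_i)
        ln <- g$saav_local_nt
        if (strand == "+") {
          gpos <- gstart + ln - 1L
          gref <- g$saav_ref_base; galt <- g$saav_alt_base
        } else {
          gpos <- gstart + len - ln
          gref <- unname(comp_base(g$saav_ref_base))
          galt <- unname(comp_base(g$saav_alt_base))
        }
        tis <- rand_tissues()
        truth_saav[[sid]] <- data.frame(
          event_id = sid, gene_id = gid, seqid = "chr1", position = gpos,
          ref_base = gref, alt_base = galt, ref_codon = g$saav_ref_codon,
          alt_codon = g$saav_alt_codon, ref_aa = g$saav_ref_aa,
          alt_aa = g$saav_alt_aa, stringsAsFactors = FALSE)
        tissue_assign[[sid]] <- tis
        evidence[[length(evidence) + 1L]] <- data.frame(
          seqid = "chr1", pos = gpos, ref = gref, alt = galt,
          stringsAsFactors = FALSE)
        add_catalog(g$variant_peptide, "novel", sid, tis)
      } else if (role == "as") {
        as_i <- as_i + 1L
        jid <- sprintf("as_%02d", as_i)
        skip <- l2g(g$skip_local[1], g$skip_local[2])
        tis <- rand_tissues()
        truth_junc[[jid]] <- data.frame(
          event_id = jid, gene_id = gid, seqid = "chr1", strand = strand,
          donor_end = skip[1] - 1L, acceptor_start = skip[2] + 1L,
          stringsAsFactors = FALSE)
        tissue_assign[[jid]] <- tis
        add_catalog(g$junction_peptides, "novel", jid, tis)
      } else if (role == "revision") {
        rev_i <- rev_i + 1L
        rid <- sprintf("rev_%02d", rev_i)
        ext <- l2g(g$ext_local[1], g$ext_local[2])
        tis <- rand_tissues()
        truth_rev[[rid]] <- data.frame(
          event_id = rid, gene_id = gid, seqid = "chr1",
          ext_start = ext[1], ext_end = ext[2], stringsAsFactors = FALSE)
        tissue_assign[[rid]] <- tis
        add_catalog(g$orphan_peptides, "novel", rid, tis)
      }
    }
    if (cursor > config$genome_length - 1050L)
      stop("capacity error: genome_length = ", config$genome_length,
           " cannot hold the requested features; the limiting count is ",
           "n_genes + n_novel_orfs = ",
           config$n_genes + config$n_novel_orfs)
  }
  pieces <- c(pieces, random_dna(config$genome_length - cursor))
  genome <- c(chr1 = paste0(pieces, collapse = ""))

  ann_df <- rbind_rows(ann_rows)
  annotation <- annotation_from_features(ann_df)
  truth <- structure(list(
    novel_loci = bind_or_empty(truth_novel, c("event_id", "seqid", "strand",
                                              "start", "end")),
    saav_sites = bind_or_empty(truth_saav, c("event_id", "gene_id", "seqid",
                                             "position", "ref_base",
                                             "alt_base", "ref_codon",
                                             "alt_codon", "ref_aa",
                                             "alt_aa")),
    junctions = bind_or_empty(truth_junc, c("event_id", "gene_id", "seqid",
                                            "strand", "donor_end",
                                            "acceptor_start")),
    revisions = bind_or_empty(truth_rev, c("event_id", "gene_id", "seqid",
                                           "ext_start", "ext_end")),
    tissue_assignment = tissue_assign), class = "synth_truth")
  cat_df <- rbind_rows(catalog)
  if (is.null(cat_df))
    cat_df <- data.frame(peptide = character(), class = character(),
                         event_id = character(), tissues = character(),
                         stringsAsFactors = FALSE)
  # a peptide that is both known and event-derived would be ambiguous
  # evidence; keep the known assignment only (does not occur by design)
  cat_df <- cat_df[!duplicated(cat_df$peptide), , drop = FALSE]
  structure(list(genome = genome, annotation = annotation,
                 annotation_gff = ann_df, known_proteome = proteome,
                 novel_proteins = novel_proteins, truth = truth,
                 peptide_catalog = cat_df,
                 transcript_evidence = bind_or_empty(
                   evidence, c("seqid", "pos", "ref", "alt")),
                 config = config),
            class = "synth_bundle")
}

bind_or_empty <- function(lst, cols) {
  df <- rbind_rows(unname(lst))
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols), stringsAsFactors = FALSE)
  }
  df
}

# local coding-strand interval [l1, l2] of a feature placed at genomic
# start `s` (length `len`) -> forward-axis genomic interval
loc2gen <- function(l1, l2, s, len, strand) {
  if (strand == "+") c(s + l1 - 1L, s + l2 - 1L)
  else c(s + len - l2, s + len - l1)
}

annotation_from_features <- function(ann_df) {
  if (is.null(ann_df) || nrow(ann_df) == 0L)
    return(gene_annotation(NULL, NULL, NULL))
  genes <- data.frame(seqid = ann_df$seqid, start = ann_df$gene_start,
                      end = ann_df$gene_end, strand = ann_df$strand,
                      gene_id = ann_df$gene_id, stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(seqid = ann_df$seqid, start = ann_df$ex1_start,
               end = ann_df$ex1_end, strand = ann_df$strand,
               gene_id = ann_df$gene_id, stringsAsFactors = FALSE),
    data.frame(seqid = ann_df$seqid, start = ann_df$ex2_start,
               end = ann_df$ex2_end, strand = ann_df$strand,
               gene_id = ann_df$gene_id, stringsAsFactors = FALSE))
  gene_annotation(genes, exons, exons)  # exons are fully coding here
}

# ---- per-role gene builders ----------------------------------------------
# each returns local (coding-strand) layout: seq, protein, gene/exon
# intervals, plus role-specific extras. Local coordinates are 1-based on
# the feature's coding strand.

split_gene_layout <- function(codons, c_split, ext_nt = 0L) {
  ilen <- 80L + sample.int(70L, 1L)
  intron <- random_intron(ilen)
  cds <- paste0(codons, collapse = "")
  part1 <- substr(cds, 1L, 3L * c_split)
  part2 <- substr(cds, 3L * c_split + 1L, nchar(cds))
  seq <- paste0(part1, intron, part2)
  list(seq = seq, ilen = ilen,
       exon1_local = c(ext_nt + 1L, ext_nt + 3L * c_split),
       exon2_local = c(ext_nt + 3L * c_split + ilen + 1L,
                       ext_nt + nchar(seq)),
       gene_local = c(ext_nt + 1L, ext_nt + nchar(seq)))
}

make_plain_gene <- function(avoid_il, n = NULL) {
  for (attempt in 1:50) {
    np <- if (is.null(n)) 60L + sample.int(40L, 1L) else n
    kr <- seq(10L, np - 7L, by = 10L)
    protein <- designed_protein(np, kr)
    if (protein_ok(protein, avoid_il)) break
  }
  codons <- c(random_codons(protein), "TAA")
  c_split <- (np %/% 2L)
  lay <- split_gene_layout(codons, c_split)
  c(lay, list(protein = protein))
}

# peptide-level uniqueness: no fully-tryptic peptide (>= 7 aa) of this
# protein may occur in any previously designed protein
protein_ok <- function(protein, avoid_il, min_unique = 1L) {
  peps <- digest_proteome(protein, 0L)
  if (length(peps) < 2L) return(FALSE)
  if (length(avoid_il) == 0L) return(TRUE)
  hay <- paste(avoid_il, collapse = "*")
  hits <- vapply(il_collapse(peps), function(p) grepl(p, hay, fixed = TRUE),
                 logical(1))
  !any(hits)
}

make_novel_orf <- function(avoid_il) {
  for (attempt in 1:50) {
    np <- 80L + 10L * sample.int(4L, 1L)
    kr <- seq(10L, np - 7L, by = 10L)
    protein <- designed_protein(np, kr)
    peps <- digest_proteome(protein, 0L)
    if (length(peps) >= 2L && protein_ok(protein, avoid_il)) {
      cds <- paste0(c(random_codons(protein), "TAA"), collapse = "")
      return(list(seq = cds, protein = protein, peptides = peps))
    }
  }
  stop("could not design a detectable novel ORF")
}

make_saav_gene <- function(avoid_il) {
  for (attempt in 1:100) {
    g <- make_plain_gene(avoid_il)
    codons <- random_codons(g$protein)
    pep_tab <- digest_one(g$protein, 0L, 10L, 40L)
    if (nrow(pep_tab) == 0L) next
    pep_tab <- pep_tab[sample.int(nrow(pep_tab)), , drop = FALSE]
    pick <- find_saav_site(g$protein, codons, pep_tab, avoid_il)
    if (is.null(pick)) next
    c_split <- nchar(g$protein) %/% 2L
    lay <- split_gene_layout(c(codons, "TAA"), c_split)
    ln <- 3L * (pick$residue - 1L) + pick$codon_position
    if (ln > 3L * c_split) ln <- ln + lay$ilen
    return(c(lay, list(protein = g$protein,
                       variant_peptide = pick$variant_peptide,
                       saav_local_nt = ln,
                       saav_ref_base = pick$ref_base,
                       saav_alt_base = pick$alt_base,
                       saav_ref_codon = pick$ref_codon,
                       saav_alt_codon = pick$alt_codon,
                       saav_ref_aa = pick$ref_aa,
                       saav_alt_aa = pick$alt_aa)))
  }
  stop("could not design a SAAV gene")
}

# choose a residue inside a fully-tryptic peptide (>= 10 aa) whose codon
# admits a single-base non-synonymous change to a residue that keeps the
# tryptic boundaries intact; the variant peptide must have a unique best
# placement in the designed proteome
find_saav_site <- function(protein, codons, pep_tab, avoid_il) {
  pch <- strsplit(protein, "")[[1]]
  for (r in seq_len(nrow(pep_tab))) {
    ps <- pep_tab$start[r]; pe <- pep_tab$end[r]
    for (pos in sample((ps + 1L):(pe - 1L))) {
      ref_aa <- pch[pos]
      if (ref_aa %in% c("K", "R", "P", "M")) next
      ref_codon <- codons[pos]
      rb <- strsplit(ref_codon, "")[[1]]
      cands <- list()
      for (j in 1:3) for (b in setdiff(c("A", "C", "G", "T"), rb[j])) {
        alt <- rb; alt[j] <- b
        alt_codon <- paste0(alt, collapse = "")
        alt_aa <- codon_to_aa(alt_codon)
        if (alt_aa == "*" || alt_aa %in% c("K", "R", "P")) next
        if (il_collapse(alt_aa) == il_collapse(ref_aa)) next
        cands[[length(cands) + 1L]] <- list(j = j, b = b,
                                            alt_codon = alt_codon,
                                            alt_aa = alt_aa)
      }
      if (length(cands) == 0L) next
      cand <- cands[[sample.int(length(cands), 1L)]]
      vp <- pch[ps:pe]
      vp[pos - ps + 1L] <- cand$alt_aa
      vp <- paste0(vp, collapse = "")
      hay <- paste(c(avoid_il, il_collapse(protein)), collapse = "*")
      if (grepl(il_collapse(vp), hay, fixed = TRUE)) next
      return(list(residue = pos, codon_position = cand$j,
                  ref_base = rb[cand$j], alt_base = cand$b,
                  ref_codon = ref_codon, alt_codon = cand$alt_codon,
                  ref_aa = ref_aa, alt_aa = cand$alt_aa,
                  variant_peptide = vp))
    }
  }
  NULL
}

make_as_gene <- function(avoid_il) {
  na <- 30L; m <- 10L; nb <- 30L
  for (attempt in 1:50) {
    n <- na + m + nb
    kr <- c(8L, 16L, 24L,                      # within A
            na + m + c(5L, 12L, 20L, 28L))     # within B
    protein <- designed_protein(n, kr)
    pch <- strsplit(protein, "")[[1]]
    pch[na + 1L] <- "V"                        # skip starts GTx
    pch[na + m] <- "E"                         # skip ends GAG -> ...AG
    protein <- paste0(pch, collapse = "")
    if (!protein_ok(protein, avoid_il)) next
    codons <- random_codons(protein)
    codons[na + 1L] <- sample(c("GTA", "GTC", "GTG", "GTT"), 1L)
    codons[na + m] <- "GAG"
    # novel isoform: skip removed, in frame
    iso <- paste0(pch[c(seq_len(na), (na + m + 1L):n)], collapse = "")
    iso_tab <- digest_one(iso, 2L, 7L, 40L)
    span <- iso_tab[iso_tab$start <= na - 3L & iso_tab$end >= na + 4L, ,
                    drop = FALSE]
    if (nrow(span) == 0L) next
    junc_peps <- unique(span$peptide)
    hay <- paste(c(avoid_il, il_collapse(protein)), collapse = "*")
    junc_peps <- junc_peps[!vapply(il_collapse(junc_peps), function(p)
      grepl(p, hay, fixed = TRUE), logical(1))]
    if (length(junc_peps) == 0L) next
    c_split <- na + m + 15L
    lay <- split_gene_layout(c(codons, "TAA"), c_split)
    return(c(lay, list(protein = protein,
                       junction_peptides = junc_peps,
                       skip_local = c(3L * na + 1L, 3L * (na + m)))))
  }
  stop("could not design an AS gene")
}

make_revision_gene <- function(avoid_il) {
  e <- 24L
  for (attempt in 1:50) {
    ext <- designed_protein(e, c(8L, 16L))
    np <- 60L + sample.int(20L, 1L)
    kr <- seq(12L, np - 7L, by = 12L)
    protein <- designed_protein(np, kr)
    full <- paste0(ext, protein, collapse = "")
    if (!protein_ok(protein, avoid_il) || !protein_ok(full, avoid_il)) next
    # orphan peptides: tryptic products of the extended product that
    # overlap the extension (the last one straddles the annotated start)
    tab <- digest_one(full, 2L, 7L, 40L)
    orphan <- unique(tab$peptide[tab$start <= e])
    straddle <- any(tab$start <= e & tab$end > e)
    if (length(orphan) < 2L || !straddle) next
    ext_cds <- paste0(random_codons(ext), collapse = "")
    codons <- c(random_codons(protein), "TAA")
    c_split <- np %/% 2L
    lay <- split_gene_layout(codons, c_split, ext_nt = nchar(ext_cds))
    lay$seq <- paste0(ext_cds, lay$seq)
    return(c(lay, list(protein = protein, orphan_peptides = orphan,
                       ext_local = c(1L, nchar(ext_cds)))))
  }
  stop("could not design a revision gene")
}
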