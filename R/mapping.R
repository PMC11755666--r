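#' Partition identified peptides into known and orphan sets
#'
#' A peptide is "known" when it occurs as a contiguous substring of any
#' protein in the known proteome; everything else is an orphan and becomes a
#' candidate genome search-specific peptide (GSSP). Isoleucine and leucine
#' are treated as equivalent by default (mass-indistinguishable in MS).
#'
#' @param peptides character vector of peptide sequences.
#' @param known_proteome named character vector / `AAStringSet` / FASTA path.
#' @param il_equivalent collapse I and L before matching (default `TRUE`).
#' @return a list with character vectors `known` and `orphan` (original
#'   spellings, input order preserved within each).
#' @export
match_known <- function(peptides, known_proteome, il_equivalent = TRUE) {
  prot <- load_proteome(known_proteome)
  if (length(prot) == 0L) stop("known proteome is empty")
  if (any(!nzchar(peptides))) stop("empty peptide sequence in input")
  hay <- paste(if (il_equivalent) il_collapse(prot) else prot, collapse = "*")
  ndl <- if (il_equivalent) il_collapse(peptides) else peptides
  is_known <- vapply(ndl, function(p) grepl(p, hay, fixed = TRUE), logical(1),
                     USE.NAMES = FALSE)
  list(known = peptides[is_known], orphan = peptides[!is_known])
}

load_proteome <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x))
    return(as_named_seqs(Biostrings::readAAStringSet(x)))
  as_named_seqs(x, "proteome")
}

empty_gssp <- function() {
  data.frame(peptide = character(), seqid = character(), strand = character(),
             frame = integer(), start = integer(), end = integer(),
             spans_junction = logical(), source_orf = character(),
             n_placements = integer(), is_unique = logical(),
             stringsAsFactors = FALSE)
}

finish_gssp <- function(df) {
  if (nrow(df) > 0L) {
    key <- paste(df$peptide, df$seqid, df$strand,
                 vapply(df$blocks, function(b) paste(t(b), collapse = ","),
                        character(1)), sep = "|")
    df <- df[!duplicated(key), , drop = FALSE]
    np <- table(df$peptide)
    df$n_placements <- as.integer(np[df$peptide])
    df$is_unique <- df$n_placements == 1L
    rownames(df) <- NULL
  }
  class(df) <- c("gssp_mappings", "data.frame")
  df
}

#' Anchor orphan peptides to genomic coordinates via ORF entries
#'
#' Finds every genome-derived ORF entry of the search database that contains
#' each orphan peptide (I/L-equivalent by default), converts the protein
#' offset into a genomic interval through the ORF's coordinates, collapses
#' placements with identical coordinates that arise from overlapping ORFs,
#' and flags uniquely placed peptides. Decoy entries and transcript-frame
#' entries (which carry no genomic coordinates) are never used.
#'
#' @param orphans character vector of orphan peptides.
#' @param db a `search_db` from [build_search_db()].
#' @param il_equivalent collapse I/L before matching.
#' @return a data.frame of class `gssp_mappings`, one row per placement:
#'   `peptide`, `seqid`, `strand`, `frame`, `start`, `end`, `blocks`
#'   (list-column of 2-column matrices in coding order), `spans_junction`
#'   (all `FALSE` here), `source_orf`, `n_placements`, `is_unique`.
#'   Peptides with zero placements get one row with `NA` coordinates and
#'   `n_placements = 0` (retained for reporting, never event evidence).
#' @export
map_to_genome <- function(orphans, db, il_equivalent = TRUE) {
  stopifnot(inherits(db, "search_db"))
  tg <- db$targets
  tg <- tg[tg$provenance == "genome6", , drop = FALSE]
  orphans <- unique(orphans)
  rows <- list()
  orf_aa <- if (il_equivalent) il_collapse(tg$aa_seq) else tg$aa_seq
  for (pep in orphans) {
    p <- if (il_equivalent) il_collapse(pep) else pep
    Lp <- nchar(p)
    hit <- grep(p, orf_aa, fixed = TRUE)
    found <- FALSE
    for (h in hit) {
      offs <- gregexpr(p, orf_aa[h], fixed = TRUE)[[1]]
      for (r1 in offs) {
        r2 <- r1 + Lp - 1L
        if (tg$strand[h] == "+") {
          b <- c(tg$start[h] + 3L * (r1 - 1L), tg$start[h] + 3L * r2 - 1L)
        } else {
          b <- c(tg$end[h] - 3L * r2 + 1L, tg$end[h] - 3L * (r1 - 1L))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, seqid = tg$seqid[h], strand = tg$strand[h],
          frame = tg$frame[h], start = b[1], end = b[2],
          spans_junction = FALSE, source_orf = tg$id[h],
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$blocks <- list(matrix(b, ncol = 2,
          dimnames = list(NULL, c("start", "end"))))
        found <- TRUE
      }
    }
    if (!found) {
      unplaced <- data.frame(
        peptide = pep, seqid = NA_character_, strand = NA_character_,
        frame = NA_integer_, start = NA_integer_, end = NA_integer_,
        spans_junction = FALSE, source_orf = NA_character_,
        stringsAsFactors = FALSE)
      unplaced$blocks <- list(matrix(integer(0), ncol = 2,
        dimnames = list(NULL, c("start", "end"))))
      rows[[length(rows) + 1L]] <- unplaced
    }
  }
  df <- rbind_rows(rows)
  if (is.null(df)) { df <- empty_gssp(); df$blocks <- list() }
  placed <- df[!is.na(df$seqid), , drop = FALSE]
  unplaced <- df[is.na(df$seqid), , drop = FALSE]
  placed <- finish_gssp(placed)
  if (nrow(unplaced) > 0L) {
    unplaced$n_placements <- 0L
    unplaced$is_unique <- FALSE
    placed <- rbind(placed, unplaced)
  }
  class(placed) <- c("gssp_mappings", "data.frame")
  rownames(placed) <- NULL
  placed
}

# 3-frame amino-acid translations of one oriented sequence; codons with N
# or stops become "*" / "X" breaks so fixed-string peptide search cannot
# run across them.
frame_aa <- function(oriented) {
  lapply(0:2, function(f) {
    n <- (nchar(oriented) - f) %/% 3L
    if (n < 1L) return("")
    st <- f + 3L * (seq_len(n) - 1L) + 1L
    aa <- codon_to_aa(substring(oriented, st, st + 2L))
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  })
}

#' Search spliced two-block genomic placements for an orphan peptide
#'
#' For peptides with no contiguous genomic placement, searches for a
#' two-block placement across an intron: the peptide is split into a donor
#' part and an acceptor part (a codon may straddle the junction — intron
#' phases 0, 1 and 2 are all considered), each block must be at least
#' `min_block_nt` long, both blocks must lie on the same sequence and
#' strand with `0 < intron length <= max_intron`, the straddling codon must
#' reassemble to the observed residue, and the intron must carry the
#' donor/acceptor dinucleotide motifs (GT...AG by default; add `"GC"` to
#' `donors` for the minor GC-AG class).
#'
#' @param orphan one peptide sequence.
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param max_intron maximum intron length in bases (default 10000).
#' @param donors,acceptors intron-terminal dinucleotide motifs (coding
#'   strand).
#' @param min_block_nt minimum genomic block length in nucleotides
#'   (default 9, i.e. three complete residues per side).
#' @param il_equivalent collapse I/L when matching translated frames.
#' @param check_contiguous verify first that the peptide has no contiguous
#'   six-frame placement and return no candidates if it has one.
#' @return a `gssp_mappings` data.frame of junction candidates
#'   (`spans_junction = TRUE`); zero rows is a valid result.
#' @export
find_splice_mapping <- function(orphan, genome, max_intron = 10000L,
                                donors = "GT", acceptors = "AG",
                                min_block_nt = 9L, il_equivalent = TRUE,
                                check_contiguous = TRUE) {
  seqs <- load_dna(genome)
  stopifnot(length(orphan) == 1L, nchar(orphan) >= 2L)
  pep <- if (il_equivalent) il_collapse(orphan) else orphan
  Lp <- nchar(pep)
  rows <- list()
  for (sid in names(seqs)) {
    fwd <- seqs[[sid]]
    Ltot <- nchar(fwd)
    for (strand in c("+", "-")) {
      S <- if (strand == "+") fwd else revcomp(fwd)
      faa <- frame_aa(S)
      if (il_equivalent) faa <- lapply(faa, il_collapse)
      if (check_contiguous &&
          any(vapply(faa, function(a) grepl(pep, a, fixed = TRUE),
                     logical(1))))
        return(empty_junction_result())
      rows <- c(rows, splice_scan_one(S, faa, pep, sid, strand, Ltot,
                                      max_intron, donors, acceptors,
                                      min_block_nt, il_equivalent, orphan))
    }
  }
  df <- rbind_rows(rows)
  if (is.null(df)) return(empty_junction_result())
  finish_gssp(df)
}

empty_junction_result <- function() {
  df <- empty_gssp()
  df$blocks <- list()
  class(df) <- c("gssp_mappings", "data.frame")
  df
}

# all residue-index occurrences of aa pattern `pat` in each of 3 frames of
# the oriented sequence; returns list of integer vectors per frame
frame_hits <- function(faa, pat) {
  lapply(faa, function(a) {
    if (!nzchar(a) || !nzchar(pat)) return(integer(0))
    m <- gregexpr(pat, a, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  })
}

splice_scan_one <- function(S, faa, pep, sid, strand, Ltot, max_intron,
                            donors, acceptors, min_block_nt, il_equivalent,
                            orphan) {
  Lp <- nchar(pep)
  out <- list()
  if (Lp < 6L) return(out)
  for (k in 3:(Lp - 3L)) {
    for (phase in 0:2) {
      b1_len <- 3L * k + phase
      b2_len <- 3L * Lp - b1_len
      if (b1_len < min_block_nt || b2_len < min_block_nt) next
      p1 <- substr(pep, 1L, k)
      straddle <- if (phase > 0L) substr(pep, k + 1L, k + 1L) else ""
      p2_from <- k + 1L + (phase > 0L)
      p2 <- if (p2_from <= Lp) substr(pep, p2_from, Lp) else ""
      if (phase > 0L && !nzchar(p2)) next
      h1 <- frame_hits(faa, p1)
      h2 <- frame_hits(faa, p2)
      for (f1 in 0:2) {
        for (m1 in h1[[f1 + 1L]]) {
          b1s <- f1 + 3L * (m1 - 1L) + 1L
          b1e <- b1s + b1_len - 1L
          if (b1e + 2L > nchar(S)) next
          if (!substr(S, b1e + 1L, b1e + 2L) %in% donors) next
          for (f2 in 0:2) {
            for (m2 in h2[[f2 + 1L]]) {
              p2s_nt <- f2 + 3L * (m2 - 1L) + 1L
              b2s <- p2s_nt - (if (phase > 0L) 3L - phase else 0L)
              b2e <- b2s + b2_len - 1L
              if (b2s < 1L || b2e > nchar(S)) next
              ilen <- b2s - b1e - 1L
              if (ilen <= 0L || ilen > max_intron) next
              if (!substr(S, b2s - 2L, b2s - 1L) %in% acceptors) next
              if (phase > 0L) {
                cod <- paste0(substr(S, b1e - phase + 1L, b1e),
                              substr(S, b2s, b2s + 2L - phase))
                aa <- codon_to_aa(cod)
                if (is.na(aa) || aa == "*") next
                ok <- if (il_equivalent) il_collapse(aa) == straddle
                      else aa == straddle
                if (!ok) next
              }
              blk <- to_forward_blocks(rbind(c(b1s, b1e), c(b2s, b2e)),
                                       strand, Ltot)
              row <- data.frame(
                peptide = orphan, seqid = sid, strand = strand,
                frame = f1, start = min(blk), end = max(blk),
                spans_junction = TRUE, source_orf = NA_character_,
                stringsAsFactors = FALSE)
              row$blocks <- list(blk)
              out[[length(out) + 1L]] <- row
            }
          }
        }
      }
    }
  }
  out
}

# oriented-coordinate blocks (coding order) -> forward-axis blocks, still in
# coding order (rows), each row start <= end on the forward axis
to_forward_blocks <- function(b, strand, Ltot) {
  if (strand == "-") {
    b <- cbind(Ltot - b[, 2] + 1L, Ltot - b[, 1] + 1L)
  }
  colnames(b) <- c("start", "end")
  b
}

#' Extract and translate the genomic blocks of a placement
#'
#' The translate-back check: splicing the blocks of a placement out of the
#' genome in coding order and translating must reproduce the peptide
#' (modulo I/L). Used as a standing assertion on every placement the
#' pipeline emits.
#'
#' @param blocks a 2-column matrix of forward-axis blocks in coding order.
#' @param seq the genome sequence (character) the blocks refer to.
#' @param strand `"+"` or `"-"`.
#' @return the translated amino-acid sequence.
#' @export
translate_blocks <- function(blocks, seq, strand) {
  pieces <- vapply(seq_len(nrow(blocks)), function(i) {
    s <- substr(seq, blocks[i, 1], blocks[i, 2])
    if (strand == "-") revcomp(s) else s
  }, character(1))
  translate_dna(paste0(pieces, collapse = ""), strip_stop = FALSE)
}

#' Cluster GSSP placements into candidate loci
#'
#' Unique placements on the same sequence and strand whose spans lie within
#' `gap` bases of each other form one candidate locus, the unit on which
#' novel genes and revisions are called.
#'
#' @param gssps a `gssp_mappings` data.frame (placed rows only are used).
#' @param gap maximum gap in bases between placements of one locus
#'   (default 1000).
#' @return the input rows with a `locus_id` column (`NA` for unplaced rows).
#' @export
cluster_gssp_loci <- function(gssps, gap = 1000L) {
  gssps$locus_id <- NA_character_
  ok <- !is.na(gssps$seqid)
  if (!any(ok)) return(gssps)
  gr <- GenomicRanges::GRanges(
    seqnames = gssps$seqid[ok],
    ranges = IRanges::IRanges(gssps$start[ok], gssps$end[ok]),
    strand = gssps$strand[ok])
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L,
                               ignore.strand = FALSE)
  hit <- GenomicRanges::findOverlaps(gr, red, ignore.strand = FALSE)
  li <- integer(length(gr))
  li[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  gssps$locus_id[ok] <- paste0("locus_", li)
  attr(gssps, "loci") <- data.frame(
    locus_id = paste0("locus_", seq_along(red)),
    seqid = as.character(GenomicRanges::seqnames(red)),
    strand = as.character(GenomicRanges::strand(red)),
    start = GenomicRanges::start(red), end = GenomicRanges::end(red),
    stringsAsFactors = FALSE)
  gssps
}

#' Write GSSP placements as BED12
#'
#' One line per placement; spliced placements use blockCount/blockSizes/
#' blockStarts. BED is 0-based half-open; internal coordinates (1-based
#' inclusive) are converted at this boundary.
#'
#' @param gssps a `gssp_mappings` data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gssp_bed <- function(gssps, path) {
  ok <- which(!is.na(gssps$seqid))
  lines <- vapply(ok, function(i) {
    b <- gssps$blocks[[i]]
    b <- b[order(b[, 1]), , drop = FALSE]   # BED blocks in forward order
    chromStart <- min(b[, 1]) - 1L
    chromEnd <- max(b[, 2])
    sizes <- b[, 2] - b[, 1] + 1L
    starts <- b[, 1] - 1L - chromStart
    paste(gssps$seqid[i], chromStart, chromEnd, gssps$peptide[i], 0,
          gssps$strand[i], chromStart, chromEnd, "0,0,0", nrow(b),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
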