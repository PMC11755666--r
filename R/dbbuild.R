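#' Six-frame translation of a genome into an ORF catalogue
#'
#' Translates every sequence in all three frames on both strands, splits each
#' frame at stop codons (and at codons containing `N`, which are
#' untranslatable) into stop-to-stop segments, and emits per segment either
#' the ORF beginning at the first in-frame start codon, or — when the segment
#' contains no start codon — the whole segment as a `"fragment"` entry so
#' that peptides from ORFs with non-canonical starts remain findable.
#' Alternative starts (`GTG`, `TTG`) are translated as initiator methionine,
#' the convention of prokaryote-style ORF callers and the observed start-codon
#' usage of proteogenomically recovered plant genes.
#'
#' Genomic coordinates are 1-based inclusive on the forward strand; the
#' interval includes the trailing stop codon when the segment has one.
#'
#' @param genome named character vector or `DNAStringSet` of genome sequences
#'   (alphabet `A/C/G/T/N`), or the path of a FASTA file.
#' @param min_orf_len minimum ORF length in codons (amino acids); shorter
#'   ORFs and fragments are dropped. Default 20.
#' @param start_codons codon set recognised as translation starts.
#' @return a data.frame of class `orf_set`, one row per ORF, with columns
#'   `orf_id`, `seqid`, `strand`, `frame` (0/1/2 on the coding strand),
#'   `start`, `end` (forward-axis, 1-based inclusive, stop codon included
#'   when present), `aa_seq`, `start_codon` (codon or `"fragment"`),
#'   `has_stop`, `source`.
#' @export
six_frame_translate <- function(genome, min_orf_len = 20L,
                                start_codons = DEFAULT_START_CODONS) {
  seqs <- load_dna(genome)
  stopifnot(min_orf_len >= 1L)
  check_dna_alphabet(seqs)
  out <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    if (nchar(s) == 0L) next
    out[[length(out) + 1L]] <-
      scan_frames(s, sid, "+", min_orf_len, start_codons, "genome6")
    out[[length(out) + 1L]] <-
      scan_frames(revcomp(s), sid, "-", min_orf_len, start_codons, "genome6")
  }
  orfs <- rbind_rows(out)
  if (is.null(orfs)) orfs <- empty_orf_set()
  orfs$orf_id <- format_orf_id(orfs)
  class(orfs) <- c("orf_set", "data.frame")
  orfs
}

#' Three-frame translation of transcript sequences
#'
#' Same segment and start-codon logic as [six_frame_translate()], applied to
#' the three forward frames only (transcripts are already stranded).
#' Coordinates are transcript-local, 1-based inclusive.
#'
#' @inheritParams six_frame_translate
#' @param transcripts named character vector, `DNAStringSet` or FASTA path.
#' @return an `orf_set` data.frame with `source = "transcript3"` and
#'   `strand = "+"` throughout.
#' @export
three_frame_translate <- function(transcripts, min_orf_len = 20L,
                                  start_codons = DEFAULT_START_CODONS) {
  seqs <- load_dna(transcripts)
  stopifnot(min_orf_len >= 1L)
  check_dna_alphabet(seqs)
  out <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    if (nchar(s) == 0L) next
    out[[length(out) + 1L]] <-
      scan_frames(s, sid, "+", min_orf_len, start_codons, "transcript3")
  }
  orfs <- rbind_rows(out)
  if (is.null(orfs)) orfs <- empty_orf_set()
  orfs$orf_id <- format_orf_id(orfs)
  class(orfs) <- c("orf_set", "data.frame")
  orfs
}

load_dna <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x) && !grepl("^[ACGTN]*$", x)) {
    return(as_named_seqs(Biostrings::readDNAStringSet(x)))
  }
  as_named_seqs(x, "genome")
}

empty_orf_set <- function() {
  data.frame(seqid = character(), strand = character(), frame = integer(),
             start = integer(), end = integer(), aa_seq = character(),
             start_codon = character(), has_stop = logical(),
             source = character(), stringsAsFactors = FALSE)
}

# Scan the three frames of one oriented sequence. `oriented` is the coding
# strand 5'->3'; for strand == "-" it is the reverse complement of the
# stored sequence and coordinates are mapped back to the forward axis.
scan_frames <- function(oriented, seqid, strand, min_orf_len, start_codons,
                        source) {
  L <- nchar(oriented)
  rows <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 1L) next
    starts_nt <- f + 3L * (seq_len(n_cod) - 1L) + 1L
    codons <- substring(oriented, starts_nt, starts_nt + 2L)
    aa <- codon_to_aa(codons)
    is_break <- is.na(aa) | aa == "*"
    # segments: maximal runs of non-break codons
    r <- rle(is_break)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    seg_i <- idx_start[!r$values]
    seg_j <- idx_end[!r$values]
    for (k in seq_along(seg_i)) {
      i <- seg_i[k]; j <- seg_j[k]
      stop_after <- j < n_cod && !is.na(aa[j + 1L]) && aa[j + 1L] == "*"
      first_start <- i - 1L + match(TRUE, codons[i:j] %in% start_codons)
      if (!is.na(first_start)) {
        orf_i <- first_start
        aa_seq <- c("M", if (orf_i < j) aa[(orf_i + 1L):j])
        sc <- codons[orf_i]
      } else {
        orf_i <- i
        aa_seq <- aa[i:j]
        sc <- "fragment"
      }
      if (length(aa_seq) < min_orf_len) next
      nt1 <- f + 3L * (orf_i - 1L) + 1L
      nt2 <- f + 3L * j + if (stop_after) 3L else 0L
      if (strand == "+") {
        gstart <- nt1; gend <- nt2
      } else {
        gstart <- L - nt2 + 1L; gend <- L - nt1 + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = seqid, strand = strand, frame = f,
        start = gstart, end = gend,
        aa_seq = paste0(aa_seq, collapse = ""),
        start_codon = sc, has_stop = stop_after, source = source,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_orf_set())
  rbind_rows(rows)
}

#' Format and parse coordinate-bearing ORF identifiers
#'
#' Genome ORFs use `g6|<seqid>|<strand>|<frame>|<start>-<end>|<start_codon>`;
#' transcript ORFs use `t3|<transcript_id>|<frame>|<start>-<end>`.
#' Coordinates are 1-based inclusive. `parse_orf_id()` inverts the format so
#' that placements can be reconstructed from database headers alone.
#'
#' @param orfs an `orf_set` data.frame (or any data.frame with the ORF
#'   columns).
#' @return `format_orf_id()`: a character vector of identifiers;
#'   `parse_orf_id()`: a data.frame with columns `source`, `seqid`, `strand`,
#'   `frame`, `start`, `end`, `start_codon` (`NA` for transcript entries).
#' @export
format_orf_id <- function(orfs) {
  ifelse(orfs$source == "genome6",
         paste("g6", orfs$seqid, orfs$strand, orfs$frame,
               paste0(orfs$start, "-", orfs$end), orfs$start_codon,
               sep = "|"),
         paste("t3", orfs$seqid, orfs$frame,
               paste0(orfs$start, "-", orfs$end), sep = "|"))
}

#' @rdname format_orf_id
#' @param ids character vector of ORF identifiers.
#' @export
parse_orf_id <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  one <- function(p) {
    if (p[[1]] == "g6") {
      rng <- strsplit(p[[5]], "-", fixed = TRUE)[[1]]
      data.frame(source = "genome6", seqid = p[[2]], strand = p[[3]],
                 frame = as.integer(p[[4]]), start = as.integer(rng[1]),
                 end = as.integer(rng[2]), start_codon = p[[6]],
                 stringsAsFactors = FALSE)
    } else if (p[[1]] == "t3") {
      rng <- strsplit(p[[4]], "-", fixed = TRUE)[[1]]
      data.frame(source = "transcript3", seqid = p[[2]], strand = "+",
                 frame = as.integer(p[[3]]), start = as.integer(rng[1]),
                 end = as.integer(rng[2]), start_codon = NA_character_,
                 stringsAsFactors = FALSE)
    } else stop("unrecognised ORF identifier: ", paste(p, collapse = "|"))
  }
  rbind_rows(lapply(parts, one))
}

#' Build a concatenated target-decoy search database
#'
#' Combines the known proteome with translated ORF entries, collapses ORFs
#' that are identical in both amino-acid sequence and coordinates (they arise
#' when overlapping frames emit the same product), and generates one reversed
#' decoy per target with the `rev_` identifier prefix.
#'
#' @param known named character vector / `AAStringSet` / FASTA path of the
#'   known proteome (may be empty).
#' @param orfs an `orf_set` data.frame from [six_frame_translate()] and/or
#'   [three_frame_translate()], or `NULL`.
#' @param decoy_prefix identifier prefix marking decoy entries.
#' @return a list of class `search_db` with elements `targets` (data.frame:
#'   `id`, `aa_seq`, `provenance`, and the ORF coordinate columns, `NA` for
#'   known proteins) and `decoys` (data.frame: `id`, `aa_seq`).
#' @export
build_search_db <- function(known = NULL, orfs = NULL, decoy_prefix = "rev_") {
  ktab <- NULL
  if (!is.null(known) && length(known) > 0L) {
    kseq <- if (is.character(known) && length(known) == 1L &&
                file.exists(known) && is.null(names(known)))
      as_named_seqs(Biostrings::readAAStringSet(known)) else
      as_named_seqs(known, "known proteome")
    ktab <- data.frame(id = names(kseq), aa_seq = unname(kseq),
                       provenance = "known", seqid = NA_character_,
                       strand = NA_character_, frame = NA_integer_,
                       start = NA_integer_, end = NA_integer_,
                       start_codon = NA_character_, stringsAsFactors = FALSE)
  }
  otab <- NULL
  if (!is.null(orfs) && nrow(orfs) > 0L) {
    dup <- duplicated(orfs[, c("aa_seq", "seqid", "strand", "start", "end")])
    orfs <- orfs[!dup, , drop = FALSE]
    otab <- data.frame(id = orfs$orf_id, aa_seq = orfs$aa_seq,
                       provenance = orfs$source, seqid = orfs$seqid,
                       strand = orfs$strand, frame = orfs$frame,
                       start = orfs$start, end = orfs$end,
                       start_codon = orfs$start_codon,
                       stringsAsFactors = FALSE)
  }
  targets <- rbind(ktab, otab)
  if (is.null(targets))
    targets <- data.frame(id = character(), aa_seq = character(),
                          provenance = character(), seqid = character(),
                          strand = character(), frame = integer(),
                          start = integer(), end = integer(),
                          start_codon = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(targets$id)) {
    coll <- unique(targets$id[duplicated(targets$id)])
    stop("duplicate database identifiers: ", paste(coll, collapse = ", "))
  }
  decoys <- data.frame(
    id = paste0(decoy_prefix, targets$id),
    aa_seq = reverse_string(targets$aa_seq),
    stringsAsFactors = FALSE)
  structure(list(targets = targets, decoys = decoys,
                 decoy_prefix = decoy_prefix),
            class = "search_db")
}

reverse_string <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste0(rev(ch), collapse = ""),
         character(1))
}

#' Write a search database as FASTA
#'
#' Targets first, then decoys; ORF headers carry the coordinate grammar of
#' [format_orf_id()].
#'
#' @param db a `search_db` object.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_search_db <- function(db, path) {
  stopifnot(inherits(db, "search_db"))
  ids <- c(db$targets$id, db$decoys$id)
  seqs <- c(db$targets$aa_seq, db$decoys$aa_seq)
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}
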