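#' @importFrom Biostrings GENETIC_CODE DNAStringSet DNAString reverseComplement
#'   AAStringSet readDNAStringSet readAAStringSet writeXStringSet
#' @importFrom methods is
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# rbind a list of data.frames; NULL when the list is empty
rbind_rows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codon -> amino acid lookup (standard code); names are codons
codon_to_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

codons_for_aa <- function(aa) {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

#' Collapse isoleucine to leucine for mass-equivalent peptide comparison
#'
#' Isoleucine and leucine are isobaric and indistinguishable by standard
#' MS/MS, so peptide-to-protein matching treats them as one residue.
#'
#' @param x character vector of amino-acid sequences.
#' @return `x` with every `I` replaced by `L`.
#' @export
il_collapse <- function(x) {
  gsub("I", "L", x, fixed = TRUE)
}

# Translate a DNA string (length a multiple of 3 or trailing bases ignored)
# to amino acids. Stops translate to "*"; codons containing N to NA.
translate_codons <- function(codons) {
  aa <- codon_to_aa(codons)
  aa
}

translate_dna <- function(seq, strip_stop = TRUE) {
  n <- floor(nchar(seq) / 3)
  if (n == 0L) return("")
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- codon_to_aa(codons)
  if (strip_stop) aa <- aa[aa != "*" | is.na(aa)]
  paste0(aa, collapse = "")
}

# coerce character vector / XStringSet to a named character vector
as_named_seqs <- function(x, what = "sequences") {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
    # FASTA descriptions: keep the first whitespace-delimited token as id
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0L)
      names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop(what, " must be a character vector or an XStringSet")
}

check_dna_alphabet <- function(seqs) {
  offending <- unique(unlist(regmatches(seqs, gregexpr("[^ACGTN]", seqs))))
  if (length(offending) > 0L)
    stop("non-DNA character(s) in input: ", paste(offending, collapse = ", "))
  invisible(TRUE)
}

check_aa_alphabet <- function(seqs) {
  pat <- paste0("[^", paste0(AA_ALPHABET20, collapse = ""), "]")
  offending <- unique(unlist(regmatches(seqs, gregexpr(pat, seqs))))
  if (length(offending) > 0L)
    stop("non-amino-acid character(s) in input: ", paste(offending, collapse = ", "))
  invisible(TRUE)
}

# deterministic random DNA / protein generation helpers (caller seeds RNG)
random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n_res, kr_every = NULL) {
  aa <- sample(setdiff(AA_ALPHABET20, c("M")), n_res, replace = TRUE)
  if (!is.null(kr_every)) {
    # sprinkle tryptic sites so digestion yields peptides of useful length
    pos <- seq(kr_every, n_res - 1L, by = kr_every)
    aa[pos] <- sample(c("K", "R"), length(pos), replace = TRUE)
    # avoid K/R followed by P which would suppress cleavage
    aa[pos + 1L][aa[pos + 1L] == "P"] <- "A"
  }
  paste0(c("M", aa[-1L]), collapse = "")
}

# reverse-translate a protein to a CDS by sampling synonymous codons;
# initiator M always uses ATG, and a TAA stop is appended
reverse_translate <- function(protein, stop_codon = "TAA") {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(seq_along(aa), function(i) {
    if (i == 1L && aa[i] == "M") return("ATG")
    cand <- codons_for_aa(aa[i])
    cand[sample.int(length(cand), 1L)]
  }, character(1))
  paste0(c(codons, stop_codon), collapse = "")
}
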