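# Independent brute-force oracles, written before and kept independent of
# the implementation paths they check.

GC <- Biostrings::GENETIC_CODE

# --- tryptic digestion oracle: enumerate every substring and keep the
# valid cleavage products (both ends at cleavage boundaries or termini,
# internal missed cleavages <= mc)
oracle_digest <- function(protein, mc, min_len = 7L, max_len = 40L) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  is_site <- function(i) {
    i >= 1 && i < n && ch[i] %in% c("K", "R") && ch[i + 1] != "P"
  }
  peps <- character(0)
  for (s in 1:n) {
    for (e in s:n) {
      if (!(s == 1 || is_site(s - 1))) next
      if (!(e == n || is_site(e))) next
      len <- e - s + 1
      if (len < min_len || len > max_len) next
      internal <- if (e > s) sum(vapply(s:(e - 1), is_site, logical(1))) else 0
      if (internal > mc) next
      peps <- c(peps, substr(protein, s, e))
    }
  }
  sort(unique(peps))
}

# --- six-frame oracle: position-by-position scan, one frame at a time
oracle_sixframe <- function(seqs, min_orf_len, starts = c("ATG", "GTG", "TTG")) {
  rows <- list()
  for (sid in names(seqs)) {
    for (strand in c("+", "-")) {
      s <- seqs[[sid]]
      L <- nchar(s)
      o <- if (strand == "+") s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      for (f in 0:2) {
        ncod <- (nchar(o) - f) %/% 3
        if (ncod < 1) next
        cods <- character(ncod)
        for (i in 1:ncod) cods[i] <- substr(o, f + 3 * i - 2, f + 3 * i)
        aa <- unname(GC[cods])
        brk <- is.na(aa) | aa == "*"
        i <- 1
        while (i <= ncod) {
          if (brk[i]) { i <- i + 1; next }
          j <- i
          while (j < ncod && !brk[j + 1]) j <- j + 1
          stop_after <- (j < ncod) && !is.na(aa[j + 1]) && aa[j + 1] == "*"
          st <- NA
          for (k in i:j) if (cods[k] %in% starts) { st <- k; break }
          if (!is.na(st)) {
            prod <- c("M", if (st < j) aa[(st + 1):j])
            sc <- cods[st]
            oi <- st
          } else {
            prod <- aa[i:j]
            sc <- "fragment"
            oi <- i
          }
          if (length(prod) >= min_orf_len) {
            nt1 <- f + 3 * (oi - 1) + 1
            nt2 <- f + 3 * j + if (stop_after) 3 else 0
            gs <- if (strand == "+") nt1 else nchar(o) - nt2 + 1
            ge <- if (strand == "+") nt2 else nchar(o) - nt1 + 1
            rows[[length(rows) + 1]] <- data.frame(
              seqid = sid, strand = strand, frame = f, start = gs, end = ge,
              aa_seq = paste0(prod, collapse = ""), start_codon = sc,
              stringsAsFactors = FALSE)
          }
          i <- j + 1
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(data.frame(seqid = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      aa_seq = character(), start_codon = character()))
  df[order(df$seqid, df$strand, df$frame, df$start), , drop = FALSE]
}

orf_key <- function(df) {
  sort(paste(df$seqid, df$strand, df$frame, df$start, df$end, df$aa_seq,
             df$start_codon))
}

# --- Pearson oracle from the sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# --- substring partition oracle
oracle_known <- function(peptides, proteome, il = TRUE) {
  f <- function(z) if (il) gsub("I", "L", z, fixed = TRUE) else z
  vapply(peptides, function(p)
    any(vapply(proteome, function(pr)
      grepl(f(p), f(pr), fixed = TRUE), logical(1))), logical(1),
    USE.NAMES = FALSE)
}

# --- splice oracle: enumerate every GT..AG intron on both strands of a
# small genome, splice it out, translate in 3 frames, and search for the
# peptide; returns the set of junction keys (seqid strand intron coords)
oracle_splice_junctions <- function(pep, seqs, max_intron, il = TRUE) {
  f <- function(z) if (il) gsub("I", "L", z, fixed = TRUE) else z
  keys <- character(0)
  for (sid in names(seqs)) {
    fwd <- seqs[[sid]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      o <- if (strand == "+") fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      gts <- gregexpr("GT", o, fixed = TRUE)[[1]]
      ags <- gregexpr("AG", o, fixed = TRUE)[[1]]
      if (gts[1] == -1 || ags[1] == -1) next
      for (g in gts) for (a in ags) {
        ilen <- a + 2 - g
        if (ilen < 4 || ilen > max_intron) next
        spliced <- paste0(substr(o, 1, g - 1), substr(o, a + 2, nchar(o)))
        hit <- FALSE
        for (fr in 0:2) {
          ncod <- (nchar(spliced) - fr) %/% 3
          if (ncod < nchar(pep)) next
          st <- fr + 3 * (seq_len(ncod) - 1) + 1
          aa <- unname(GC[substring(spliced, st, st + 2)])
          aa[is.na(aa)] <- "X"
          tr <- paste0(aa, collapse = "")
          m <- regexpr(f(pep), f(tr), fixed = TRUE)
          if (m != -1) {
            # the placement must genuinely span the junction: the peptide
            # must start before the splice point and end after it
            p1 <- fr + 3 * (as.integer(m) - 1) + 1
            p2 <- p1 + 3 * nchar(pep) - 1
            if (p1 <= g - 1 - 8 && p2 >= g + 8) hit <- TRUE
          }
        }
        if (hit) {
          # intron in forward coordinates
          i1 <- if (strand == "+") g else L - (a + 1) + 1
          i2 <- if (strand == "+") a + 1 else L - g + 1
          keys <- c(keys, paste(sid, strand, i1, i2))
        }
      }
    }
  }
  sort(unique(keys))
}
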