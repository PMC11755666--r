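#' Default modification mass table
#'
#' Eighteen modifications common in eukaryotes with monoisotopic mass
#' shifts from the public Unimod registry. The table is a plain data.frame
#' and fully user-replaceable; `residues = "any"` means no residue
#' restriction.
#'
#' @return a data.frame: `name`, `delta` (Da), `residues`, `terminus`.
#' @export
default_modification_table <- function() {
  data.frame(
    name = c("carbamylation", "oxidation", "acetylation", "phosphorylation",
             "methylation", "dimethylation", "trimethylation", "deamidation",
             "formylation", "carbamidomethylation", "hexnac", "hexose",
             "glygly", "succinylation", "malonylation", "crotonylation",
             "propionylation", "butyrylation"),
    delta = c(43.005814, 15.994915, 42.010565, 79.966331, 14.015650,
              28.031300, 42.046950, 0.984016, 27.994915, 57.021464,
              203.079373, 162.052824, 114.042927, 100.016044, 86.000394,
              68.026215, 56.026215, 70.041865),
    residues = c("K", "MW", "K", "STY", "KR", "KR", "K", "NQ", "K", "C",
                 "NST", "ST", "K", "K", "K", "K", "K", "K"),
    terminus = "none",
    stringsAsFactors = FALSE)
}

#' Read / write a modification table as TSV
#'
#' @param path TSV with columns `name`, `delta`, `residues`, `terminus`.
#' @return a modification table data.frame.
#' @export
read_modification_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "delta", "residues", "terminus") %in% names(tab)))
  tab
}

#' @rdname read_modification_table
#' @param table the modification table to write.
#' @export
write_modification_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Annotate precursor delta masses against a modification table
#'
#' A simplified open-modification annotation: each accepted PSM's precursor
#' mass delta is classified as rejected (|delta| above the
#' `ptm_max_shift` cap), unmodified (within `ptm_tolerance` of zero),
#' matched (nearest table entry within tolerance; every entry within
#' tolerance is listed as ambiguous), or unmatched (a real shift no entry
#' explains). No spectrum-level site localisation is attempted.
#'
#' @param psms a PSM data.frame with a `precursor_delta_mass` column; when
#'   an `accepted` column is present only accepted target rows are
#'   annotated.
#' @param table a modification table (see [default_modification_table()]).
#' @param config a [pipeline_config()] (uses `ptm_max_shift`,
#'   `ptm_tolerance`).
#' @return a list of class `ptm_annotation`: `annotations` (data.frame:
#'   `peptide`, `observed_delta`, `status`, `matched_name`, `mass_error`,
#'   `ambiguous_matches`), `counts` (named per-modification counts plus
#'   `unmodified`, `unmatched`, `rejected`), `most_frequent` (modification
#'   name or `NA`).
#' @export
annotate_delta_masses <- function(psms, table = default_modification_table(),
                                  config = pipeline_config()) {
  if (nrow(table) == 0L) stop("modification table is empty")
  stopifnot("precursor_delta_mass" %in% names(psms))
  if ("accepted" %in% names(psms))
    psms <- psms[psms$accepted & !psms$is_decoy, , drop = FALSE]
  tab <- table[abs(table$delta) <= config$ptm_max_shift, , drop = FALSE]
  d <- psms$precursor_delta_mass
  n <- length(d)
  status <- character(n)
  matched <- rep(NA_character_, n)
  err <- rep(NA_real_, n)
  ambig <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (abs(d[i]) > config$ptm_max_shift) { status[i] <- "rejected"; next }
    if (abs(d[i]) <= config$ptm_tolerance) { status[i] <- "unmodified"; next }
    dev <- abs(tab$delta - d[i])
    within <- which(dev <= config$ptm_tolerance)
    if (length(within) == 0L) { status[i] <- "unmatched"; next }
    status[i] <- "matched"
    best <- within[which.min(dev[within])]
    matched[i] <- tab$name[best]
    err[i] <- d[i] - tab$delta[best]
    ambig[i] <- paste(tab$name[within[order(dev[within])]], collapse = ",")
  }
  ann <- data.frame(peptide = psms$peptide %||% rep(NA_character_, n),
                    observed_delta = d, status = status,
                    matched_name = matched, mass_error = err,
                    ambiguous_matches = ambig, stringsAsFactors = FALSE)
  per_mod <- table(factor(matched, levels = tab$name))
  counts <- c(as.list(per_mod),
              list(unmodified = sum(status == "unmodified"),
                   unmatched = sum(status == "unmatched"),
                   rejected = sum(status == "rejected")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  mf <- if (any(per_mod > 0)) names(per_mod)[which.max(per_mod)] else
    NA_character_
  structure(list(annotations = ann, counts = counts, most_frequent = mf),
            class = "ptm_annotation")
}
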