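#' Class-specific target-decoy FDR filtering
#'
#' Estimates q-values separately within each peptide class (by default
#' `known` and `novel`) and accepts targets at a q-value threshold. Searching
#' a six-frame genome database inflates the novel search space enormously
#' relative to the known proteome, so false positives concentrate unevenly
#' in the novel class; pooling the classes would let the abundant, mostly
#' correct known identifications mask a high novel-class error rate.
#' Class-specific estimation is the standard proteogenomics remedy.
#'
#' Within a class, rows are ranked by score (descending; at equal score
#' decoys rank above targets, the conservative tie-break). The raw FDR at
#' score s is `d(s)/t(s)`, the decoy and target counts at or above s (or
#' the more conservative `(d+1)/t` with
#' `plus_one = TRUE`), and the q-value is the cumulative minimum of the raw
#' FDR from the bottom of the ranking upward. Decoys are never accepted.
#'
#' By default scores are first rolled up to the best score per
#' (peptide, class) so the estimate is at peptide level; `level = "psm"`
#' scores every row independently.
#'
#' @param psms a PSM data.frame with columns `peptide`, `score`, `is_decoy`,
#'   `class` (and any others, preserved).
#' @param fdr_threshold acceptance threshold on the q-value (default 0.01,
#'   i.e. 1% FDR).
#' @param classes class labels to process; rows with other labels are an
#'   error.
#' @param level `"peptide"` (default) or `"psm"`.
#' @param plus_one use the `(d+1)/t` decoy count correction.
#' @return a list of class `fdr_result`: `psms` (the input with `q_value`
#'   and `accepted` columns added), `thresholds` (per-class score cutoff:
#'   the lowest accepted target score, `NA` when nothing is accepted or no
#'   decoys exist), `fdr_threshold`, `level`.
#' @export
class_specific_fdr <- function(psms, fdr_threshold = 0.01,
                               classes = c("known", "novel"),
                               level = c("peptide", "psm"),
                               plus_one = FALSE) {
  level <- match.arg(level)
  stopifnot(is.data.frame(psms),
            all(c("peptide", "score", "is_decoy", "class") %in% names(psms)))
  if (!all(is.finite(psms$score))) stop("PSM scores must be finite")
  unknown <- setdiff(unique(psms$class), classes)
  if (length(unknown) > 0L)
    stop("unknown peptide class label(s): ", paste(unknown, collapse = ", "))
  psms$q_value <- NA_real_
  psms$accepted <- FALSE
  thresholds <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    ci <- which(psms$class == cl)
    if (length(ci) == 0L) next
    sub <- psms[ci, , drop = FALSE]
    if (sum(!sub$is_decoy) == 0L)
      stop("class '", cl, "' has no target rows")
    if (level == "peptide") {
      key <- paste0(sub$peptide, "\r", sub$is_decoy)
      best <- tapply(sub$score, key, max)
      units <- data.frame(score = as.numeric(best),
                          is_decoy = grepl("\rTRUE$", names(best)),
                          key = names(best), stringsAsFactors = FALSE)
    } else {
      units <- data.frame(score = sub$score, is_decoy = sub$is_decoy,
                          key = seq_len(nrow(sub)), stringsAsFactors = FALSE)
    }
    if (sum(units$is_decoy) == 0L)
      warning("class '", cl, "': no decoys; FDR unestimable, q set to 0")
    # rank: score descending, decoys before targets at ties
    o <- order(-units$score, !units$is_decoy)
    units <- units[o, , drop = FALSE]
    d_cum <- cumsum(units$is_decoy)
    t_cum <- cumsum(!units$is_decoy)
    raw <- (d_cum + if (plus_one) 1 else 0) / pmax(t_cum, 1L)
    if (sum(units$is_decoy) == 0L) raw <- rep(0, nrow(units))
    q <- rev(cummin(rev(raw)))
    units$q_value <- q
    if (level == "peptide") {
      m <- match(paste0(sub$peptide, "\r", sub$is_decoy), units$key)
      qv <- units$q_value[m]
    } else {
      qv <- units$q_value[order(o)]
    }
    psms$q_value[ci] <- qv
    acc <- !psms$is_decoy[ci] & qv <= fdr_threshold
    psms$accepted[ci] <- acc
    if (any(acc)) thresholds[cl] <- min(psms$score[ci][acc])
  }
  structure(list(psms = psms, thresholds = thresholds,
                 fdr_threshold = fdr_threshold, level = level),
            class = "fdr_result")
}

#' Empirical FDR of an accepted set against simulation truth
#'
#' For simulated PSM tables carrying a `truth_correct` flag, computes the
#' realised fraction of incorrect identifications among accepted targets —
#' the quantity the target-decoy estimate is supposed to control.
#'
#' @param result an `fdr_result` from [class_specific_fdr()].
#' @param by_class return one value per class instead of the pooled fraction.
#' @return fraction in `[0, 1]` (or a named vector per class); 0 with a
#'   warning when nothing is accepted.
#' @export
empirical_fdr <- function(result, by_class = FALSE) {
  stopifnot(inherits(result, "fdr_result"))
  psms <- result$psms
  acc <- psms[psms$accepted & !psms$is_decoy, , drop = FALSE]
  if (is.null(psms$truth_correct) ||
      (nrow(acc) > 0L && anyNA(acc$truth_correct)))
    stop("truth_correct flags missing on accepted targets")
  if (nrow(acc) == 0L) {
    warning("no accepted identifications; empirical FDR reported as 0")
    if (by_class)
      return(stats::setNames(rep(0, length(result$thresholds)),
                             names(result$thresholds)))
    return(0)
  }
  if (by_class) {
    cls <- names(result$thresholds)
    vapply(stats::setNames(cls, cls), function(cl) {
      a <- acc[acc$class == cl, , drop = FALSE]
      if (nrow(a) == 0L) 0 else mean(!a$truth_correct)
    }, numeric(1))
  } else {
    mean(!acc$truth_correct)
  }
}
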