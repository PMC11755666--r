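#' Quantifiability filter on an intensity matrix
#'
#' Keeps features detected (non-missing, positive) in at least
#' `min_detections` replicates of at least one tissue — the "at least twice
#' in three biological replicates" rule.
#'
#' @param mat numeric matrix, features x samples; `NA` or 0 = not detected.
#' @param groups factor/character of tissue labels, one per column.
#' @param min_detections minimum detections within a tissue (default 2).
#' @return the filtered matrix.
#' @export
quantifiable_filter <- function(mat, groups, min_detections = 2L) {
  stopifnot(ncol(mat) == length(groups))
  if (min_detections > max(table(groups)))
    stop("min_detections exceeds the replicate count of every tissue")
  det <- !is.na(mat) & mat > 0
  keep <- rep(FALSE, nrow(mat))
  for (g in unique(groups)) {
    cnt <- rowSums(det[, groups == g, drop = FALSE])
    keep <- keep | cnt >= min_detections
  }
  mat[keep, , drop = FALSE]
}

#' Differential protein expression between two tissues
#'
#' Per-feature two-sample t-test on log2 intensities (Welch by default;
#' `pooled = TRUE` gives the classical equal-variance Student test),
#' Benjamini-Hochberg q-values across all tested features, and the
#' fold-change/p-value gate: a feature is differentially expressed when its
#' linear fold change is >= `dep_fc` or <= 1/`dep_fc` and its raw p-value is
#' <= `dep_p` (`strict_q = TRUE` gates on the q-value instead). Features
#' must pass [quantifiable_filter()] in both tissues of the comparison;
#' missing values are excluded, never imputed.
#'
#' The reported `log2_fc` is the second-named tissue over the first.
#'
#' @param mat numeric intensity matrix (linear scale unless
#'   `log_transformed`).
#' @param groups tissue label per column.
#' @param comparison character vector of two tissue labels `c(A, B)`.
#' @param config a [pipeline_config()] (uses `dep_fc`, `dep_p`).
#' @param min_detections quantifiability threshold within each tissue.
#' @param pooled use pooled-variance Student's t-test.
#' @param strict_q gate on BH q instead of raw p.
#' @param log_transformed input is already log2 (skip the transform).
#' @return a data.frame of class `dep_records`: `feature`, `tissue_a`,
#'   `tissue_b`, `log2_fc`, `p_value`, `q_value`, `direction`, `is_dep`.
#' @export
call_deps <- function(mat, groups, comparison, config = pipeline_config(),
                      min_detections = 2L, pooled = FALSE, strict_q = FALSE,
                      log_transformed = FALSE) {
  stopifnot(length(comparison) == 2L, all(comparison %in% groups))
  a <- comparison[1]; b <- comparison[2]
  ia <- which(groups == a); ib <- which(groups == b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("fewer than 2 replicates in a comparison tissue")
  det <- !is.na(mat) & mat > 0
  keep <- rowSums(det[, ia, drop = FALSE]) >= min_detections &
    rowSums(det[, ib, drop = FALSE]) >= min_detections
  m <- mat[keep, , drop = FALSE]
  if (nrow(m) == 0L)
    return(structure(data.frame(feature = character(), tissue_a = character(),
                                tissue_b = character(), log2_fc = numeric(),
                                p_value = numeric(), q_value = numeric(),
                                direction = character(), is_dep = logical(),
                                stringsAsFactors = FALSE),
                     class = c("dep_records", "data.frame")))
  lm_ <- if (log_transformed) m else log2(ifelse(det[keep, , drop = FALSE],
                                                 m, NA))
  res <- t(vapply(seq_len(nrow(lm_)), function(i) {
    xa <- lm_[i, ia]; xa <- xa[!is.na(xa)]
    xb <- lm_[i, ib]; xb <- xb[!is.na(xb)]
    fc <- mean(xb) - mean(xa)
    if (stats::sd(c(xa - mean(xa), xb - mean(xb))) == 0) {
      p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      p <- tryCatch(stats::t.test(xb, xa, var.equal = pooled)$p.value,
                    error = function(e) 1)
    }
    c(fc, p)
  }, numeric(2)))
  q <- stats::p.adjust(res[, 2], method = "BH")
  lfc_gate <- abs(res[, 1]) >= log2(config$dep_fc)
  p_gate <- if (strict_q) q <= config$dep_p else res[, 2] <= config$dep_p
  out <- data.frame(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
                    tissue_a = a, tissue_b = b, log2_fc = res[, 1],
                    p_value = res[, 2], q_value = q,
                    direction = ifelse(res[, 1] >= 0, "up", "down"),
                    is_dep = lfc_gate & p_gate, stringsAsFactors = FALSE)
  class(out) <- c("dep_records", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation of transcript and protein changes, split by subset
#'
#' Computes the Pearson correlation between per-feature protein and
#' transcript log2 ratios for four subsets: all shared features; the
#' cor-DEGs-DEPs (differential in both layers); and, within the
#' cor-DEGs-DEPs, the same-trend (signs agree) and opposite-trend subsets.
#' A subset with fewer than 3 members gets `NA` with a warning.
#'
#' @param protein_ratios,transcript_ratios named numeric vectors of
#'   per-feature log2 ratios for the same comparison.
#' @param dep_flags,deg_flags named logical vectors (differential protein /
#'   transcript); defaults treat every feature as differential.
#' @return a data.frame: `subset`, `n`, `r`.
#' @export
correlate_omics <- function(protein_ratios, transcript_ratios,
                            dep_flags = NULL, deg_flags = NULL) {
  shared <- intersect(names(protein_ratios), names(transcript_ratios))
  if (length(shared) == 0L) stop("no shared feature identifiers")
  p <- protein_ratios[shared]; t_ <- transcript_ratios[shared]
  if (is.null(dep_flags))
    dep_flags <- stats::setNames(rep(TRUE, length(shared)), shared)
  if (is.null(deg_flags))
    deg_flags <- stats::setNames(rep(TRUE, length(shared)), shared)
  cor_set <- shared[dep_flags[shared] & deg_flags[shared] &
                      !is.na(dep_flags[shared]) & !is.na(deg_flags[shared])]
  same <- cor_set[sign(p[cor_set]) == sign(t_[cor_set])]
  oppo <- cor_set[sign(p[cor_set]) != sign(t_[cor_set])]
  one <- function(label, ids) {
    if (length(ids) < 3L) {
      warning("subset '", label, "' has fewer than 3 features; r omitted")
      r <- NA_real_
    } else r <- stats::cor(p[ids], t_[ids], method = "pearson")
    data.frame(subset = label, n = length(ids), r = r,
               stringsAsFactors = FALSE)
  }
  rbind(one("all", shared), one("cor_degs_deps", cor_set),
        one("same_trend", same), one("opposite_trend", oppo))
}
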