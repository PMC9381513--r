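#' Detection prevalence and mean expression per group
#'
#' For one gene, reports per annotation group the percentage of
#' observations with expression above `threshold` and the mean expression
#' over all observations of the group (zeros included), on the matrix's
#' declared scale. This is the per-lineage summary used to describe, e.g.,
#' what fraction of tumor cells express an ectonucleotidase transcript and
#' at what mean level.
#'
#' @param expr an [expression_matrix()].
#' @param group_by name of the annotation column defining groups.
#' @param gene gene symbol.
#' @param threshold detection cutoff; an observation is "detected" when its
#'   value is strictly greater (default 0).
#' @return data.frame: `gene`, `group`, `n`, `percent_detected`,
#'   `mean_expression`.
#' @export
detection_prevalence <- function(expr, group_by, gene, threshold = 0) {
  if (!gene %in% rownames(expr$values)) {
    stop("detection_prevalence: gene not in matrix: ", gene)
  }
  if (!group_by %in% names(expr$annotations)) {
    stop("detection_prevalence: annotation column not found: ", group_by)
  }
  v <- expr$values[gene, ]
  grp <- expr$annotations[[group_by]]
  out <- do.call(rbind, lapply(split(v, grp), function(x) {
    data.frame(n = length(x),
               percent_detected = 100 * mean(x > threshold),
               mean_expression = mean(x))
  }))
  data.frame(gene = gene, group = rownames(out), out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score observations against gene signatures
#'
#' The default score of an observation for a signature is
#' `log2(pseudocount + mean(expression of the signature's genes))`, the
#' log2-mean population-abundance score; `method = "mean_log2"` instead
#' averages `log2(pseudocount + expression)` per gene. Signature genes
#' absent from the matrix are dropped with a warning; a signature with no
#' gene present scores NA (flagged, not zero).
#'
#' @param expr an [expression_matrix()].
#' @param signatures a [signature_set()].
#' @param pseudocount added inside the log (default 1).
#' @param method `"log2_mean"` (default) or `"mean_log2"`.
#' @return object of class `signature_scores`: observations x signatures
#'   numeric matrix with attribute `method`.
#' @export
signature_score <- function(expr, signatures, pseudocount = 1,
                            method = c("log2_mean", "mean_log2")) {
  method <- match.arg(method)
  stopifnot(inherits(signatures, "signature_set"))
  genes <- rownames(expr$values)
  scores <- sapply(names(signatures), function(s) {
    g <- unclass(signatures)[[s]]
    present <- intersect(g, genes)
    if (length(present) < length(g)) {
      warning("signature_score: ", s, ": ", length(g) - length(present),
              " gene(s) absent from matrix, dropped")
    }
    if (length(present) == 0L) {
      warning("signature_score: ", s, ": no gene present; score undefined")
      return(rep(NA_real_, ncol(expr$values)))
    }
    sub <- expr$values[present, , drop = FALSE]
    if (method == "log2_mean") {
      log2(pseudocount + colMeans(sub))
    } else {
      colMeans(log2(pseudocount + sub))
    }
  })
  scores <- matrix(scores, ncol = length(signatures),
                   dimnames = list(colnames(expr$values), names(signatures)))
  structure(scores, method = method, class = c("signature_scores", "matrix"))
}

#' Quartile- or double-gene-stratified score comparison
#'
#' Splits observations into a high and a low group from a stratification
#' variable and compares every signature's scores between the groups with
#' an unpaired two-sided Wilcoxon rank-sum test. Quartile mode takes the
#' top versus bottom quartile (`floor(n/4)` observations each; ties at the
#' cut are resolved by rank with ascending observation-id tie-break).
#' Double-gene mode takes observations above both medians of two
#' stratification variables versus observations below both.
#'
#' @param scores a [signature_score()] result.
#' @param strat_values numeric per-observation stratification variable
#'   (e.g. a gene's expression).
#' @param mode `"quartile"` or `"double_gene"`.
#' @param strat_values2 second variable, required for double-gene mode.
#' @return data.frame: `signature`, `n_high`, `n_low`, `statistic` (rank-sum
#'   W), `p`, `p_adj` (Benjamini-Hochberg across signatures).
#' @export
stratify_and_compare <- function(scores, strat_values,
                                 mode = c("quartile", "double_gene"),
                                 strat_values2 = NULL) {
  mode <- match.arg(mode)
  n <- nrow(scores)
  stopifnot(length(strat_values) == n)
  obs_id <- rownames(scores)
  if (is.null(obs_id)) obs_id <- as.character(seq_len(n))
  if (mode == "quartile") {
    q <- floor(n / 4)
    ord <- order(strat_values, obs_id)
    low_idx <- ord[seq_len(q)]
    high_idx <- ord[seq.int(n - q + 1L, n)]
  } else {
    stopifnot(length(strat_values2) == n)
    m1 <- stats::median(strat_values)
    m2 <- stats::median(strat_values2)
    high_idx <- which(strat_values > m1 & strat_values2 > m2)
    low_idx <- which(strat_values < m1 & strat_values2 < m2)
  }
  if (length(high_idx) < 4L || length(low_idx) < 4L) {
    stop("stratify_and_compare: degenerate strata (need >= 4 observations per group)")
  }
  res <- do.call(rbind, lapply(colnames(scores), function(s) {
    hi <- scores[high_idx, s]
    lo <- scores[low_idx, s]
    if (anyNA(hi) || anyNA(lo)) {
      return(data.frame(signature = s, n_high = length(high_idx),
                        n_low = length(low_idx), statistic = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(hi, lo, alternative = "two.sided",
                                              paired = FALSE))
    data.frame(signature = s, n_high = length(high_idx),
               n_low = length(low_idx), statistic = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}
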