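#' Per-cell DNA coefficient of variation
#'
#' For every cell, the coefficient of variation (CV) of its per-cycle DNA
#' (nuclear stain) intensities: population standard deviation (divisor `n`)
#' divided by the mean. Cells whose mean DNA intensity is exactly 0 carry no
#' nucleus at any cycle; their CV is undefined and they are flagged instead.
#'
#' @param table a [cell_table()] with at least 2 DNA cycles.
#' @return data.frame with columns `cell_id`, `cv` (NA when undefined) and
#'   `zero_dna` (logical).
#' @export
compute_dna_cv <- function(table) {
  if (length(table$dna_cols) < 2L) stop("CV requires >=2 cycles")
  dna <- as.matrix(table$data[, table$dna_cols, drop = FALSE])
  mu <- rowMeans(dna)
  ssd <- sqrt(rowMeans(dna^2) - mu^2)      # population sd
  cv <- ifelse(mu > 0, ssd / mu, NA_real_)
  data.frame(cell_id = table$data$cell_id, cv = cv, zero_dna = mu == 0,
             stringsAsFactors = FALSE)
}

#' Remove cells lost across imaging cycles
#'
#' Implements the nuclear-stain QC filter: cells with zero DNA intensity are
#' removed first, then cells whose DNA CV exceeds
#' `mean(CV) + sd_multiplier * sd(CV)` are removed. The mean and sd of the CV
#' distribution are computed once, over all CV-defined cells, before any
#' CV-based removal (single pass).
#'
#' @param table a [cell_table()].
#' @param sd_multiplier threshold multiplier, default 3.
#' @return list with elements `table` (filtered `cell_table`) and `report`
#'   (a `qc_report`).
#' @export
filter_dna_cv <- function(table, sd_multiplier = 3) {
  cvs <- compute_dna_cv(table)
  zero <- cvs$zero_dna
  if (all(zero)) {
    warning("filter_dna_cv: all cells have zero DNA intensity")
    rep <- qc_report(n_input = n_cells(table),
                    removed = data.frame(cell_id = cvs$cell_id,
                                         reason = "zero_dna",
                                         stringsAsFactors = FALSE),
                    cv_threshold = NA_real_)
    return(list(table = subset_cells(table, !zero), report = rep))
  }
  defined <- cvs$cv[!zero]
  thr <- mean(defined) + sd_multiplier * stats::sd(defined)
  if (is.na(thr)) thr <- Inf                      # single defined cell
  high_cv <- !zero & cvs$cv > thr
  removed <- rbind(
    data.frame(cell_id = cvs$cell_id[zero],
               reason = rep("zero_dna", sum(zero)),
               stringsAsFactors = FALSE),
    data.frame(cell_id = cvs$cell_id[high_cv],
               reason = rep("high_cv", sum(high_cv)),
               stringsAsFactors = FALSE)
  )
  list(
    table = subset_cells(table, !zero & !high_cv),
    report = qc_report(n_input = n_cells(table), removed = removed,
                       cv_threshold = thr)
  )
}

#' Remove highly autofluorescent cells
#'
#' Fits a 2-component Gaussian mixture to the natural-log (plus one
#' pseudocount) intensities of each named autofluorescence channel; cells
#' assigned to the higher-mean component with posterior probability > 0.5
#' are removed. If the component means are separated by less than
#' `min_separation` log units the channel is considered unimodal and no
#' cells are removed for it. Removals are unioned over channels.
#'
#' @param table a [cell_table()].
#' @param af_markers character vector of autofluorescence channel names;
#'   empty vector leaves the table unchanged.
#' @param min_separation minimum component-mean separation (log units).
#' @param seed integer seed for mixture fitting.
#' @return list with `table` and `report` as in [filter_dna_cv()].
#' @export
filter_autofluorescence <- function(table, af_markers, min_separation = 0.5,
                                    seed = 1L) {
  miss <- setdiff(af_markers, table$marker_cols)
  if (length(miss) > 0L) {
    stop("filter_autofluorescence: AF channel not in table: ",
         paste(miss, collapse = ", "))
  }
  remove <- rep(FALSE, n_cells(table))
  comp <- list()
  for (mk in af_markers) {
    fit <- fit_gmm2(log1p(table$data[[mk]]), seed = seed)
    comp[[mk]] <- fit[c("means", "sds", "weights")]
    if (is.null(fit$posterior_hi)) next
    if (diff(range(fit$means)) < min_separation) next
    remove <- remove | fit$posterior_hi > 0.5
  }
  removed <- data.frame(cell_id = table$data$cell_id[remove],
                        reason = rep("high_af", sum(remove)),
                        stringsAsFactors = FALSE)
  list(
    table = subset_cells(table, !remove),
    report = qc_report(n_input = n_cells(table), removed = removed,
                       af_components = comp)
  )
}

#' Full single-cell QC pipeline
#'
#' Applies the filters in fixed order: zero-DNA removal, DNA-CV filter, then
#' the autofluorescence filter, and reconciles counts in a combined report.
#'
#' @inheritParams filter_dna_cv
#' @inheritParams filter_autofluorescence
#' @return list with `table` (QC-passed cells) and `report`.
#' @export
qc_pipeline <- function(table, sd_multiplier = 3, af_markers = character(0),
                        min_separation = 0.5, seed = 1L) {
  s1 <- filter_dna_cv(table, sd_multiplier = sd_multiplier)
  s2 <- filter_autofluorescence(s1$table, af_markers = af_markers,
                                min_separation = min_separation, seed = seed)
  removed <- rbind(s1$report$removed, s2$report$removed)
  rep <- qc_report(n_input = n_cells(table), removed = removed,
                   cv_threshold = s1$report$cv_threshold,
                   af_components = s2$report$af_components)
  list(table = s2$table, report = rep)
}

qc_report <- function(n_input, removed, cv_threshold = NA_real_,
                      af_components = NULL) {
  stopifnot(!anyDuplicated(removed$cell_id))
  structure(
    list(
      n_input = n_input,
      n_removed_zero_dna = sum(removed$reason == "zero_dna"),
      n_removed_cv = sum(removed$reason == "high_cv"),
      n_removed_af = sum(removed$reason == "high_af"),
      n_retained = n_input - nrow(removed),
      removed = removed,
      cv_threshold = cv_threshold,
      af_components = af_components
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d cells in; removed %d zero-DNA, %d high-CV (thr %.4g), %d high-AF; %d retained\n",
    x$n_input, x$n_removed_zero_dna, x$n_removed_cv, x$cv_threshold,
    x$n_removed_af, x$n_retained
  ))
  invisible(x)
}

subset_cells <- function(table, keep) {
  d <- table$data[keep, , drop = FALSE]
  rownames(d) <- NULL
  structure(list(data = d, marker_cols = table$marker_cols,
                 dna_cols = table$dna_cols),
            class = "cell_table")
}

# Two-component univariate Gaussian mixture on already-transformed values,
# fitted by EM (mclust) from a deterministic median-split initialization
# plus seeded random-quantile restarts; the best log-likelihood is kept.
# Returns component parameters and each cell's posterior for the
# higher-mean component; degenerate inputs give posterior_hi = NULL.
fit_gmm2 <- function(v, seed = 1L, n_restarts = 10L) {
  if (length(unique(v)) < 2L) {
    warning("fit_gmm2: values are constant; no mixture fitted")
    return(list(means = rep(v[1L], 2L), sds = c(0, 0), weights = c(1, 0),
                posterior_hi = NULL))
  }
  set.seed(seed)
  cuts <- c(0.5, stats::runif(n_restarts - 1L, 0.1, 0.9))
  best <- NULL
  for (p in cuts) {
    split <- as.integer(v > stats::quantile(v, p)) + 1L
    if (length(unique(split)) < 2L) next
    em <- tryCatch(
      mclust::meV(data = v, z = mclust::unmap(split), prior = NULL,
                  control = mclust::emControl()),
      error = function(e) NULL
    )
    if (is.null(em) || !is.finite(em$loglik)) next
    if (is.null(best) || em$loglik > best$loglik) best <- em
  }
  if (is.null(best)) {
    # EM degenerates when a component's variance collapses (e.g. perfectly
    # separated or tied values); fall back to a hard 2-means split
    km <- tryCatch(stats::kmeans(v, centers = 2, nstart = 5),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2L) {
      warning("fit_gmm2: mixture fit failed; treating as unimodal")
      return(list(means = rep(mean(v), 2L), sds = rep(stats::sd(v), 2L),
                  weights = c(1, 0), posterior_hi = NULL))
    }
    mu <- as.numeric(tapply(v, km$cluster, mean))
    sds <- as.numeric(tapply(v, km$cluster, function(x) {
      max(stats::sd(x), 1e-6)
    }))
    sds[is.na(sds)] <- 1e-6
    hi <- which.max(mu)
    return(list(means = mu, sds = sds,
                weights = as.numeric(table(km$cluster)) / length(v),
                posterior_hi = as.numeric(km$cluster == hi)))
  }
  mu <- as.numeric(best$parameters$mean)
  sig <- sqrt(as.numeric(best$parameters$variance$sigmasq))
  if (length(sig) == 1L) sig <- rep(sig, 2L)
  hi <- which.max(mu)
  list(means = mu, sds = sig, weights = as.numeric(best$parameters$pro),
       posterior_hi = best$z[, hi])
}
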