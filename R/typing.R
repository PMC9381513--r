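#' Gate a marker by two-component Gaussian mixture modeling
#'
#' Fits a 2-component Gaussian mixture to `log(value + 1)`; the higher-mean
#' component defines marker positivity. The gate threshold is the intensity
#' between the two component means at which the posterior probabilities of
#' the components are equal. If the component means are separated by less
#' than `min_separation` log units the marker is treated as unimodal and all
#' cells are called negative.
#'
#' @param values nonnegative per-cell intensities (>= 20 cells).
#' @param seed integer seed for the mixture fit.
#' @param min_separation minimum log-scale separation of component means.
#' @param marker optional marker name carried in the result.
#' @return object of class `gate_result`: list with `marker`, `threshold`
#'   (intensity scale; NA when no gate), `means`, `sds`, `weights` (log
#'   scale), `positive` (logical per cell), `posterior` (probability of the
#'   positive component).
#' @export
gmm_gate <- function(values, seed = 1L, min_separation = 0.5, marker = NULL) {
  if (length(values) < 20L) stop("gmm_gate: need >= 20 cells")
  lv <- log1p(values)
  n <- length(values)
  no_gate <- function(fit) {
    structure(list(marker = marker, threshold = NA_real_, means = fit$means,
                   sds = fit$sds, weights = fit$weights,
                   positive = rep(FALSE, n), posterior = rep(0, n)),
              class = "gate_result")
  }
  if (length(unique(values)) < 2L) {
    warning("gmm_gate: constant values; all cells negative")
    return(no_gate(list(means = rep(lv[1L], 2L), sds = c(0, 0),
                        weights = c(1, 0))))
  }
  fit <- fit_gmm2(lv, seed = seed)
  if (is.null(fit$posterior_hi) || diff(range(fit$means)) < min_separation) {
    return(no_gate(fit))
  }
  structure(
    list(marker = marker, threshold = gate_threshold(fit),
         means = fit$means, sds = fit$sds, weights = fit$weights,
         positive = fit$posterior_hi > 0.5, posterior = fit$posterior_hi),
    class = "gate_result"
  )
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf(
    "gate_result%s: threshold %.4g; %d/%d positive; log-means %.2f / %.2f\n",
    if (is.null(x$marker)) "" else paste0(" [", x$marker, "]"),
    x$threshold, sum(x$positive), length(x$positive),
    min(x$means), max(x$means)
  ))
  invisible(x)
}

# Intensity at which the two mixture components have equal posterior,
# searched between the component means on the log scale.
gate_threshold <- function(fit) {
  lo <- which.min(fit$means)
  hi <- which.max(fit$means)
  f <- function(x) {
    fit$weights[hi] * stats::dnorm(x, fit$means[hi], max(fit$sds[hi], 1e-6)) -
      fit$weights[lo] * stats::dnorm(x, fit$means[lo], max(fit$sds[lo], 1e-6))
  }
  root <- tryCatch(
    stats::uniroot(f, lower = fit$means[lo], upper = fit$means[hi])$root,
    error = function(e) mean(fit$means)
  )
  expm1(root)
}

#' Default lineage gating rules
#'
#' Ordered rules assigning each cell its lineage from gated marker
#' positivity; the first matching rule wins. The default hierarchy resolves
#' double-positives toward the rarer, more specific lineages: Endothelial
#' (CD31+), then Lymphoid (CD45+ CD3+), then Myeloid (CD45+ PU.1+, or CD45+
#' alone when PU.1 is absent from the panel), then Tumor (SOX2+); anything
#' else is Other.
#'
#' @return list of rules, each `list(label=, markers=, fallback_markers=)`.
#' @export
default_typing_rules <- function() {
  list(
    list(label = "Endothelial", markers = "CD31"),
    list(label = "Lymphoid", markers = c("CD45", "CD3")),
    list(label = "Myeloid", markers = c("CD45", "PU.1"),
         fallback_markers = "CD45"),
    list(label = "Tumor", markers = "SOX2")
  )
}

#' Lineage labels for a cell table
#'
#' @return character vector of the five lineage labels.
#' @export
cell_type_labels <- function() {
  c("Tumor", "Myeloid", "Lymphoid", "Endothelial", "Other")
}

#' Assign lineage labels by hierarchical marker gating
#'
#' Fits a [gmm_gate()] per rule marker and assigns each cell the label of
#' the first rule whose markers are all gated positive; cells matching no
#' rule become `"Other"`. Gates are fitted per sample (CyCIF intensity
#' scales vary by slide), so samples are gated independently and labels
#' concatenated.
#'
#' @param table a [cell_table()].
#' @param rules ordered rule list, as from [default_typing_rules()]. A rule
#'   may carry `fallback_markers` used when one of its `markers` is absent
#'   from the panel; otherwise a missing rule marker is an error.
#' @param seed integer seed for the gate fits.
#' @param min_separation passed to [gmm_gate()].
#' @return object of class `cell_type_call`: list with `label` (character
#'   per cell, levels [cell_type_labels()]), `posterior` (per-cell product
#'   of contributing gate posteriors; 1 - max rule posterior for Other
#'   cells has no meaning, so Other cells carry NA), and `gates` (per
#'   sample, per marker `gate_result`).
#' @export
assign_cell_types <- function(table, rules = default_typing_rules(),
                              seed = 1L, min_separation = 0.5) {
  rules <- lapply(rules, function(r) {
    have <- all(r$markers %in% table$marker_cols)
    if (!have && !is.null(r$fallback_markers) &&
        all(r$fallback_markers %in% table$marker_cols)) {
      r$markers <- r$fallback_markers
    } else if (!have) {
      stop("assign_cell_types: rule marker missing from panel: ",
           paste(setdiff(r$markers, table$marker_cols), collapse = ", "))
    }
    r
  })
  need <- unique(unlist(lapply(rules, `[[`, "markers")))
  n <- n_cells(table)
  label <- rep("Other", n)
  posterior <- rep(NA_real_, n)
  gates <- list()
  for (sid in unique(table$data$sample_id)) {
    rows <- which(table$data$sample_id == sid)
    sample_gates <- list()
    for (mk in need) {
      sample_gates[[mk]] <- gmm_gate(table$data[[mk]][rows], seed = seed,
                                     min_separation = min_separation,
                                     marker = mk)
    }
    assigned <- rep(FALSE, length(rows))
    for (r in rules) {
      pos <- rep(TRUE, length(rows))
      post <- rep(1, length(rows))
      for (mk in r$markers) {
        pos <- pos & sample_gates[[mk]]$positive
        post <- post * sample_gates[[mk]]$posterior
      }
      take <- pos & !assigned
      label[rows[take]] <- r$label
      posterior[rows[take]] <- post[take]
      assigned <- assigned | pos
    }
    gates[[sid]] <- sample_gates
  }
  structure(list(label = label, posterior = posterior, gates = gates),
            class = "cell_type_call")
}

#' @export
print.cell_type_call <- function(x, ...) {
  tab <- table(factor(x$label, levels = cell_type_labels()))
  cat("cell_type_call:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
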