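#' Spatial cross-correlation query
#'
#' Describes one spatial correlation function: the Pearson correlation
#' between variable U on cells of type A and variable V on each A-cell's
#' k-th nearest neighbor of type B, evaluated for k = 1..kmax and indexed by
#' the mean pair distance in micrometers.
#'
#' Types may be any assigned label, `"All"`, or a complement such as
#' `"non-Tumor"`. Variables are either a marker name (used as
#' `log(intensity + 1)`) or a cell-type name (used as a binary indicator of
#' that type).
#'
#' @param type_a,type_b cell-type selectors for the focal (A) and neighbor
#'   (B) populations.
#' @param var_u,var_v variable on A cells / B neighbors: marker name or
#'   type label.
#' @param kmax maximum neighbor order (default 200).
#' @param min_pairs minimum pair count for a defined correlation (default 30).
#' @return object of class `correlation_query`.
#' @export
correlation_query <- function(type_a, type_b, var_u, var_v,
                              kmax = 200L, min_pairs = 30L) {
  stopifnot(kmax >= 1L, min_pairs >= 2L)
  structure(list(type_a = type_a, type_b = type_b, var_u = var_u,
                 var_v = var_v, kmax = as.integer(kmax),
                 min_pairs = as.integer(min_pairs)),
            class = "correlation_query")
}

resolve_type_set <- function(labels, type) {
  if (identical(type, "All")) return(rep(TRUE, length(labels)))
  if (grepl("^non-", type)) return(labels != sub("^non-", "", type))
  labels == type
}

typed_labels <- function(typed) {
  if (inherits(typed, "cell_type_call")) typed$label else as.character(typed)
}

# Variable values for every cell: log1p(marker) or binary type indicator.
resolve_variable <- function(table, labels, var) {
  if (var %in% table$marker_cols) {
    log1p(table$data[[var]])
  } else {
    as.numeric(resolve_type_set(labels, var))
  }
}

#' k-nearest neighbors of a given type
#'
#' For every cell of type A, finds its 1st..kmax-th nearest neighbors of
#' type B by Euclidean distance in micrometers. The focal cell is excluded
#' from its own neighbor list (relevant when A and B overlap); exact
#' distance ties are broken by ascending `cell_id`. When fewer than k
#' type-B neighbors exist, that order is marked unavailable (NA).
#'
#' @param table a [cell_table()].
#' @param typed a `cell_type_call` or plain character label vector.
#' @param type_a,type_b type selectors (see [correlation_query()]).
#' @param kmax highest neighbor order to return.
#' @return list with `a_rows` (row indices of A cells in `table$data`),
#'   `nn_row` (n_A x kmax matrix of neighbor row indices, NA when
#'   unavailable), `nn_dist` (matching distances, um).
#' @export
knn_of_type <- function(table, typed, type_a, type_b, kmax) {
  labels <- typed_labels(typed)
  stopifnot(length(labels) == n_cells(table))
  a_rows <- which(resolve_type_set(labels, type_a))
  b_rows <- which(resolve_type_set(labels, type_b))
  nA <- length(a_rows)
  nB <- length(b_rows)
  nn_row <- matrix(NA_integer_, nrow = nA, ncol = kmax)
  nn_dist <- matrix(NA_real_, nrow = nA, ncol = kmax)
  if (nA == 0L || nB == 0L) {
    return(list(a_rows = a_rows, nn_row = nn_row, nn_dist = nn_dist))
  }
  x <- table$data$x_um
  y <- table$data$y_um
  ids_b <- table$data$cell_id[b_rows]
  bx <- x[b_rows]; by <- y[b_rows]
  b_sq <- bx^2 + by^2
  chunk <- max(1L, floor(4e6 / nB))
  for (start in seq(1L, nA, by = chunk)) {
    rows <- start:min(start + chunk - 1L, nA)
    ax <- x[a_rows[rows]]; ay <- y[a_rows[rows]]
    d2 <- outer(ax^2 + ay^2, b_sq, `+`) -
      2 * (outer(ax, bx) + outer(ay, by))
    d2[d2 < 0] <- 0
    for (i in seq_along(rows)) {
      di <- d2[i, ]
      di[b_rows == a_rows[rows[i]]] <- Inf      # exclude the focal cell
      avail <- sum(is.finite(di))
      kk <- min(kmax, avail)
      if (kk == 0L) next
      ord <- order(di, ids_b)[seq_len(kk)]
      nn_row[rows[i], seq_len(kk)] <- b_rows[ord]
      nn_dist[rows[i], seq_len(kk)] <- sqrt(di[ord])
    }
  }
  list(a_rows = a_rows, nn_row = nn_row, nn_dist = nn_dist)
}

#' Spatial correlation curve over neighbor orders
#'
#' Evaluates, for each k = 1..kmax, the Pearson correlation between U on
#' type-A cells and V on their k-th nearest type-B neighbors, together with
#' the mean pair distance in micrometers. Orders with fewer than
#' `min_pairs` available pairs, or with zero variance in U or V, are
#' reported as undefined (NA) and are excluded from curve fitting.
#'
#' @param table a [cell_table()].
#' @param typed a `cell_type_call` or label vector.
#' @param query a [correlation_query()].
#' @param keep_pairs attach the per-pair values (U per A cell, V and
#'   distance per neighbor order) to the curve, enabling the anchor-cell
#'   bootstrap in [fit_exponential()] (default TRUE).
#' @return data.frame of class `correlation_curve` with columns `k`,
#'   `mean_distance_um`, `pearson_r`, `n_pairs`; the query, the sampling
#'   window area, and (optionally) the pair data are attached as
#'   attributes.
#' @export
correlation_curve <- function(table, typed, query, keep_pairs = TRUE) {
  labels <- typed_labels(typed)
  for (v in c(query$var_u, query$var_v)) {
    if (!v %in% table$marker_cols && !v %in% labels &&
        !identical(v, "All") && !grepl("^non-", v)) {
      stop("correlation_curve: variable not a marker or type label: ", v)
    }
  }
  U_all <- resolve_variable(table, labels, query$var_u)
  V_all <- resolve_variable(table, labels, query$var_v)
  nn <- knn_of_type(table, typed, query$type_a, query$type_b, query$kmax)
  u <- U_all[nn$a_rows]
  out <- data.frame(k = seq_len(query$kmax),
                    mean_distance_um = NA_real_,
                    pearson_r = NA_real_,
                    n_pairs = 0L)
  for (k in seq_len(query$kmax)) {
    valid <- !is.na(nn$nn_row[, k])
    np <- sum(valid)
    out$n_pairs[k] <- np
    if (np == 0L) next
    out$mean_distance_um[k] <- mean(nn$nn_dist[valid, k])
    if (np < query$min_pairs) next
    uk <- u[valid]
    vk <- V_all[nn$nn_row[valid, k]]
    if (stats::sd(uk) == 0 || stats::sd(vk) == 0) next
    out$pearson_r[k] <- stats::cor(uk, vk)
  }
  pairs <- NULL
  if (isTRUE(keep_pairs)) {
    v_mat <- matrix(V_all[nn$nn_row], nrow = length(u))
    # field support for the parametric bootstrap: coordinates of every
    # cell carrying U or V, with index maps from A cells and neighbor
    # slots into those rows
    field_rows <- sort(unique(c(nn$a_rows, nn$nn_row[!is.na(nn$nn_row)])))
    field_pos <- match(seq_len(n_cells(table)), field_rows)
    nn_field <- matrix(field_pos[nn$nn_row], nrow = length(u))
    pairs <- list(
      u = u, v = v_mat, d = nn$nn_dist,
      field_xy = cbind(table$data$x_um[field_rows],
                       table$data$y_um[field_rows]),
      a_field_idx = field_pos[nn$a_rows],
      nn_field_idx = nn_field,
      shared_uv = identical(query$var_u, query$var_v) &&
        identical(query$type_a, query$type_b),
      gaussian_ok = query$var_u %in% table$marker_cols &&
        query$var_v %in% table$marker_cols
    )
  }
  structure(out, query = query,
            window_area_um2 = convex_hull_area(table$data$x_um,
                                               table$data$y_um),
            pairs = pairs,
            class = c("correlation_curve", "data.frame"))
}

convex_hull_area <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  abs(sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)) / 2
}

#' Fit an exponential decay to a spatial correlation curve
#'
#' Nonlinear least squares of `C(d) = c * exp(b * d)` over the curve's
#' defined `(mean_distance_um, pearson_r)` points. `c` is the correlation
#' strength (the fitted zero-distance amplitude, the per-core summary
#' statistic) and `b` the decay rate per micrometer. If the 95% confidence
#' interval for `c` contains 0, `c` is deemed insignificant and
#' `c_effective` is set to 0.
#'
#' The uncertainty of `c` has components that a plain least-squares
#' interval misses: pair-sampling noise is correlated across neighbor
#' orders (consecutive orders reuse the same anchor cells and overlapping
#' neighbor sets), and the latent spatial process behind a real
#' correlation is observed as a single realization whose empirical
#' correlation structure fluctuates around the ensemble value at every
#' scale up to the core diameter. The default `"parametric"` method
#' therefore estimates `SE(c)` by a parametric bootstrap under the fitted
#' model: replicate realizations of a unit-variance exponential-covariance
#' Gaussian field with decay length `-1/b` are drawn at the actual cell
#' positions (one Cholesky factor, reused), mixed into replicate
#' standardized marker values with coupling `c` (clamped to `[0, 1)`), and
#' pushed through the fixed neighbor structure, curve evaluation, and
#' refit. This propagates all variance components under the model. It
#' requires the pair-level data that [correlation_curve()] attaches by
#' default and applies when both variables are markers.
#'
#' Alternatives: `"cell_bootstrap"` resamples anchor cells with their
#' neighbor rows and refits (captures cross-order sampling dependence but
#' not realization variance; an analytic window-scale term
#' `c^2 * pi * ell^2 / A` is added unless `field_variance = FALSE`);
#' `"linearized"` is the plain nls covariance plus the same analytic term,
#' used automatically for curves without pair data; `"point_bootstrap"` is
#' a naive percentile bootstrap over curve points, provided for comparison
#' (it treats points as independent and is anticonservative).
#' `ci_method = "auto"` (default) picks `"parametric"` for marker-marker
#' queries with pair data, `"cell_bootstrap"` for queries involving binary
#' type indicators, and `"linearized"` otherwise.
#'
#' @param curve a [correlation_curve()].
#' @param weighted weight points by `n_pairs` (default unweighted).
#' @param ci_method `"auto"`, `"parametric"`, `"cell_bootstrap"`,
#'   `"linearized"`, or `"point_bootstrap"`.
#' @param field_variance add the analytic realization-variance component
#'   to `"linearized"` / `"cell_bootstrap"` intervals (default TRUE;
#'   ignored for `"parametric"`, which already contains it).
#' @param n_boot bootstrap replicates (default 200; the parametric method
#'   uses `min(n_boot, 100)` field replicates, enough to estimate an SE).
#' @param seed seed for bootstrap resampling.
#' @return object of class `exponential_fit`: list with `c`, `b`, `se_c`,
#'   `ci_c_95`, `significant`, `c_effective`, `converged`, `rss`,
#'   `n_points`.
#' @export
fit_exponential <- function(curve, weighted = FALSE,
                            ci_method = c("auto", "parametric",
                                          "cell_bootstrap", "linearized",
                                          "point_bootstrap"),
                            field_variance = TRUE,
                            n_boot = 200L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  pairs <- attr(curve, "pairs")
  if (ci_method == "auto") {
    ci_method <- if (is.null(pairs)) {
      "linearized"
    } else if (isTRUE(pairs$gaussian_ok)) {
      "parametric"
    } else {
      "cell_bootstrap"
    }
  }
  if (ci_method %in% c("parametric", "cell_bootstrap") && is.null(pairs)) {
    stop("fit_exponential: ", ci_method, " needs a curve with pair data ",
         "(correlation_curve(..., keep_pairs = TRUE))")
  }
  defined <- !is.na(curve$pearson_r) & !is.na(curve$mean_distance_um)
  pts <- curve[defined, , drop = FALSE]
  if (nrow(pts) < 3L) stop("fit_exponential: need >= 3 defined curve points")
  d <- pts$mean_distance_um
  r <- pts$pearson_r
  w <- if (weighted) pts$n_pairs else rep(1, nrow(pts))

  if (stats::sd(r) == 0) {       # constant curve: c = r, no decay
    cc <- r[1L]
    return(new_exponential_fit(c = cc, b = 0, se_c = 0,
                               ci = c(cc, cc), converged = TRUE, rss = 0,
                               n_points = nrow(pts)))
  }

  fit <- fit_exp_nls(d, r, w)
  if (is.null(fit)) {
    return(new_exponential_fit(c = NA_real_, b = NA_real_, se_c = NA_real_,
                               ci = c(NA_real_, NA_real_), converged = FALSE,
                               rss = NA_real_, n_points = nrow(pts)))
  }
  est <- stats::coef(fit)
  if (est[["bb"]] > 0) {
    warning("fit_exponential: fitted decay rate b is positive")
  }
  area <- attr(curve, "window_area_um2")
  var_field <- 0
  if (isTRUE(field_variance) && !is.null(area) && is.finite(area) &&
      est[["bb"]] < 0) {
    ell_hat <- -1 / est[["bb"]]
    var_field <- est[["cc"]]^2 * pi * ell_hat^2 / area
  }

  if (ci_method == "linearized") {
    se_fit <- tryCatch(summary(fit)$coefficients["cc", "Std. Error"],
                       error = function(e) NA_real_)
    se_c <- sqrt(se_fit^2 + var_field)
    ci <- est[["cc"]] + c(-1.96, 1.96) * se_c
  } else if (ci_method == "parametric") {
    set.seed(seed)
    boots <- parametric_boot_c(pairs, est, defined, w, min(n_boot, 100L))
    se_c <- stats::sd(boots, na.rm = TRUE)
    ci <- est[["cc"]] + c(-1.96, 1.96) * se_c
  } else if (ci_method == "cell_bootstrap") {
    set.seed(seed)
    n_a <- length(pairs$u)
    boots <- replicate(n_boot, {
      rows <- sample.int(n_a, replace = TRUE)
      refit_curve_rows(pairs, rows, defined, w)
    })
    se_boot <- stats::sd(boots, na.rm = TRUE)
    se_c <- sqrt(se_boot^2 + var_field)
    ci <- est[["cc"]] + c(-1.96, 1.96) * se_c
  } else {                       # point_bootstrap
    set.seed(seed)
    boots <- replicate(n_boot, {
      idx <- sample.int(nrow(pts), replace = TRUE)
      bf <- fit_exp_nls(d[idx], r[idx], w[idx])
      if (is.null(bf)) NA_real_ else stats::coef(bf)[["cc"]]
    })
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    se_c <- stats::sd(boots, na.rm = TRUE)
  }
  new_exponential_fit(c = est[["cc"]], b = est[["bb"]], se_c = se_c,
                      ci = ci, converged = TRUE,
                      rss = sum(stats::residuals(fit)^2),
                      n_points = nrow(pts))
}

# Parametric bootstrap under the fitted model: new realizations of a
# latent exponential-covariance field (decay length -1/b, coupling
# strength c clamped to [0, 1)) are drawn at the actual cell positions,
# standardized marker values are regenerated, and the curve and fit are
# recomputed through the fixed neighbor structure. One Cholesky factor is
# shared by all replicates. Returns the replicate c-hats.
parametric_boot_c <- function(pairs, est, defined, w, n_boot) {
  rho_hat <- min(max(est[["cc"]], 0), 0.99)
  m <- nrow(pairs$field_xy)
  n_a <- length(pairs$u)
  use_field <- rho_hat > 0 && est[["bb"]] < 0
  R <- NULL
  if (use_field) {
    span <- max(diff(range(pairs$field_xy[, 1L])),
                diff(range(pairs$field_xy[, 2L])))
    ell_hat <- min(-1 / est[["bb"]], 10 * span)
    C <- exp(-as.matrix(stats::dist(pairs$field_xy)) / ell_hat)
    diag(C) <- diag(C) + 1e-8
    R <- chol(C)
  }
  dme <- colMeans(pairs$d[, defined, drop = FALSE], na.rm = TRUE)
  nnf <- pairs$nn_field_idx[, defined, drop = FALSE]
  vapply(seq_len(n_boot), function(b) {
    L <- if (use_field) {
      drop(crossprod(R, stats::rnorm(m)))
    } else {
      numeric(m)
    }
    v_field <- sqrt(rho_hat) * L + sqrt(1 - rho_hat) * stats::rnorm(m)
    u_star <- if (pairs$shared_uv) {
      v_field[pairs$a_field_idx]
    } else {
      sqrt(rho_hat) * L[pairs$a_field_idx] +
        sqrt(1 - rho_hat) * stats::rnorm(n_a)
    }
    v_star <- matrix(v_field[nnf], nrow = n_a)
    rb <- suppressWarnings(as.numeric(stats::cor(u_star, v_star,
                                                 use = "pairwise.complete.obs")))
    ok <- is.finite(rb) & is.finite(dme)
    if (sum(ok) < 3L) return(NA_real_)
    bf <- fit_exp_nls(dme[ok], rb[ok], w[ok])
    if (is.null(bf)) NA_real_ else stats::coef(bf)[["cc"]]
  }, 0)
}

# One anchor-cell bootstrap draw: recompute the curve over the resampled
# rows (only at the originally defined orders) and refit; returns c-hat.
refit_curve_rows <- function(pairs, rows, defined, w) {
  uu <- pairs$u[rows]
  if (stats::sd(uu) == 0) return(NA_real_)
  vb <- pairs$v[rows, defined, drop = FALSE]
  db <- pairs$d[rows, defined, drop = FALSE]
  rb <- suppressWarnings(as.numeric(stats::cor(uu, vb,
                                               use = "pairwise.complete.obs")))
  dm <- colMeans(db, na.rm = TRUE)
  ok <- is.finite(rb) & is.finite(dm)
  if (sum(ok) < 3L) return(NA_real_)
  bf <- fit_exp_nls(dm[ok], rb[ok], w[ok])
  if (is.null(bf)) NA_real_ else stats::coef(bf)[["cc"]]
}

fit_exp_nls <- function(d, r, w) {
  c0 <- r[which.min(d)]
  nz <- which(r != 0)
  b0 <- if (length(nz) >= 2L && stats::sd(d[nz]) > 0) {
    slope <- stats::coef(stats::lm(log(abs(r[nz])) ~ d[nz]))[[2L]]
    if (is.finite(slope)) slope else -0.01
  } else {
    -0.01
  }
  if (c0 == 0) c0 <- mean(r)
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      r ~ cc * exp(bb * d),
      start = list(cc = c0, bb = b0),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
}

new_exponential_fit <- function(c, b, se_c, ci, converged, rss, n_points) {
  significant <- converged && all(is.finite(ci)) && (ci[1L] > 0 || ci[2L] < 0)
  structure(
    list(c = c, b = b, se_c = se_c, ci_c_95 = ci,
         significant = significant,
         c_effective = if (significant) c else 0,
         converged = converged, rss = rss, n_points = n_points),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "exponential_fit: c = %.4g [%.4g, %.4g], b = %.4g /um, %s (%d points)\n",
    x$c, x$ci_c_95[1L], x$ci_c_95[2L], x$b,
    if (x$significant) "significant" else "not significant", x$n_points
  ))
  invisible(x)
}

#' Fit the spatial correlation per core
#'
#' Splits a multi-core table by `core_id`, evaluates the correlation curve
#' and exponential fit on each core, and tabulates the per-core correlation
#' strengths.
#'
#' @param table a [cell_table()] (possibly many cores).
#' @param typed a `cell_type_call` or label vector aligned with `table`.
#' @param query a [correlation_query()].
#' @param ... passed to [fit_exponential()].
#' @return list with `summary` (data.frame: core_id, patient_id, c, b,
#'   significant, c_effective, converged) and `fits` (named list of
#'   `exponential_fit`).
#' @export
fit_cores <- function(table, typed, query, ...) {
  labels <- typed_labels(typed)
  cores <- unique(table$data$core_id)
  fits <- list()
  rows_list <- split(seq_len(n_cells(table)), table$data$core_id)
  summary <- do.call(rbind, lapply(cores, function(co) {
    rows <- rows_list[[co]]
    sub <- subset_cells(table, seq_len(n_cells(table)) %in% rows)
    fit <- fit_exponential(correlation_curve(sub, labels[rows], query), ...)
    fits[[co]] <<- fit
    data.frame(core_id = co, patient_id = table$data$patient_id[rows[1L]],
               c = fit$c, b = fit$b, significant = fit$significant,
               c_effective = fit$c_effective, converged = fit$converged,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, fits = fits)
}

#' Classify per-patient interaction from per-core fits
#'
#' A patient is classified `"high"` interaction when every one of their
#' cores has a significant correlation strength `c`, and `"low"` otherwise.
#'
#' @param core_summary data.frame with columns `patient_id` and
#'   `significant`, one row per core (as from [fit_cores()]`$summary`).
#' @return data.frame of class `interaction_call`: `patient_id`, `n_cores`,
#'   `n_significant`, `class`.
#' @export
interaction_class <- function(core_summary) {
  stopifnot(all(c("patient_id", "significant") %in% names(core_summary)))
  if (nrow(core_summary) == 0L) stop("interaction_class: no cores")
  agg <- lapply(split(core_summary, core_summary$patient_id), function(d) {
    data.frame(patient_id = d$patient_id[1L], n_cores = nrow(d),
               n_significant = sum(d$significant),
               class = if (all(d$significant)) "high" else "low",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  structure(out, class = c("interaction_call", "data.frame"))
}
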