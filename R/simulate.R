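#' Configuration for the synthetic tissue generator
#'
#' Describes one simulated tissue core: field size, per-type cell densities
#' (homogeneous Poisson or clustered Thomas process), per-type log-normal
#' marker intensity parameters, planted cross-marker spatial couplings, and
#' planted QC defects. The defaults emulate a densely cellular glioma TMA
#' core: a 1 x 1 mm field at ~2500 cells/mm^2 dominated by tumor and myeloid
#' cells, with lineage markers (SOX2, CD45, CD3, PU.1, CD31), functional
#' markers (CD73, CD39, CD163, CD11b, PD-L1, HIF1a), one autofluorescence
#' channel, and a Tumor-CD73 x Myeloid-CD39 coupling of strength 0.6 decaying
#' over 50 um.
#'
#' @param field_size_um numeric length-2, field width and height in um.
#' @param densities named numeric, cells per mm^2 for each cell type.
#' @param process `"poisson"` or `"thomas"`; the Thomas process places
#'   Poisson-distributed parents and Gaussian-scattered offspring.
#' @param thomas list with `parents_per_mm2`, `mean_offspring`,
#'   `cluster_sd_um` (used when `process = "thomas"`; densities are then
#'   interpreted as target mean densities and set the per-type parent rates).
#' @param marker_log_mean numeric matrix, rows = cell types, columns =
#'   markers: natural-log mean intensity of each marker in each type.
#' @param marker_log_sd named numeric, natural-log sd per marker.
#' @param couplings list of [coupling()] specs planting spatial
#'   cross-correlation between markers on two cell types.
#' @param n_cycles number of DNA (nuclear stain) cycles (default 6).
#' @param dna_log_mean,dna_log_sd log-normal parameters of per-cycle DNA
#'   intensity.
#' @param af_marker name of the autofluorescence channel.
#' @param qc_defects list: `lost_frac` fraction of cells losing their nucleus
#'   mid-experiment (DNA set to 0 from a random middle cycle onward, so at
#'   least the second half of the cycles is lost and the DNA CV is
#'   decisively inflated), `af_frac` fraction of highly autofluorescent
#'   cells, `af_log_mean` / `af_log_sd` their AF-channel log-normal
#'   parameters.
#' @param sample_id,core_id,patient_id identifiers stamped on every cell.
#' @param seed integer seed; the generator is fully reproducible given the
#'   config.
#' @param exact_field_max above this number of coupled cells the latent
#'   Gaussian field is sampled by a nearest-neighbor (Vecchia) approximation
#'   instead of an exact Cholesky draw.
#' @return list of class `tissue_sim_config`.
#' @export
tissue_sim_config <- function(field_size_um = c(1000, 1000),
                              densities = c(Tumor = 1200, Myeloid = 700,
                                            Lymphoid = 120, Endothelial = 120,
                                            Other = 360),
                              process = c("poisson", "thomas"),
                              thomas = list(parents_per_mm2 = 30,
                                            mean_offspring = NULL,
                                            cluster_sd_um = 60),
                              marker_log_mean = NULL,
                              marker_log_sd = NULL,
                              couplings = list(
                                coupling("Tumor", "CD73", "Myeloid", "CD39",
                                         rho = 0.6, ell_um = 50)
                              ),
                              n_cycles = 6,
                              dna_log_mean = 7, dna_log_sd = 0.15,
                              af_marker = "AF1",
                              qc_defects = list(lost_frac = 0.02,
                                                af_frac = 0.05,
                                                af_log_mean = 4,
                                                af_log_sd = 0.2),
                              sample_id = "sample1", core_id = "core1",
                              patient_id = "patient1",
                              seed = 1L,
                              exact_field_max = 5000L) {
  process <- match.arg(process)
  types <- names(densities)
  if (is.null(types) || any(densities <= 0)) {
    stop("tissue_sim_config: densities must be named and positive")
  }
  if (is.null(marker_log_mean)) {
    marker_log_mean <- default_marker_log_mean(types, af_marker)
  }
  markers <- colnames(marker_log_mean)
  if (is.null(marker_log_sd)) {
    marker_log_sd <- stats::setNames(rep(0.3, length(markers)), markers)
    if (af_marker %in% markers) marker_log_sd[af_marker] <- 0.2
  }
  for (cp in couplings) {
    if (cp$rho < 0 || cp$rho > 1) {
      stop("tissue_sim_config: coupling rho must lie in [0, 1]")
    }
    if (cp$ell_um <= 0) stop("tissue_sim_config: coupling ell_um must be > 0")
    for (ty in c(cp$type_a, cp$type_b)) {
      if (!ty %in% types) stop("tissue_sim_config: unknown coupled type ", ty)
    }
    for (mk in c(cp$marker_u, cp$marker_v)) {
      if (!mk %in% markers) stop("tissue_sim_config: unknown coupled marker ", mk)
    }
  }
  structure(
    list(field_size_um = field_size_um, densities = densities,
         process = process, thomas = thomas,
         marker_log_mean = marker_log_mean, marker_log_sd = marker_log_sd,
         couplings = couplings, n_cycles = n_cycles,
         dna_log_mean = dna_log_mean, dna_log_sd = dna_log_sd,
         af_marker = af_marker, qc_defects = qc_defects,
         sample_id = sample_id, core_id = core_id, patient_id = patient_id,
         seed = as.integer(seed), exact_field_max = exact_field_max),
    class = "tissue_sim_config"
  )
}

#' Planted spatial coupling between two markers on two cell types
#'
#' Declares that marker `marker_u` on cells of `type_a` and marker `marker_v`
#' on cells of `type_b` share a latent Gaussian field, so that the
#' correlation of their log intensities at inter-cell distance `d` is
#' `rho * exp(-d / ell_um)` in expectation: `rho` is the zero-distance
#' correlation strength and `ell_um` the decay length in micrometers.
#'
#' @param type_a,marker_u variable U: a marker on type-A cells.
#' @param type_b,marker_v variable V: a marker on type-B cells.
#' @param rho target correlation at zero distance, in \[0, 1\].
#' @param ell_um correlation length in micrometers (> 0).
#' @return coupling spec list.
#' @export
coupling <- function(type_a, marker_u, type_b, marker_v, rho, ell_um) {
  list(type_a = type_a, marker_u = marker_u, type_b = type_b,
       marker_v = marker_v, rho = rho, ell_um = ell_um)
}

default_marker_log_mean <- function(types, af_marker = "AF1") {
  markers <- c("SOX2", "CD45", "CD3", "PU.1", "CD31", "CD73", "CD39",
               "CD163", "CD11b", "PD-L1", "HIF1a", af_marker)
  m <- matrix(0.5, nrow = length(types), ncol = length(markers),
              dimnames = list(types, markers))
  hi <- function(type, marker, value = 3) {
    if (type %in% types) m[type, marker] <<- value
  }
  hi("Tumor", "SOX2"); hi("Tumor", "CD73")
  hi("Tumor", "HIF1a", 2); hi("Tumor", "PD-L1", 1.5)
  hi("Myeloid", "CD45"); hi("Myeloid", "PU.1"); hi("Myeloid", "CD39")
  hi("Myeloid", "CD163", 2.5); hi("Myeloid", "CD11b", 2.5)
  hi("Lymphoid", "CD45"); hi("Lymphoid", "CD3")
  hi("Endothelial", "CD31"); hi("Endothelial", "CD39", 2.5)
  m[, af_marker] <- 1
  m
}

#' Simulate a tissue core with known ground truth
#'
#' Draws cell positions from the configured point processes, assigns
#' log-normal marker intensities per cell type, plants the configured
#' cross-marker spatial couplings through a shared exponential-covariance
#' latent Gaussian field, plants QC defects, and returns both the emitted
#' [cell_table()] and a ground-truth record aligned 1:1 with its rows.
#'
#' For each coupling, a zero-mean unit-variance field `L` with covariance
#' `exp(-d/ell)` is sampled at the coupled cells' positions (exact Cholesky
#' draw up to `exact_field_max` cells, nearest-neighbor Gaussian-process
#' approximation beyond) and mixed into the two coupled markers'
#' standardized log intensities as `sqrt(rho) * L + sqrt(1-rho) * noise`.
#'
#' @param config a [tissue_sim_config()].
#' @return list with elements `table` (a `cell_table`) and `truth` (list:
#'   `type` per-cell true label, `latent` matrix of latent field values per
#'   coupling (NA for uncoupled cells), `c_true` / `b_true` the planted
#'   amplitude `rho` and decay rate `-1/ell_um` per coupling, `lost_idx` /
#'   `af_idx` row indices of planted QC defects).
#' @export
simulate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_sim_config"))
  set.seed(config$seed)
  fw <- config$field_size_um[1L]
  fh <- config$field_size_um[2L]
  area_mm2 <- fw * fh / 1e6

  pos <- simulate_positions(config, fw, fh, area_mm2)
  type <- pos$type
  n <- length(type)
  markers <- colnames(config$marker_log_mean)

  # standardized log-intensity residuals, one column per marker
  z <- matrix(stats::rnorm(n * length(markers)), nrow = n,
              dimnames = list(NULL, markers))

  latent <- matrix(NA_real_, nrow = n, ncol = length(config$couplings))
  cp_names <- vapply(config$couplings, function(cp) {
    paste0(cp$type_a, ".", cp$marker_u, "_x_", cp$type_b, ".", cp$marker_v)
  }, "")
  colnames(latent) <- cp_names
  for (j in seq_along(config$couplings)) {
    cp <- config$couplings[[j]]
    for (ty in unique(c(cp$type_a, cp$type_b))) {
      if (config$densities[[ty]] * area_mm2 < 10) {
        warning("simulate_tissue: expected fewer than 10 cells of coupled type ",
                ty, "; field may be too small")
      }
    }
    idx <- which(type %in% c(cp$type_a, cp$type_b))
    if (length(idx) == 0L) next
    L <- sample_exponential_field(pos$x[idx], pos$y[idx], cp$ell_um,
                                  config$exact_field_max)
    latent[idx, j] <- L
    mix <- function(rows, marker) {
      z[rows, marker] <<- sqrt(cp$rho) * latent[rows, j] +
        sqrt(1 - cp$rho) * stats::rnorm(length(rows))
    }
    a_rows <- which(type == cp$type_a)
    b_rows <- which(type == cp$type_b)
    if (cp$type_a == cp$type_b && cp$marker_u == cp$marker_v) {
      mix(a_rows, cp$marker_u)        # one variable coupled with itself
    } else {
      mix(a_rows, cp$marker_u)
      mix(b_rows, cp$marker_v)
    }
  }

  log_int <- config$marker_log_mean[type, , drop = FALSE] +
    sweep(z, 2L, config$marker_log_sd[markers], `*`)
  intensity <- exp(log_int)

  dna <- matrix(
    exp(stats::rnorm(n * config$n_cycles, config$dna_log_mean,
                     config$dna_log_sd)),
    nrow = n
  )
  colnames(dna) <- paste0("DNA", seq_len(config$n_cycles))

  # planted QC defects: disjoint lost-nucleus and high-AF cell sets
  qd <- config$qc_defects
  n_lost <- round(qd$lost_frac * n)
  n_af <- round(qd$af_frac * n)
  shuffled <- sample.int(n)
  lost_idx <- sort(shuffled[seq_len(n_lost)])
  af_idx <- sort(shuffled[n_lost + seq_len(n_af)])
  if (n_lost > 0 && config$n_cycles >= 2) {
    # a "lost" nucleus detaches around the middle of the run and is gone
    # for the remainder: all cycles from a random middle cycle are zeroed
    lo <- max(2L, config$n_cycles %/% 2L)
    hi <- min(config$n_cycles, lo + 1L)
    start <- if (lo == hi) rep(lo, n_lost) else {
      sample(lo:hi, n_lost, replace = TRUE)
    }
    for (i in seq_len(n_lost)) {
      dna[lost_idx[i], start[i]:config$n_cycles] <- 0
    }
  }
  if (n_af > 0 && config$af_marker %in% markers) {
    intensity[af_idx, config$af_marker] <-
      exp(stats::rnorm(n_af, qd$af_log_mean, qd$af_log_sd))
  }

  d <- data.frame(
    cell_id = sprintf("c%06d", seq_len(n)),
    sample_id = config$sample_id, core_id = config$core_id,
    patient_id = config$patient_id,
    x_um = pos$x, y_um = pos$y,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (k in seq_len(config$n_cycles)) d[[colnames(dna)[k]]] <- dna[, k]
  for (mk in markers) d[[mk]] <- intensity[, mk]

  tab <- cell_table(d, marker_cols = markers, dna_cols = colnames(dna))
  truth <- list(
    type = type,
    latent = latent,
    c_true = vapply(config$couplings, function(cp) cp$rho, 0),
    b_true = vapply(config$couplings, function(cp) -1 / cp$ell_um, 0),
    lost_idx = lost_idx,
    af_idx = af_idx,
    couplings = cp_names
  )
  list(table = tab, truth = truth)
}

simulate_positions <- function(config, fw, fh, area_mm2) {
  xs <- ys <- numeric(0)
  type <- character(0)
  for (ty in names(config$densities)) {
    if (config$process == "poisson") {
      n_ty <- stats::rpois(1L, config$densities[[ty]] * area_mm2)
      x <- stats::runif(n_ty, 0, fw)
      y <- stats::runif(n_ty, 0, fh)
    } else {
      th <- config$thomas
      n_par <- stats::rpois(1L, th$parents_per_mm2 * area_mm2)
      mean_off <- if (is.null(th$mean_offspring)) {
        config$densities[[ty]] / th$parents_per_mm2
      } else {
        th$mean_offspring
      }
      n_off <- stats::rpois(n_par, mean_off)
      px <- rep(stats::runif(n_par, 0, fw), n_off)
      py <- rep(stats::runif(n_par, 0, fh), n_off)
      n_ty <- sum(n_off)
      # torus wrap keeps the realized density equal to the target
      x <- (px + stats::rnorm(n_ty, 0, th$cluster_sd_um)) %% fw
      y <- (py + stats::rnorm(n_ty, 0, th$cluster_sd_um)) %% fh
    }
    xs <- c(xs, x); ys <- c(ys, y)
    type <- c(type, rep(ty, n_ty))
  }
  list(x = xs, y = ys, type = type)
}

# Draw a zero-mean unit-variance Gaussian field with covariance exp(-d/ell)
# at the given points: exact Cholesky up to exact_field_max points, then a
# sequential nearest-neighbor (Vecchia, m = 30) approximation.
sample_exponential_field <- function(x, y, ell_um, exact_field_max = 5000L) {
  n <- length(x)
  if (n == 1L) return(stats::rnorm(1L))
  if (n <= exact_field_max) {
    D <- as.matrix(stats::dist(cbind(x, y)))
    C <- exp(-D / ell_um)
    diag(C) <- diag(C) + 1e-8
    return(drop(crossprod(chol(C), stats::rnorm(n))))
  }
  m <- 30L
  ord <- order(x + y)
  xo <- x[ord]; yo <- y[ord]
  L <- numeric(n)
  L[1L] <- stats::rnorm(1L)
  z <- stats::rnorm(n - 1L)
  for (i in 2:n) {
    prev <- seq_len(i - 1L)
    d2 <- (xo[prev] - xo[i])^2 + (yo[prev] - yo[i])^2
    nb <- prev[order(d2)[seq_len(min(m, i - 1L))]]
    Cnn <- exp(-as.matrix(stats::dist(cbind(xo[nb], yo[nb]))) / ell_um)
    diag(Cnn) <- diag(Cnn) + 1e-8
    cni <- exp(-sqrt(d2[nb]) / ell_um)
    w <- solve(Cnn, cni)
    mu <- sum(w * L[nb])
    v <- max(1 - sum(w * cni), 1e-10)
    L[i] <- mu + sqrt(v) * z[i - 1L]
  }
  out <- numeric(n)
  out[ord] <- L
  out
}

#' Simulate a group-structured bulk expression matrix
#'
#' Generates a log-scale expression matrix over the union of the signature
#' genes plus background genes, with a "high" group in which every signature
#' gene is shifted upward by `effect` log units. Used to exercise signature
#' scoring and the quartile-stratified group comparison with known truth.
#'
#' @param n_samples total number of samples (>= 4, split evenly into `high`
#'   and `low` groups).
#' @param signatures a [signature_set()].
#' @param effect scalar or per-signature named numeric: log-scale shift of
#'   signature genes in the high group (a gene in several signatures gets
#'   the largest applicable shift).
#' @param noise_sd per-value Gaussian noise sd on the log scale.
#' @param n_background number of unshifted background genes.
#' @param baseline_range range of per-gene baseline means (log scale).
#' @param seed integer seed.
#' @return an `expr_matrix` with a `group` annotation column; value scale
#'   `"log2(TPM/10+1)"`.
#' @export
simulate_bulk <- function(n_samples, signatures, effect = 1, noise_sd = 0.5,
                          n_background = 100, baseline_range = c(1, 5),
                          seed = 1L) {
  stopifnot(inherits(signatures, "signature_set"))
  if (n_samples < 4L || n_samples %% 2L != 0L) {
    stop("simulate_bulk: n_samples must be an even number >= 4")
  }
  set.seed(seed)
  if (length(effect) == 1L && is.null(names(effect))) {
    effect <- stats::setNames(rep(effect, length(signatures)),
                              names(signatures))
  }
  miss <- setdiff(names(signatures), names(effect))
  if (length(miss) > 0L) stop("simulate_bulk: no effect given for ", miss[1L])
  sig_genes <- unique(unlist(signatures))
  genes <- c(sig_genes, sprintf("BG%04d", seq_len(n_background)))
  shift <- stats::setNames(rep(0, length(genes)), genes)
  for (s in names(signatures)) {
    g <- unclass(signatures)[[s]]
    shift[g] <- pmax(shift[g], effect[[s]])
  }
  group <- rep(c("high", "low"), each = n_samples / 2L)
  mu <- stats::runif(length(genes), baseline_range[1L], baseline_range[2L])
  vals <- matrix(mu, nrow = length(genes), ncol = n_samples) +
    outer(shift, as.numeric(group == "high")) +
    matrix(stats::rnorm(length(genes) * n_samples, 0, noise_sd),
           nrow = length(genes))
  vals <- pmax(vals, 0)
  rownames(vals) <- genes
  colnames(vals) <- sprintf("s%03d", seq_len(n_samples))
  expression_matrix(
    vals,
    annotations = data.frame(obs_id = colnames(vals), group = group,
                             stringsAsFactors = FALSE),
    value_scale = "log2(TPM/10+1)"
  )
}
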