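# Small in-code fixtures shared across test files.

# Minimal hand-built table: n cells on given coordinates, one marker and
# two DNA cycles unless overridden.
tiny_table <- function(x, y, markers = list(M1 = rep(1, length(x))),
                       dna = NULL, ids = NULL, sample_id = "s1",
                       core_id = "c1", patient_id = "p1") {
  n <- length(x)
  if (is.null(dna)) dna <- list(DNA1 = rep(10, n), DNA2 = rep(10, n))
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_len(n))
  d <- data.frame(cell_id = ids, sample_id = sample_id, core_id = core_id,
                  patient_id = patient_id, x_um = x, y_um = y,
                  check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(dna)) d[[nm]] <- dna[[nm]]
  for (nm in names(markers)) d[[nm]] <- markers[[nm]]
  cell_table(d, marker_cols = names(markers), dna_cols = names(dna))
}

# Random scattered table with random type labels, for oracle comparisons.
random_typed_table <- function(n, seed, types = c("A", "B"),
                               field = 300) {
  set.seed(seed)
  tab <- tiny_table(
    x = runif(n, 0, field), y = runif(n, 0, field),
    markers = list(M1 = rexp(n, 0.1), M2 = rexp(n, 0.1))
  )
  labels <- sample(types, n, replace = TRUE)
  list(table = tab, labels = labels)
}

# Exhaustive O(n^2) oracle for k-th nearest neighbors of a type, with the
# same ascending-cell_id tie-break contract as knn_of_type.
brute_knn <- function(table, labels, type_a, type_b, kmax) {
  a_rows <- which(tmecorr:::resolve_type_set(labels, type_a))
  b_rows <- which(tmecorr:::resolve_type_set(labels, type_b))
  x <- table$data$x_um; y <- table$data$y_um
  ids <- table$data$cell_id
  nn_row <- matrix(NA_integer_, length(a_rows), kmax)
  nn_dist <- matrix(NA_real_, length(a_rows), kmax)
  for (i in seq_along(a_rows)) {
    a <- a_rows[i]
    cand <- setdiff(b_rows, a)
    if (length(cand) == 0L) next
    d <- sqrt((x[cand] - x[a])^2 + (y[cand] - y[a])^2)
    ord <- order(d, ids[cand])
    kk <- min(kmax, length(cand))
    nn_row[i, seq_len(kk)] <- cand[ord[seq_len(kk)]]
    nn_dist[i, seq_len(kk)] <- d[ord[seq_len(kk)]]
  }
  list(a_rows = a_rows, nn_row = nn_row, nn_dist = nn_dist)
}

# Oracle correlation curve built directly on brute_knn output.
brute_curve <- function(table, labels, query) {
  U <- tmecorr:::resolve_variable(table, labels, query$var_u)
  V <- tmecorr:::resolve_variable(table, labels, query$var_v)
  nn <- brute_knn(table, labels, query$type_a, query$type_b, query$kmax)
  u <- U[nn$a_rows]
  out <- data.frame(k = seq_len(query$kmax), mean_distance_um = NA_real_,
                    pearson_r = NA_real_, n_pairs = 0L)
  for (k in seq_len(query$kmax)) {
    ok <- !is.na(nn$nn_row[, k])
    out$n_pairs[k] <- sum(ok)
    if (!any(ok)) next
    out$mean_distance_um[k] <- mean(nn$nn_dist[ok, k])
    if (sum(ok) < query$min_pairs) next
    uk <- u[ok]; vk <- V[nn$nn_row[ok, k]]
    if (sd(uk) == 0 || sd(vk) == 0) next
    out$pearson_r[k] <- cor(uk, vk)
  }
  out
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# A tissue config without QC defects, for spatial-statistics tests.
clean_config <- function(seed, rho = 0.6, ell = 50, ...) {
  tissue_sim_config(
    seed = seed,
    couplings = list(coupling("Tumor", "CD73", "Myeloid", "CD39",
                              rho = rho, ell_um = ell)),
    qc_defects = list(lost_frac = 0, af_frac = 0, af_log_mean = 4,
                      af_log_sd = 0.2),
    ...
  )
}
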