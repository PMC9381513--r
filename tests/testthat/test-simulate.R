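test_that("the generator is reproducible under a fixed seed", {
  cfg <- tissue_sim_config(seed = 101, field_size_um = c(400, 400))
  s1 <- simulate_tissue(cfg)
  s2 <- simulate_tissue(cfg)
  expect_identical(s1$table$data, s2$table$data)
  expect_identical(s1$truth$latent, s2$truth$latent)
  s3 <- simulate_tissue(tissue_sim_config(seed = 102,
                                          field_size_um = c(400, 400)))
  expect_false(identical(s1$table$data, s3$table$data))
})

test_that("ground truth is aligned 1:1 with emitted rows", {
  sim <- simulate_tissue(tissue_sim_config(seed = 103,
                                           field_size_um = c(500, 500)))
  expect_equal(length(sim$truth$type), n_cells(sim$table))
  expect_equal(nrow(sim$truth$latent), n_cells(sim$table))
  # latent defined exactly on coupled types
  coupled <- sim$truth$type %in% c("Tumor", "Myeloid")
  expect_true(all(!is.na(sim$truth$latent[coupled, 1])))
  expect_true(all(is.na(sim$truth$latent[!coupled, 1])))
})

test_that("uncoupled markers show no spatial cross-correlation", {
  rs <- vapply(1:20, function(s) {
    sim <- simulate_tissue(clean_config(s, rho = 0,
                                        field_size_um = c(500, 500)))
    q <- correlation_query("Tumor", "Myeloid", "CD73", "CD39",
                          kmax = 1, min_pairs = 10)
    correlation_curve(sim$table, sim$truth$type, q)$pearson_r[1]
  }, 0)
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("planted coupling reproduces rho*exp(-d/ell) at the first neighbor", {
  sim <- simulate_tissue(clean_config(104, rho = 0.8, ell = 50))
  q <- correlation_query("Tumor", "Myeloid", "CD73", "CD39",
                        kmax = 1, min_pairs = 10)
  cv <- correlation_curve(sim$table, sim$truth$type, q)
  expected <- 0.8 * exp(-cv$mean_distance_um[1] / 50)
  expect_equal(cv$pearson_r[1], expected, tolerance = 0.13)
})

test_that("marker marginals match the configured log-normal parameters", {
  cfg <- clean_config(105, field_size_um = c(1500, 1500))
  sim <- simulate_tissue(cfg)
  sox2 <- sim$table$data$SOX2[sim$truth$type == "Tumor"]
  ks <- ks.test(log(sox2), "pnorm", mean = 3, sd = 0.3)
  expect_gt(ks$p.value, 0.01)
  cd45 <- sim$table$data$CD45[sim$truth$type == "Lymphoid"]
  ks2 <- ks.test(log(cd45), "pnorm", mean = 3, sd = 0.3)
  expect_gt(ks2$p.value, 0.01)
})

test_that("planted QC defects behave as designed", {
  sim <- simulate_tissue(tissue_sim_config(seed = 106))
  dna <- as.matrix(sim$table$data[, sim$table$dna_cols])
  # lost cells have zeros from some cycle >= 2 onward
  expect_true(all(dna[sim$truth$lost_idx, ncol(dna)] == 0))
  expect_true(all(dna[sim$truth$lost_idx, 1] > 0))
  intact <- setdiff(seq_len(n_cells(sim$table)), sim$truth$lost_idx)
  expect_true(all(dna[intact, ] > 0))
  # AF cells are brighter than the background population
  af <- sim$table$data$AF1
  expect_gt(min(af[sim$truth$af_idx]), max(af[-sim$truth$af_idx]) * 0.5)
  expect_gt(mean(log(af[sim$truth$af_idx])), 3)
})

test_that("invalid coupling strength is rejected", {
  expect_error(tissue_sim_config(
    couplings = list(coupling("Tumor", "CD73", "Myeloid", "CD39",
                              rho = 1.2, ell_um = 50))), "rho")
  expect_error(tissue_sim_config(
    couplings = list(coupling("Tumor", "CD73", "Myeloid", "CD39",
                              rho = 0.5, ell_um = -1))), "ell_um")
})

test_that("a field too small for a coupled type warns", {
  cfg <- clean_config(107, field_size_um = c(120, 120),
                      densities = c(Tumor = 1200, Myeloid = 500))
  expect_warning(simulate_tissue(cfg), "fewer than 10")
})

test_that("the Thomas process clusters cells beyond Poisson variance", {
  cfg <- tissue_sim_config(seed = 108, process = "thomas",
                           densities = c(Tumor = 1500),
                           thomas = list(parents_per_mm2 = 20,
                                         mean_offspring = NULL,
                                         cluster_sd_um = 30),
                           couplings = list())
  sim <- simulate_tissue(cfg)
  # quadrat counts: clustered pattern has variance >> mean
  qx <- cut(sim$table$data$x_um, seq(0, 1000, by = 125))
  qy <- cut(sim$table$data$y_um, seq(0, 1000, by = 125))
  counts <- as.vector(table(qx, qy))
  expect_gt(var(counts) / mean(counts), 2)
})

test_that("bulk simulation shifts signature genes in the high group only", {
  sigs <- signature_set(list(S1 = paste0("A", 1:4), S2 = paste0("B", 1:3)))
  ex <- simulate_bulk(20, sigs, effect = c(S1 = 2, S2 = 0), noise_sd = 0.2,
                      seed = 109)
  expect_identical(ex$values, simulate_bulk(20, sigs,
                                            effect = c(S1 = 2, S2 = 0),
                                            noise_sd = 0.2,
                                            seed = 109)$values)
  hi <- ex$annotations$group == "high"
  d1 <- mean(ex$values[paste0("A", 1:4), hi]) -
    mean(ex$values[paste0("A", 1:4), !hi])
  d2 <- mean(ex$values[paste0("B", 1:3), hi]) -
    mean(ex$values[paste0("B", 1:3), !hi])
  dbg <- mean(ex$values[grep("^BG", rownames(ex$values)), hi]) -
    mean(ex$values[grep("^BG", rownames(ex$values)), !hi])
  expect_equal(d1, 2, tolerance = 0.3)
  expect_lt(abs(d2), 0.3)
  expect_lt(abs(dbg), 0.2)
})

test_that("bulk simulation rejects invalid designs", {
  sigs <- signature_set(list(S = "G1"))
  expect_error(simulate_bulk(3, sigs), "even")
  expect_error(simulate_bulk(7, sigs), "even")
})
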