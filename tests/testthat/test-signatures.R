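make_expr <- function(values, groups = NULL) {
  ann <- if (is.null(groups)) NULL else {
    data.frame(obs_id = colnames(values), group = groups,
               stringsAsFactors = FALSE)
  }
  expression_matrix(values, annotations = ann,
                    value_scale = "log2(TPM/10+1)")
}

test_that("detection prevalence matches hand computation", {
  m <- matrix(c(0, 0, 1, 3), nrow = 1,
              dimnames = list("NT5E", paste0("c", 1:4)))
  ex <- make_expr(m, groups = rep("Tumor", 4))
  pv <- detection_prevalence(ex, "group", "NT5E")
  expect_equal(pv$percent_detected, 50)
  expect_equal(pv$mean_expression, 1.0)
  expect_equal(pv$n, 4L)
})

test_that("an undetected gene reports 0% and mean 0", {
  m <- matrix(0, nrow = 2, ncol = 5,
              dimnames = list(c("G1", "G2"), paste0("c", 1:5)))
  ex <- make_expr(m, groups = c("a", "a", "b", "b", "b"))
  pv <- detection_prevalence(ex, "group", "G1")
  expect_equal(pv$percent_detected, c(0, 0))
  expect_equal(pv$mean_expression, c(0, 0))
  expect_equal(sum(pv$n), 5L)
})

test_that("absent gene is an error naming the gene", {
  ex <- make_expr(matrix(1, 1, 2, dimnames = list("G1", c("a", "b"))))
  expect_error(detection_prevalence(ex, "obs_id", "NT5E"), "NT5E")
})

test_that("single-gene signature score is log2(pseudocount + value)", {
  m <- matrix(c(3, 0), nrow = 1, dimnames = list("CD163", c("s1", "s2")))
  ex <- make_expr(m)
  sc <- signature_score(ex, signature_set(list(TAM = "CD163")))
  expect_equal(sc["s1", "TAM"], 2)          # log2(1 + 3)
  expect_equal(sc["s2", "TAM"], 0)          # log2(1 + 0)
})

test_that("doubling expression raises scores by <1 and preserves order", {
  set.seed(51)
  m <- matrix(rexp(60, 0.3), nrow = 6,
              dimnames = list(paste0("G", 1:6), paste0("s", 1:10)))
  sigs <- signature_set(list(sig = paste0("G", 1:6)))
  s1 <- signature_score(make_expr(m), sigs)
  s2 <- signature_score(make_expr(2 * m), sigs)
  expect_true(all(s2 > s1))
  expect_true(all(s2 - s1 < 1))
  expect_equal(order(s1[, 1]), order(s2[, 1]))
})

test_that("missing signature genes are dropped and all-absent is flagged NA", {
  m <- matrix(1:4, nrow = 2, dimnames = list(c("G1", "G2"), c("s1", "s2")))
  ex <- make_expr(m)
  expect_warning(
    sc <- signature_score(ex, signature_set(list(A = c("G1", "ZZZ")))),
    "dropped")
  expect_equal(unname(sc[, "A"]), log2(1 + c(1, 3)))
  suppressWarnings(expect_warning(
    sc2 <- signature_score(ex, signature_set(list(B = "NOPE"))),
    "undefined"))
  expect_true(all(is.na(sc2[, "B"])))
})

test_that("score is invariant to gene order within a signature", {
  set.seed(52)
  m <- matrix(rexp(40), nrow = 4,
              dimnames = list(paste0("G", 1:4), paste0("s", 1:10)))
  ex <- make_expr(m)
  a <- signature_score(ex, signature_set(list(S = paste0("G", 1:4))))
  b <- signature_score(ex, signature_set(list(S = paste0("G", 4:1))))
  expect_equal(a, b)
})

test_that("quartile mode on 168 observations gives groups of 42 and 42", {
  set.seed(53)
  n <- 168
  m <- matrix(rnorm(3 * n, 5), nrow = 3,
              dimnames = list(paste0("G", 1:3), sprintf("s%03d", 1:n)))
  sc <- signature_score(make_expr(abs(m)),
                        signature_set(list(S = paste0("G", 1:3))))
  cmp <- stratify_and_compare(sc, strat_values = rnorm(n))
  expect_equal(cmp$n_high, 42L)
  expect_equal(cmp$n_low, 42L)
})

test_that("double-gene mode compares double-high vs double-low observations", {
  set.seed(54)
  n <- 40
  m <- matrix(rexp(2 * n), nrow = 2,
              dimnames = list(c("G1", "G2"), sprintf("s%02d", 1:n)))
  sc <- signature_score(make_expr(m), signature_set(list(S = c("G1", "G2"))))
  v1 <- rnorm(n); v2 <- rnorm(n)
  cmp <- stratify_and_compare(sc, v1, mode = "double_gene",
                              strat_values2 = v2)
  hi <- sum(v1 > median(v1) & v2 > median(v2))
  lo <- sum(v1 < median(v1) & v2 < median(v2))
  expect_equal(cmp$n_high, hi)
  expect_equal(cmp$n_low, lo)
})

test_that("rank-sum test agrees with exact enumeration for small groups", {
  # exact two-sided p by enumerating all group assignments
  exact_p <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    obs <- sum(r[seq_along(x)])
    combs <- utils::combn(length(pooled), length(x))
    stats <- apply(combs, 2, function(idx) sum(r[idx]))
    mu <- mean(stats)
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(55)
  for (i in 1:5) {
    x <- rnorm(6)
    y <- rnorm(7, 0.5)
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(wt$p.value, exact_p(x, y), tolerance = 1e-10)
  }
})

test_that("permuted group labels keep the test near its nominal level", {
  set.seed(56)
  sigs <- signature_set(list(S1 = paste0("A", 1:5), S2 = paste0("B", 1:5)))
  rejections <- vapply(1:60, function(s) {
    ex <- simulate_bulk(40, sigs, effect = 0, seed = 1000 + s)
    sc <- signature_score(ex, sigs)
    strat <- rnorm(40)
    cmp <- stratify_and_compare(sc, strat)
    cmp$p < 0.05
  }, logical(2))
  expect_lte(mean(rejections), 0.10)
})
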