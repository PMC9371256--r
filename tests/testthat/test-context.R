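test_that("the affinity construction matches a brute-force cosine oracle", {
  set.seed(211)
  m <- matrix(rnorm(25), 5)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  thr <- crossfc:::threshold_rows(m, 0.25)
  k <- ceiling(0.25 * 4)
  oracle_thr <- matrix(0, 5, 5)
  for (i in 1:5) {
    vals <- m[i, -i]
    keep <- setdiff(1:5, i)[order(-vals)][seq_len(k)]
    oracle_thr[i, keep] <- m[i, keep]
  }
  expect_equal(thr, oracle_thr)
  aff <- crossfc:::cosine_affinity(thr)
  for (i in 1:5) for (j in 1:5) {
    cosine <- sum(thr[i, ] * thr[j, ]) /
      sqrt(sum(thr[i, ]^2) * sum(thr[j, ]^2))
    expect_equal(aff[i, j], max(cosine, 0), tolerance = 1e-10)
  }
})

test_that("the principal gradient separates a planted two-block structure", {
  set.seed(212)
  n <- 40
  block <- rep(c(0, 1), each = n / 2)
  fc <- outer(block, block, function(a, b) ifelse(a == b, 0.8, 0.1)) +
    matrix(rnorm(n * n, sd = 0.02), n, n)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 0
  gr <- suppressWarnings(principal_gradient(fc))
  agree <- max(mean((gr$scores > 0) == (block == 1)),
               mean((gr$scores > 0) == (block == 0)))
  expect_equal(agree, 1)
})

test_that("the gradient is permutation equivariant and sign-anchored", {
  inst <- tiny_instance(60, seed = 213)
  gr <- principal_gradient(inst$haemo)
  perm <- sample(60)
  gr_p <- principal_gradient(inst$haemo[perm, perm])
  expect_equal(abs(gr_p$scores), abs(gr$scores[perm]), tolerance = 1e-8)
  anchored <- principal_gradient(inst$haemo, anchor = gr$scores)
  expect_gte(cor(anchored$scores, gr$scores), 0)
})

test_that("structure-function coupling uses only nonzero structural edges", {
  sc <- matrix(0, 6, 6)
  sc[1, 2:5] <- c(1, 2, 3, 4); sc[2:5, 1] <- c(1, 2, 3, 4)
  sc[2, 3] <- sc[3, 2] <- 5
  sc[2, 4] <- sc[4, 2] <- 1
  sc[3, 4] <- sc[4, 3] <- 2
  fc <- matrix(rnorm(36), 6); fc <- (fc + t(fc)) / 2; diag(fc) <- 0
  fc[1, 2:5] <- sc[1, 2:5]^3; fc[2:5, 1] <- sc[2:5, 1]^3  # monotone transform
  out <- suppressWarnings(structure_function_coupling(sc, fc))
  expect_equal(out[1], 1)
  fc[1, 2:5] <- -sc[1, 2:5]; fc[2:5, 1] <- -sc[2:5, 1]
  out2 <- suppressWarnings(structure_function_coupling(sc, fc))
  expect_equal(out2[1], -1)
  # region 6 has no structural connections; oracle for region 2 by hand
  expect_true(is.na(out[6]))
  nz <- which(sc[2, -2] != 0)
  oracle <- cor(sc[2, -2][nz], fc[2, -2][nz], method = "spearman")
  expect_equal(out2[2], oracle)
})

test_that("depth associations reduce to per-depth spin tests with FDR", {
  g <- make_geometry(60, seed = 221)
  map <- smooth_sphere_map(g, 0.5, seed = 222)
  cm <- make_context_maps(g, map, seed = 223)
  spins <- generate_spins(g, 100, seed = 224)
  res <- depth_profile_association(map, cm$depth_profiles, spins)
  expect_length(res$r, 50)
  expect_length(res$p_spin, 50)
  for (d in c(1, 15, 50)) {
    single <- spin_pvalue(map, cm$depth_profiles[, d], spins)
    expect_equal(res$r[d], single$r)
    expect_equal(res$p_spin[d], single$p_spin)
  }
  expect_identical(res$significant, bh_fdr(res$p_spin, 0.05)$reject)
  profiles2 <- cm$depth_profiles
  profiles2[, 7] <- map  # a depth equal to the map itself
  res2 <- depth_profile_association(map, profiles2, spins)
  expect_equal(res2$r[7], 1)
})

test_that("robust sigmoid and unit rescaling follow their formulas", {
  x <- c(0, 5, 10)
  ns <- robust_sigmoid(x)
  iqr_n <- (quantile(x, 0.75) - quantile(x, 0.25)) / 1.349
  expect_equal(ns, unname(1 / (1 + exp(-(x - 5) / iqr_n))), ignore_attr = TRUE)
  expect_equal(ns[2], 0.5)
  set.seed(231)
  z <- rnorm(50)
  expect_true(all(diff(robust_sigmoid(sort(z))) > 0))
  expect_true(all(robust_sigmoid(z) > 0 & robust_sigmoid(z) < 1))
  expect_error(robust_sigmoid(rep(1, 10)), "interquartile")

  expect_equal(unit_rescale(c(2, 4, 8)), c(0, 1 / 3, 1))
  expect_equal(unit_rescale(3 + 2 * z), unit_rescale(z))
  expect_error(unit_rescale(rep(2, 5)), "constant")
})

test_that("differential stability averages donor-pair rank correlations", {
  regions <- paste0("r", 1:10)
  mk <- function(v) matrix(v, 10, 1, dimnames = list(regions, "G1"))
  same <- list(a = mk(1:10), b = mk(1:10))
  class(same) <- "expression_panel"
  expect_equal(differential_stability(same, "G1"), 1)
  rev2 <- list(a = mk(1:10), b = mk(10:1))
  class(rev2) <- "expression_panel"
  expect_equal(differential_stability(rev2, "G1"), -1)
  set.seed(241)
  four <- lapply(1:4, function(k) mk(rnorm(10)))
  names(four) <- paste0("d", 1:4)
  class(four) <- "expression_panel"
  pairs <- utils::combn(4, 2)
  oracle <- mean(apply(pairs, 2, function(pr) {
    cor(four[[pr[1]]][, 1], four[[pr[2]]][, 1], method = "spearman")
  }))
  expect_equal(differential_stability(four, "G1"), oracle)
  expect_error(differential_stability(same, "nope"), "not found")
})

test_that("expression-map association recovers a planted anticorrelation", {
  g <- make_geometry(200, seed = 251)
  anchor <- smooth_sphere_map(g, 0.5, seed = 252)
  cm <- make_context_maps(g, anchor, planted_cor = -0.6, seed = 253)
  spins <- generate_spins(g, 100, seed = 254)
  res <- expression_map_association(anchor, cm$expression, "ANCHOR_GENE", spins)
  expect_gte(res$r, -0.7)
  expect_lte(res$r, -0.5)
  direct <- spin_pvalue(anchor, res$expression, spins)
  expect_equal(res$p_spin, direct$p_spin)
  expect_equal(res$r, direct$r)
  # a map tested against itself as expression
  self <- spin_pvalue(anchor, anchor, spins)
  expect_equal(self$r, 1)
  expect_error(expression_map_association(anchor, cm$expression, "XX", spins),
               "not found")
})
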