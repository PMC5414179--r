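test_that("QC filter drops low-MAF and low-INFO variants with reasons", {
  variants <- data.frame(id = paste0("v", 1:5),
                         maf = c(0.19, 0.005, 0.3, 0.02, 0.4),
                         info = c(0.92, 0.9, 0.48, 0.82, 0.96))
  res <- variant_qc_filter(variants)
  expect_equal(res$retained$id, c("v1", "v4", "v5"))
  expect_equal(res$excluded$reason[res$excluded$id == "v2"], "low_maf")
  expect_equal(res$excluded$reason[res$excluded$id == "v3"], "low_info")
})

test_that("QC filter keeps boundary values and handles empty/absent INFO", {
  empty <- variant_qc_filter(data.frame(id = character(), maf = numeric()))
  expect_equal(nrow(empty$retained), 0)
  expect_equal(nrow(empty$excluded), 0)
  boundary <- variant_qc_filter(data.frame(id = "b", maf = 0.01, info = 0.5))
  expect_equal(boundary$retained$id, "b")
  no_info <- variant_qc_filter(data.frame(id = "x", maf = 0.2,
                                          info = NA_real_))
  expect_equal(no_info$retained$id, "x")
})

test_that("the six-sample worked example gives statistic 4 and p 0.0455", {
  st <- score_test(c(0, 1, 2, 0, 1, 2), c(0, 0, 1, 0, 1, 1))
  expect_equal(st$score_stat, 4, tolerance = 1e-12)
  expect_equal(st$p_value, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(st$p_value, 0.0455, tolerance = 1e-3)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(score_test(rep(1, 6), c(0, 1, 0, 1, 0, 1)), "monomorphic")
  expect_error(score_test(c(0, 1, 2, 0, 1, 2), rep(1, 6)), "degenerate phenotype")
})

test_that("score p agrees with a 20,000-draw permutation p at n=200", {
  n <- 200
  g <- withr::with_seed(21, stats::rbinom(n, 2, 0.3))
  y <- withr::with_seed(22, stats::rbinom(n, 1, 0.5))
  st <- score_test(g, y, alt_fit = FALSE)
  # permutation oracle: with an intercept-only null, V is invariant under
  # permutation of y, so the statistic ranks by U^2 alone
  u_obs <- abs(sum(g * (y - mean(y))))
  n_perm <- 20000
  u_perm <- withr::with_seed(23, vapply(seq_len(n_perm), function(i) {
    abs(sum(g * (sample(y) - mean(y))))
  }, numeric(1)))
  # mid-p convention: U is lattice-valued, so ties at the observed value are
  # split to compare against the continuous chi-square reference
  p_perm <- mean(u_perm > u_obs + 1e-12) + 0.5 * mean(abs(u_perm - u_obs) <= 1e-12)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / n_perm)
  # asymptotic-vs-exact gap is O(1/n); see the matching acceptance check
  expect_lt(abs(st$p_value - p_perm), 3 * mc_sd + 0.005)
})

test_that("the statistic is invariant to affine covariate recoding and label swap", {
  n <- 300
  g <- withr::with_seed(31, stats::rbinom(n, 2, 0.25))
  x <- withr::with_seed(32, stats::rnorm(n))
  y <- withr::with_seed(33, stats::rbinom(n, 1, stats::plogis(0.2 * g + 0.5 * x)))
  a <- score_test(g, y, X = cbind(x))
  b <- score_test(g, y, X = cbind(2 * x + 3))
  expect_equal(a$score_stat, b$score_stat, tolerance = 1e-8)
  flipped <- score_test(g, 1 - y, X = cbind(x))
  expect_equal(flipped$p_value, a$p_value, tolerance = 1e-8)
  expect_equal(flipped$beta, -a$beta, tolerance = 1e-6)
})

region_fixture <- function(seed = 101, n = 1500, or = 1.6) {
  maf <- c(causal = 0.19, p1 = 0.19, p2 = 0.21, p3 = 0.22)
  pool <- make_haplotype_pool(maf, data.frame(i = "causal",
                                              j = c("p1", "p2", "p3"),
                                              r2 = c(0.9, 0.8, 0.7)))
  G <- sample_genotypes(pool, n, seed = seed)
  cc <- simulate_case_control(G, or = c(causal = or), baseline = 0,
                              seed = seed + 1)
  list(G = G, y = cc$phenotype)
}

test_that("an empty conditioning set reproduces per-variant score tests", {
  fx <- region_fixture()
  scan <- association_scan(fx$G, fx$y)
  manual <- vapply(fx$G$variants$id, function(v) {
    score_test(fx$G$genotypes[, v], fx$y)$p_value
  }, numeric(1))
  expect_equal(scan$p_value, unname(manual), tolerance = 1e-12)
})

test_that("conditioning on v equals score_test with v appended to covariates", {
  fx <- region_fixture()
  scan <- association_scan(fx$G, fx$y, condition_on = "causal")
  manual <- score_test(fx$G$genotypes[, "p1"], fx$y,
                       X = fx$G$genotypes[, "causal", drop = FALSE])
  expect_identical(scan$p_value[scan$variant == "p1"], manual$p_value)
  expect_true(is.na(scan$p_value[scan$variant == "causal"]))
  expect_error(association_scan(fx$G, fx$y, condition_on = "ghost"), "ghost")
})

test_that("conditioning on the causal variant collapses proxy signals", {
  fx <- region_fixture(seed = 202, n = 3000, or = 1.8)
  scan <- association_scan(fx$G, fx$y, alt_fit = FALSE)
  cond <- association_scan(fx$G, fx$y, condition_on = "causal",
                           alt_fit = FALSE)
  proxies <- c("p1", "p2", "p3")
  expect_true(all(scan$p_value[scan$variant %in% proxies] < 1e-3))
  expect_true(all(cond$p_value[cond$variant %in% proxies] >
                    scan$p_value[scan$variant %in% proxies]))
})

test_that("correlated_set returns exactly the planted high-LD proxies, by position", {
  maf <- rep(0.25, 12)
  names(maf) <- c("index", sprintf("hi%d", 1:8), sprintf("lo%d", 1:3))
  targets <- data.frame(i = "index",
                        j = names(maf)[-1],
                        r2 = c(0.95, 0.9, 0.85, 0.8, 0.75, 0.7, 0.66, 0.62,
                               0.3, 0.15, 0.05))
  pool <- make_haplotype_pool(maf, targets)
  G <- sample_genotypes(pool, 4000, seed = 55)
  hits <- correlated_set(G, "index", r2_threshold = 0.6)
  expect_setequal(hits, sprintf("hi%d", 1:8))
  expect_equal(hits, hits[order(G$variants$pos[match(hits, G$variants$id)])])
  expect_false("index" %in% correlated_set(G, "index", r2_threshold = 0))
  expect_length(correlated_set(G, "index", r2_threshold = 1), 0)
  expect_error(correlated_set(G, "ghost"), "ghost")
})

test_that("type-I error is nominal at alpha 0.05 under the null (moderate n)", {
  pool <- make_haplotype_pool(c(snp = 0.3))
  pvals <- vapply(seq_len(800), function(i) {
    G <- sample_genotypes(pool, 400, seed = 7000 + i)
    cc <- simulate_case_control(G, baseline = 0, seed = 8000 + i)
    score_test(G$genotypes[, 1], cc$phenotype, alt_fit = FALSE)$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.08)
})
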