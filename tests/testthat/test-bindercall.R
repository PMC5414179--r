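fwd_run <- function(df) { attr(df, "orientation") <- "forward"; df }
rev_run <- function(df) { attr(df, "orientation") <- "reverse"; df }

test_that("log ratios are allele-oriented regardless of label orientation", {
  tab <- data.frame(protein = c("p1", "p2"),
                    intensity_heavy = c(400, 100),
                    intensity_light = c(100, 100))
  fwd <- compute_log_ratios(fwd_run(tab))
  expect_equal(fwd$log2_c_over_g, c(2, 0))
  rev <- compute_log_ratios(rev_run(tab))
  expect_equal(rev$log2_c_over_g, c(-2, 0))
  expect_error(compute_log_ratios(tab, orientation = NULL), "orientation")
})

test_that("both-zero proteins are dropped and logged; single zeros floored", {
  tab <- fwd_run(data.frame(protein = c("gone", "half", "ok"),
                            intensity_heavy = c(0, 0, 200),
                            intensity_light = c(0, 100, 100)))
  lr <- compute_log_ratios(tab)
  expect_equal(lr$protein, c("half", "ok"))
  expect_equal(attr(lr, "dropped")$protein, "gone")
  # zero floored at min positive / 2 = 50
  expect_equal(lr$log2_c_over_g[lr$protein == "half"], log2(50 / 100))
})

test_that("median-centering is shift invariant and centres exactly", {
  x <- c(-1, 0.2, 0.5, 3)
  expect_equal(stats::median(normalize_ratios(x)), 0)
  expect_equal(normalize_ratios(x + 5), normalize_ratios(x))
  expect_equal(normalize_ratios(rep(2, 4)), rep(0, 4))
  expect_error(normalize_ratios(1), "at least 2")
})

test_that("IQR fences flag the planted outlier and only it", {
  x <- c(-0.1, -0.05, 0, 0.05, 0.1, 3.0)
  fl <- call_outliers(x)
  expect_equal(as.character(fl$flag), c(rep("none", 5), "upper"))
  fences <- attr(fl, "fences")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  expect_equal(unname(fences), unname(c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))))
})

test_that("fences collapse on constant input without flagging anything", {
  fl <- call_outliers(rep(0.3, 6))
  expect_true(all(fl$flag == "none"))
  expect_error(call_outliers(c(1, 2, 3)), "at least 4")
})

test_that("a symmetric planted pair yields one upper and one lower flag", {
  # bounded background: fences sit near +/-0.2, so only the planted pair can
  # exceed them
  x <- c(withr::with_seed(64, stats::runif(50, -0.1, 0.1)), 3, -3)
  fl <- call_outliers(x)
  expect_equal(sum(fl$flag == "upper"), 1)
  expect_equal(sum(fl$flag == "lower"), 1)
  expect_equal(which(fl$flag == "upper"), 51L)
  expect_equal(which(fl$flag == "lower"), 52L)
})

test_that("classification needs concordant outliers in both runs", {
  mk <- function(flags, ratios = rep(1, length(flags))) {
    data.frame(protein = paste0("p", seq_along(flags)), ratio = ratios,
               flag = flags)
  }
  fwd <- mk(c("upper", "upper", "upper", "lower", "none"))
  rev <- mk(c("upper", "none", "lower", "lower", "none"))
  calls <- classify_binders(fwd, rev)
  calls <- calls[order(calls$protein), ]
  expect_equal(calls$classification,
               c("C-preferential", "non-differential", "non-differential",
                 "G-preferential", "non-differential"))
})

test_that("classification is a partition and single-run proteins are noted", {
  fwd <- data.frame(protein = c("a", "b", "only_f"), ratio = c(2, 0, 1),
                    flag = c("upper", "none", "upper"))
  rev <- data.frame(protein = c("a", "b", "only_r"), ratio = c(2, 0, -1),
                    flag = c("upper", "none", "lower"))
  calls <- classify_binders(fwd, rev)
  expect_equal(nrow(calls), 4)
  expect_equal(sum(table(calls$protein) != 1), 0)
  expect_true(all(calls$classification[calls$protein %in% c("only_f", "only_r")]
                  == "non-differential"))
  expect_true(all(calls$note[calls$protein %in% c("only_f", "only_r")]
                  == "single-run"))
  expect_error(classify_binders(fwd[0, ], rev), "no overlapping")
})

test_that("planted binders are recovered with high precision and recall", {
  stats_over <- t(vapply(seq_len(10), function(i) {
    pd <- simulate_pulldown(n_proteins = 1005, n_c_binders = 5, effect = 2,
                            noise_sd = 0.3, seed = 500 + i)
    calls <- call_binders(pd$forward, pd$reverse)$calls
    called <- calls$protein[calls$classification == "C-preferential"]
    truth <- pd$truth$protein[pd$truth$class == "C-preferential"]
    c(recall = length(intersect(called, truth)) / length(truth),
      precision = if (length(called)) length(intersect(called, truth)) / length(called) else 1)
  }, numeric(2)))
  expect_gte(mean(stats_over[, "recall"]), 0.9)
  expect_gte(mean(stats_over[, "precision"]), 0.9)
})

test_that("concordance suppresses false positives when nothing is planted", {
  rates <- vapply(seq_len(10), function(i) {
    pd <- simulate_pulldown(n_proteins = 1000, n_c_binders = 0, effect = 0,
                            noise_sd = 0.3, seed = 900 + i)
    calls <- call_binders(pd$forward, pd$reverse)$calls
    mean(calls$classification != "non-differential")
  }, numeric(1))
  expect_lt(mean(rates), 0.01)
})

test_that("physically swapping channels with updated metadata changes nothing", {
  pd <- simulate_pulldown(n_proteins = 300, n_c_binders = 3, seed = 77)
  swap <- function(run) {
    out <- data.frame(protein = run$protein,
                      intensity_heavy = run$intensity_light,
                      intensity_light = run$intensity_heavy)
    attr(out, "orientation") <- if (attr(run, "orientation") == "forward")
      "reverse" else "forward"
    out
  }
  orig <- call_binders(pd$forward, pd$reverse)$calls
  swapped <- call_binders(swap(pd$forward), swap(pd$reverse))$calls
  ord <- order(orig$protein)
  expect_equal(orig$classification[ord],
               swapped$classification[order(swapped$protein)])
})

test_that("the pulldown generator is deterministic and validates its parameters", {
  a <- simulate_pulldown(n_proteins = 50, n_c_binders = 2, seed = 4)
  b <- simulate_pulldown(n_proteins = 50, n_c_binders = 2, seed = 4)
  expect_identical(a$forward, b$forward)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_pulldown(n_proteins = 3, n_c_binders = 2,
                                 n_g_binders = 2), "exceed")
  expect_error(simulate_pulldown(effect = -1), ">= 0")
  expect_error(simulate_pulldown(noise_sd = 0), "> 0")
})
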