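ct_row <- function(sample, target, condition, ct, replicate = 1, allele = NA,
                   template = "cDNA") {
  data.frame(sample = sample, target = target, allele = allele,
             condition = condition, template = template,
             replicate = replicate, ct = ct, stringsAsFactors = FALSE)
}

test_that("one extra cycle on the target halves the ddCt fold change", {
  ct <- rbind(ct_row("s1", "TERT", "treated", 25),
              ct_row("s1", "GAPDH", "treated", 20),
              ct_row("s1", "TERT", "scrambled", 24),
              ct_row("s1", "GAPDH", "scrambled", 20))
  res <- ddct_expression(ct, "TERT", "GAPDH", "scrambled")
  expect_equal(res$fold[res$condition == "treated"], 0.5)
  expect_equal(res$fold[res$condition == "scrambled"], 1)
  expect_equal(res$ddct[res$condition == "treated"], 1)
})

test_that("ddCt is invariant to a shared Ct offset within a sample", {
  base <- rbind(ct_row("s1", "TERT", "treated", 26.3),
                ct_row("s1", "GAPDH", "treated", 19.7),
                ct_row("s1", "TERT", "scrambled", 24.9),
                ct_row("s1", "GAPDH", "scrambled", 20.1))
  shifted <- base
  shifted$ct <- shifted$ct + 3.7
  expect_equal(ddct_expression(base, "TERT", "GAPDH", "scrambled")$fold,
               ddct_expression(shifted, "TERT", "GAPDH", "scrambled")$fold)
})

test_that("missing reference wells are reported by group", {
  ct <- rbind(ct_row("s1", "TERT", "treated", 25),
              ct_row("s1", "TERT", "scrambled", 24),
              ct_row("s1", "GAPDH", "scrambled", 20))
  expect_error(ddct_expression(ct, "TERT", "GAPDH", "scrambled"),
               "reference-gene wells.*s1.*treated")
})

test_that("a noiseless generator round trip recovers the planted fold exactly", {
  d <- qpcr_expression_design("s1", c(scrambled = 1, treated = 0.3))
  ct <- simulate_qpcr(d, replicates = 3, noise_sd = 0, seed = 1)
  res <- ddct_expression(ct, "TERT", "GAPDH", "scrambled")
  expect_equal(res$fold[res$condition == "treated"], 0.3, tolerance = 1e-12)
})

test_that("allelic Ct difference of one cycle doubles the C/G ratio", {
  ct <- rbind(ct_row("s1", "AS", "baseline", 24, allele = "C"),
              ct_row("s1", "AS", "baseline", 25, allele = "G"),
              ct_row("s1", "GAPDH", "baseline", 20))
  expect_equal(allelic_expression(ct, "AS", "GAPDH")$ratio_c_over_g, 2)
  ct$ct[1] <- 25
  expect_equal(allelic_expression(ct, "AS", "GAPDH")$ratio_c_over_g, 1)
  expect_error(allelic_expression(ct[-2, ], "AS", "GAPDH"), "allele channel")
})

test_that("noisy allelic ratios recover the planted 2.0 within 10%", {
  ratios <- vapply(seq_len(100), function(i) {
    d <- qpcr_allelic_design("s1", expression_ratio = 2, copy_ratio = 1)
    ct <- simulate_qpcr(d, replicates = 3, noise_sd = 0.1, seed = 100 + i)
    allelic_expression(ct, "TERT_allelic", "GAPDH")$ratio_c_over_g
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("copy-number adjustment is plain division with guards", {
  expect_equal(copy_number_adjust(2, 2), 1)
  expect_equal(copy_number_adjust(0.8, 0.5), 1.6)
  expect_equal(copy_number_adjust(1.7, 1), 1.7)
  expect_error(copy_number_adjust(-1, 1), "> 0")
  expect_error(copy_number_adjust(1, 0), "> 0")
})

test_that("adjusted ratio recovers per-copy preference under copy imbalance", {
  res <- vapply(seq_len(50), function(i) {
    d <- qpcr_allelic_design("s1", expression_ratio = 2.4, copy_ratio = 2)
    ct <- simulate_qpcr(d, replicates = 3, noise_sd = 0.1, seed = 700 + i)
    expr <- allelic_expression(ct, "TERT_allelic", "GAPDH")$ratio_c_over_g
    gdna <- ct[ct$template == "gDNA", ]
    g_ratio <- 2^(-(mean(gdna$ct[gdna$allele == "C"]) -
                      mean(gdna$ct[gdna$allele == "G"])))
    copy_number_adjust(expr, g_ratio)
  }, numeric(1))
  expect_lt(abs(mean(res) - 1.2), 0.12)
})

knockdown_ct <- function(fold_c, fold_g, reps = 3, sd = 0, seed = 1) {
  design <- rbind(
    data.frame(sample = "s1", target = "AS", allele = c("C", "G"),
               condition = "scrambled", amount = c(0.5, 0.5)),
    data.frame(sample = "s1", target = "AS", allele = c("C", "G"),
               condition = "siRNA3", amount = c(0.5 * fold_c, 0.5 * fold_g)),
    data.frame(sample = "s1", target = "GAPDH", allele = NA,
               condition = c("scrambled", "siRNA3"), amount = 1))
  simulate_qpcr(design, replicates = reps, noise_sd = sd, seed = seed)
}

test_that("a treated/scrambled fold of 0.4 is a 60% knockdown", {
  ct <- knockdown_ct(0.4, 0.5)
  res <- allelic_knockdown(ct, "AS", "GAPDH", "siRNA3")
  expect_equal(res$summary$mean[res$summary$allele == "C"], 60, tolerance = 1e-9)
  expect_equal(res$summary$mean[res$summary$allele == "G"], 50, tolerance = 1e-9)
})

test_that("identical replicate vectors give zero difference and p = 1", {
  tst <- allele_contrast_test(c(60, 61, 59), c(60, 61, 59), paired = TRUE)
  expect_equal(tst$difference, 0)
  expect_equal(tst$p_value, 1)
})

test_that("the paired allele contrast matches the closed-form t distribution", {
  # constant paired differences: degenerate t, reported as p = 0
  degen <- allele_contrast_test(c(60, 61, 59), c(49, 50, 48), paired = TRUE)
  expect_equal(degen$difference, 11)
  expect_lt(degen$p_value, 0.01)
  expect_match(degen$note, "zero-variance")
  # non-degenerate: equals 2 * pt(-|t|, df) to 1e-10
  a <- c(60, 61, 59); b <- c(49, 50.5, 48)
  tst <- allele_contrast_test(a, b, paired = TRUE)
  d <- a - b
  t_manual <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(tst$t, t_manual, tolerance = 1e-10)
  expect_equal(tst$p_value, 2 * stats::pt(-abs(t_manual), 2), tolerance = 1e-10)
})

test_that("the siRNA specificity Fisher test reproduces the printed 0.011", {
  expect_equal(sirna_specificity_test(3, 8, 0, 24), 0.0113, tolerance = 1e-3)
  expect_equal(sirna_specificity_test(0, 8, 0, 24), 1)
  expect_error(sirna_specificity_test(-1, 8, 0, 24), "non-negative")
  expect_error(sirna_specificity_test(9, 8, 0, 24), "exceed")
})

test_that("the Fisher enumeration agrees with fisher.test across table space", {
  for (n1 in c(3, 5, 8)) {
    for (n2 in c(4, 10, 24)) {
      for (h1 in 0:n1) {
        for (h2 in 0:min(n2, 4)) {
          mine <- sirna_specificity_test(h1, n1, h2, n2)
          ref <- stats::fisher.test(matrix(c(h1, n1 - h1, h2, n2 - h2), 2))$p.value
          expect_equal(mine, ref, tolerance = 1e-9,
                       info = sprintf("table %d/%d vs %d/%d", h1, n1, h2, n2))
        }
      }
    }
  }
  # symmetric under simultaneous group swap
  expect_equal(sirna_specificity_test(3, 8, 1, 24),
               sirna_specificity_test(1, 24, 3, 8), tolerance = 1e-12)
})

chip_tables <- function(ip_ct, ctl_ct, in_ct, amplicon = "amp6", reps = 3) {
  mk <- function(ct) data.frame(amplicon = amplicon,
                                replicate = seq_len(reps), ct = ct)
  list(ip = mk(rep(ip_ct, reps)), ctl = mk(rep(ctl_ct, reps)),
       input = mk(rep(in_ct, reps)))
}

test_that("ChIP enrichment is 1 at equal Ct and 2 per cycle of advantage", {
  tb <- chip_tables(28, 28, 24)
  expect_equal(chip_enrichment(tb$ip, tb$ctl, tb$input)$enrichment, 1)
  tb2 <- chip_tables(27, 28, 24)
  expect_equal(chip_enrichment(tb2$ip, tb2$ctl, tb2$input)$enrichment, 2)
  expect_error(chip_enrichment(tb$ip, tb$ctl, tb$input[0, ]), "missing input")
})

test_that("input-dilution adjustment scales percent input, not enrichment", {
  tb <- chip_tables(28, 29, 24)
  undil <- chip_enrichment(tb$ip, tb$ctl, tb$input, input_dilution = 1)
  dil <- chip_enrichment(tb$ip, tb$ctl, tb$input, input_dilution = 0.01)
  expect_equal(dil$enrichment, undil$enrichment)
  expect_equal(dil$pct_input_ip, undil$pct_input_ip * 0.01)
})

test_that("a planted 4-fold enrichment stands out among nine amplicons", {
  amps <- sprintf("amp%d", 1:9)
  design <- rbind(
    data.frame(sample = "chip", target = amps, condition = "IP",
               amount = ifelse(amps == "amp6", 0.04, 0.01)),
    data.frame(sample = "chip", target = amps, condition = "IgG",
               amount = 0.01),
    data.frame(sample = "chip", target = amps, condition = "input",
               amount = 1))
  ct <- simulate_qpcr(design, replicates = 3, noise_sd = 0.1, seed = 31)
  grab <- function(cond) data.frame(amplicon = ct$target[ct$condition == cond],
                                    replicate = ct$replicate[ct$condition == cond],
                                    ct = ct$ct[ct$condition == cond])
  enr <- chip_enrichment(grab("IP"), grab("IgG"), grab("input"))
  expect_gt(enr$enrichment[enr$amplicon == "amp6"], 2)
  expect_true(all(enr$enrichment[enr$amplicon != "amp6"] < 2))
})

test_that("the paired allelic ChIP contrast reports fold and p", {
  same <- chip_allelic_test(c(1.1, 1.2, 1.3), c(1.1, 1.2, 1.3))
  expect_equal(same$fold, 1)
  expect_equal(same$p_value, 1)
  ex <- chip_allelic_test(c(1.2, 1.3, 1.4), c(1.0, 1.1, 1.2))
  expect_equal(ex$fold, mean(c(1.2, 1.3, 1.4)) / mean(c(1.0, 1.1, 1.2)))
  expect_lte(ex$p_value, 0.01)
  expect_error(chip_allelic_test(1.5, 1.2), ">= 2")
  expect_error(chip_allelic_test(c(1, 2), c(1, 2, 3)), "equal-length")
})

reporter_wells <- function(c_act, g_act, reps = 3) {
  rbind(
    data.frame(construct = "empty", allele = NA, orientation = NA,
               firefly = rep(100, reps), renilla = 100),
    data.frame(construct = "FC", allele = "C", orientation = "forward",
               firefly = 100 * c_act, renilla = 100),
    data.frame(construct = "FG", allele = "G", orientation = "forward",
               firefly = 100 * g_act, renilla = 100))
}

test_that("reporter activity is 1 for empty-like wells and scales by firefly", {
  w <- reporter_wells(rep(1, 3), rep(1, 3))
  res <- reporter_activity(w)
  expect_true(all(abs(res$by_construct$mean - 1) < 1e-12))
  w2 <- reporter_wells(c(1.44, 1.44, 1.44), rep(1, 3))
  res2 <- reporter_activity(w2)
  expect_equal(res2$contrasts$forward$fold_c_over_g, 1.44)
  expect_error(reporter_activity(transform(w, renilla = 0)), "renilla")
  expect_error(reporter_activity(w[w$construct != "empty", ]), "empty")
})

test_that("noisy reporter simulations recover a planted C/G fold of 1.35", {
  folds <- vapply(seq_len(100), function(i) {
    withr::with_seed(4000 + i, {
      w <- rbind(
        data.frame(construct = "empty", allele = NA, orientation = NA,
                   firefly = stats::rlnorm(3, log(100), 0.1), renilla = 100),
        data.frame(construct = "FC", allele = "C", orientation = "forward",
                   firefly = stats::rlnorm(9, log(135 * 2), 0.1), renilla = 100),
        data.frame(construct = "FG", allele = "G", orientation = "forward",
                   firefly = stats::rlnorm(9, log(100 * 2), 0.1), renilla = 100))
    })
    reporter_activity(w)$contrasts$forward$fold_c_over_g
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1.35), 0.135)
})

test_that("the Ct generator validates input and is deterministic", {
  d <- qpcr_expression_design("s1", c(scrambled = 1, treated = 0.5))
  expect_identical(simulate_qpcr(d, seed = 5), simulate_qpcr(d, seed = 5))
  d$amount[1] <- 0
  expect_error(simulate_qpcr(d, seed = 5), "> 0")
  expect_error(simulate_qpcr(qpcr_expression_design("s1", c(scrambled = 1)),
                             replicates = 0), "replicates")
})
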