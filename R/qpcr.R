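#' Relative expression by the 2^-ddCt method
#'
#' For each (sample, condition) group, replicate Cts are averaged within the
#' group before differencing: dCt = mean Ct(target) - mean Ct(reference gene),
#' ddCt = dCt(condition) - dCt(calibrator condition within the same sample),
#' fold change = 2^-ddCt. The SEM of the fold change is propagated from the
#' replicate Ct variances by the delta method
#' (\eqn{SE(fold) = fold \cdot \ln 2 \cdot SE(ddCt)}).
#'
#' @param ct long-format Ct data.frame with columns `sample`, `target`,
#'   `condition`, `replicate`, `ct` (an `allele` column, if present, is
#'   ignored for rows of the reference gene and must be collapsed for the
#'   target beforehand for non-allelic use).
#' @param target,reference_gene target and reference-gene names.
#' @param calibrator_condition condition used as calibrator (fold 1).
#' @return data.frame per (sample, condition): `dct`, `ddct`, `fold`,
#'   `fold_sem`, `n_target`, `n_reference`.
#' @examples
#' ct <- rbind(
#'   data.frame(sample = "s1", target = "TERT",  condition = "treated",
#'              replicate = 1, ct = 25),
#'   data.frame(sample = "s1", target = "GAPDH", condition = "treated",
#'              replicate = 1, ct = 20),
#'   data.frame(sample = "s1", target = "TERT",  condition = "scrambled",
#'              replicate = 1, ct = 24),
#'   data.frame(sample = "s1", target = "GAPDH", condition = "scrambled",
#'              replicate = 1, ct = 20))
#' ddct_expression(ct, "TERT", "GAPDH", "scrambled")$fold  # 0.5, 1
#' @export
ddct_expression <- function(ct, target, reference_gene, calibrator_condition) {
  .check_ct(ct)
  groups <- unique(ct[ct$target %in% c(target, reference_gene),
                      c("sample", "condition")])
  if (!calibrator_condition %in% groups$condition) {
    stop("calibrator condition not present: ", calibrator_condition)
  }
  summ <- function(s, cond, tgt) {
    v <- ct$ct[ct$sample == s & ct$condition == cond & ct$target == tgt]
    if (!length(v)) {
      stop(sprintf("missing %s wells for sample '%s', condition '%s'",
                   if (tgt == reference_gene) "reference-gene" else "target",
                   s, cond))
    }
    list(mean = mean(v), var = stats::var(v), n = length(v))
  }
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    s <- groups$sample[k]; cond <- groups$condition[k]
    tg <- summ(s, cond, target); rf <- summ(s, cond, reference_gene)
    dct_var <- .nz(tg$var) / tg$n + .nz(rf$var) / rf$n
    data.frame(sample = s, condition = cond, dct = tg$mean - rf$mean,
               dct_var = dct_var, n_target = tg$n, n_reference = rf$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  cal <- res[res$condition == calibrator_condition, ]
  ci <- match(res$sample, cal$sample)
  if (anyNA(ci)) {
    stop("calibrator condition missing for sample(s): ",
         paste(unique(res$sample[is.na(ci)]), collapse = ", "))
  }
  res$ddct <- res$dct - cal$dct[ci]
  ddct_var <- res$dct_var + ifelse(res$condition == calibrator_condition,
                                   0, cal$dct_var[ci])
  res$fold <- 2^(-res$ddct)
  res$fold_sem <- res$fold * log(2) * sqrt(ddct_var)
  res$dct_var <- NULL
  res
}

.nz <- function(v) if (is.na(v)) 0 else v

.check_ct <- function(ct) {
  stopifnot(is.data.frame(ct),
            all(c("sample", "target", "condition", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  invisible(ct)
}

#' Allele-specific expression ratio from an allelic-discrimination assay
#'
#' Per sample, the C/G expression ratio is 2^-(mean Ct_C - mean Ct_G) on cDNA.
#' Each allele is normalised to the reference gene; the reference terms cancel
#' within a sample but are required to be present so that ratios are
#' comparable across samples measured on different plates.
#'
#' @param ct long Ct table with an `allele` column (`"C"`/`"G"` for the
#'   allelic target, NA for the reference gene) and a `template` column
#'   (`"cDNA"` rows are used).
#' @param allelic_target,reference_gene assay names.
#' @param condition condition to evaluate (default: all, per condition).
#' @return data.frame per (sample, condition): `ratio_c_over_g`, replicate
#'   counts per allele.
#' @export
allelic_expression <- function(ct, allelic_target, reference_gene,
                               condition = NULL) {
  .check_ct(ct)
  stopifnot("allele" %in% names(ct))
  if (!"template" %in% names(ct)) ct$template <- "cDNA"
  cdna <- ct[ct$template == "cDNA", ]
  if (!is.null(condition)) cdna <- cdna[cdna$condition %in% condition, ]
  groups <- unique(cdna[cdna$target == allelic_target, c("sample", "condition")])
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    s <- groups$sample[k]; cond <- groups$condition[k]
    sub <- cdna[cdna$sample == s & cdna$condition == cond, ]
    ct_c <- sub$ct[sub$target == allelic_target & sub$allele == "C"]
    ct_g <- sub$ct[sub$target == allelic_target & sub$allele == "G"]
    if (!length(ct_c) || !length(ct_g)) {
      stop(sprintf("allele channel missing for sample '%s', condition '%s'", s, cond))
    }
    if (!any(sub$target == reference_gene)) {
      stop(sprintf("reference-gene wells missing for sample '%s', condition '%s'",
                   s, cond))
    }
    data.frame(sample = s, condition = cond,
               ratio_c_over_g = 2^(-(mean(ct_c) - mean(ct_g))),
               n_c = length(ct_c), n_g = length(ct_g), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Adjust an allelic expression ratio for genomic copy number
#'
#' Divides the cDNA C/G expression ratio by the C/G ratio measured with the
#' same allelic assay on genomic DNA, so that allelic imbalance of the genome
#' itself (amplification, aneuploidy) is removed and the residual ratio
#' reflects per-copy regulatory preference.
#'
#' @param expression_ratio,genomic_dna_ratio positive numerics (vectorised).
#' @return adjusted allelic ratio(s).
#' @export
copy_number_adjust <- function(expression_ratio, genomic_dna_ratio) {
  if (any(expression_ratio <= 0) || any(genomic_dna_ratio <= 0)) {
    stop("ratios must be > 0")
  }
  expression_ratio / genomic_dna_ratio
}

#' Per-allele knockdown with an allele contrast
#'
#' For each replicate (experiment) and allele, relative expression under the
#' treated condition versus the scrambled control is
#' 2^-(dCt_treated - dCt_scrambled) with dCt = Ct(allele) - Ct(reference
#' gene); knockdown is 100 x (1 - relative expression). The two alleles are
#' compared by a two-sided t test on the replicate knockdown values, paired
#' by replicate when `paired = TRUE` (the default; replicates are independent
#' experiments in which both alleles are measured together), else Welch.
#'
#' If all paired differences are identical the t statistic is degenerate:
#' the p-value is reported as 1 when the common difference is zero and 0
#' otherwise, with a note.
#'
#' @param ct long Ct table (cDNA rows used) with `allele` for the allelic
#'   target and reference-gene rows.
#' @param allelic_target,reference_gene assay names.
#' @param treated_condition,scrambled_condition condition labels.
#' @param alleles the two allele labels to contrast (default C, G).
#' @param paired pair replicates across alleles?
#' @return list with `per_replicate` (knockdown % per replicate x allele),
#'   `summary` (per allele: mean, sem, n) and `test` (difference of means,
#'   t, df, p, method, note).
#' @export
allelic_knockdown <- function(ct, allelic_target, reference_gene,
                              treated_condition,
                              scrambled_condition = "scrambled",
                              alleles = c("C", "G"), paired = TRUE) {
  .check_ct(ct)
  stopifnot("allele" %in% names(ct), length(alleles) == 2)
  if (!"template" %in% names(ct)) ct$template <- "cDNA"
  cdna <- ct[ct$template == "cDNA", ]
  kd_one <- function(allele, rep_id) {
    val <- function(cond, tgt, all_) {
      v <- cdna$ct[cdna$condition == cond & cdna$target == tgt &
                     cdna$replicate == rep_id &
                     (if (is.na(all_)) TRUE else cdna$allele %in% all_)]
      if (!length(v)) NA_real_ else mean(v)
    }
    dct_t <- val(treated_condition, allelic_target, allele) -
      val(treated_condition, reference_gene, NA)
    dct_s <- val(scrambled_condition, allelic_target, allele) -
      val(scrambled_condition, reference_gene, NA)
    rel <- 2^(-(dct_t - dct_s))
    100 * (1 - rel)
  }
  reps <- sort(unique(cdna$replicate[cdna$target == allelic_target]))
  if (length(reps) < 2) stop("need >= 2 replicates per allele")
  per <- expand.grid(replicate = reps, allele = alleles,
                     stringsAsFactors = FALSE)
  per$knockdown_pct <- mapply(kd_one, per$allele, per$replicate)
  if (anyNA(per$knockdown_pct)) {
    stop("missing wells for at least one replicate/allele/condition combination")
  }
  kd1 <- per$knockdown_pct[per$allele == alleles[1]]
  kd2 <- per$knockdown_pct[per$allele == alleles[2]]
  test <- allele_contrast_test(kd1, kd2, paired = paired)
  summary <- data.frame(
    allele = alleles,
    mean = c(mean(kd1), mean(kd2)),
    sem = c(stats::sd(kd1), stats::sd(kd2)) / sqrt(length(reps)),
    n = length(reps))
  list(per_replicate = per, summary = summary, test = test)
}

#' Two-sided t contrast between two replicate vectors
#'
#' Paired (on per-replicate differences) or Welch unpaired two-sided t test,
#' with explicit handling of the zero-variance degenerate case (p = 1 when
#' the mean difference is zero, p = 0 otherwise).
#'
#' @param a,b numeric replicate vectors (equal length when paired).
#' @param paired logical.
#' @return list: `difference` (mean a - mean b), `t`, `df`, `p_value`,
#'   `method`, `note`.
#' @export
allele_contrast_test <- function(a, b, paired = TRUE) {
  if (paired && length(a) != length(b)) {
    stop("paired contrast requires equal-length vectors")
  }
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 replicates per group")
  diff <- mean(a) - mean(b)
  note <- ""
  if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
      note <- "zero-variance paired differences; degenerate t"
      return(list(difference = diff, t = if (mean(d) == 0) 0 else Inf,
                  df = length(d) - 1, p_value = p, method = "paired t",
                  note = note))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    method <- "paired t"
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p <- if (diff == 0) 1 else 0
      return(list(difference = diff, t = if (diff == 0) 0 else Inf,
                  df = NA_real_, p_value = p, method = "Welch t",
                  note = "zero variance in both groups; degenerate t"))
    }
    tt <- stats::t.test(a, b, paired = FALSE, var.equal = FALSE)
    method <- "Welch t"
  }
  list(difference = diff, t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = method, note = note)
}

#' Exact Fisher test of siRNA target specificity
#'
#' Two-sided Fisher exact test comparing the number of effective siRNAs for
#' the target gene against pooled control genes, by full hypergeometric
#' enumeration: the two-sided p-value is the sum of probabilities of all
#' tables with the same margins whose probability does not exceed the
#' observed table's (the convention of R's `fisher.test`).
#'
#' @param hits_target,n_target effective / total siRNAs for the target gene.
#' @param hits_controls,n_controls effective / total siRNAs pooled across
#'   control genes.
#' @return two-sided p-value.
#' @examples
#' sirna_specificity_test(3, 8, 0, 24)  # 0.0113
#' @export
sirna_specificity_test <- function(hits_target, n_target, hits_controls,
                                   n_controls) {
  counts <- c(hits_target, n_target, hits_controls, n_controls)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (hits_target > n_target || hits_controls > n_controls) {
    stop("hits cannot exceed the number of siRNAs tested")
  }
  k <- hits_target + hits_controls          # total hits (fixed margin)
  x <- 0:k
  prob <- stats::dhyper(x, n_target, n_controls, k)
  obs <- stats::dhyper(hits_target, n_target, n_controls, k)
  sum(prob[prob <= obs * (1 + 1e-7)])
}

#' ChIP-qPCR enrichment over a control antibody, per amplicon
#'
#' Percent input for each antibody is 100 x 2^-(Ct_antibody -
#' Ct_input_adjusted), where the input Ct is first adjusted for the input
#' dilution (Ct_input - log2(input_dilution)); enrichment is percent-input of
#' the specific IP divided by percent-input of the nonspecific control
#' antibody. Replicate SD of the enrichment is reported (per-replicate IP
#' and control percent-inputs against the mean input Ct).
#'
#' @param ip,control_antibody,input data.frames with columns `amplicon`,
#'   `replicate`, `ct` (>= 2 replicates each).
#' @param input_dilution fraction of input chromatin assayed relative to the
#'   IP (e.g. 0.01 for a 1% input); default 1 (no adjustment).
#' @return data.frame per amplicon: `pct_input_ip`, `pct_input_control`,
#'   `enrichment`, `enrichment_sd`, `n`.
#' @export
chip_enrichment <- function(ip, control_antibody, input, input_dilution = 1) {
  for (tb in list(ip, control_antibody, input)) {
    stopifnot(is.data.frame(tb),
              all(c("amplicon", "replicate", "ct") %in% names(tb)))
  }
  amplicons <- unique(ip$amplicon)
  rows <- lapply(amplicons, function(a) {
    ct_ip <- ip$ct[ip$amplicon == a]
    ct_ctl <- control_antibody$ct[control_antibody$amplicon == a]
    ct_in <- input$ct[input$amplicon == a]
    if (!length(ct_in)) stop("missing input wells for amplicon ", a)
    if (length(ct_ip) < 2 || length(ct_ctl) < 2) {
      stop("need >= 2 replicate Cts per antibody for amplicon ", a)
    }
    # full-input equivalent: an input that is a fraction d of the IP template
    # would reach threshold log2(1/d) cycles later, so subtract that here
    in_adj <- mean(ct_in) + log2(input_dilution)
    pct <- function(cts) 100 * 2^(-(cts - in_adj))
    pi_ip <- pct(ct_ip); pi_ctl <- pct(ct_ctl)
    enr <- mean(pi_ip) / mean(pi_ctl)
    # per-replicate enrichment spread (replicates paired by index where possible)
    nr <- min(length(pi_ip), length(pi_ctl))
    enr_reps <- pi_ip[seq_len(nr)] / pi_ctl[seq_len(nr)]
    data.frame(amplicon = a, pct_input_ip = mean(pi_ip),
               pct_input_control = mean(pi_ctl), enrichment = enr,
               enrichment_sd = stats::sd(enr_reps), n = nr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired allelic ChIP contrast
#'
#' Fold enrichment of the C over the G allele in ChIP signal
#' (input-normalised replicate vectors) with a two-sided paired t test on the
#' per-replicate differences.
#'
#' @param c_signals,g_signals equal-length paired replicate vectors (n >= 2).
#' @return list: `fold` (mean C / mean G), `t`, `df`, `p_value`.
#' @export
chip_allelic_test <- function(c_signals, g_signals) {
  if (length(c_signals) != length(g_signals)) {
    stop("paired allelic test requires equal-length replicate vectors")
  }
  if (length(c_signals) < 2) stop("need >= 2 replicate pairs")
  tst <- allele_contrast_test(c_signals, g_signals, paired = TRUE)
  list(fold = mean(c_signals) / mean(g_signals), t = tst$t, df = tst$df,
       p_value = tst$p_value, note = tst$note)
}

#' Dual-luciferase reporter activity with allele contrasts
#'
#' Per-well activity is firefly/renilla, normalised to the mean
#' firefly/renilla of the empty-vector wells. For each insert orientation the
#' C versus G allele contrast is a two-sided Welch t test on replicate
#' activities, with the C/G fold of mean activities.
#'
#' @param wells data.frame with columns `construct`, `allele` (`"C"`, `"G"`
#'   or NA for the empty vector), `orientation` (NA for empty), `firefly`,
#'   `renilla` (> 0).
#' @param empty_construct name of the empty-vector construct.
#' @return list with `activities` (per well), `by_construct` (mean, sd, n)
#'   and `contrasts` (per orientation: fold C/G, t, df, p).
#' @export
reporter_activity <- function(wells, empty_construct = "empty") {
  stopifnot(is.data.frame(wells),
            all(c("construct", "allele", "orientation", "firefly", "renilla")
                %in% names(wells)))
  if (any(wells$renilla <= 0)) stop("renilla activities must be > 0")
  empty <- wells$construct == empty_construct
  if (!any(empty)) stop("no empty-vector wells found (construct '",
                        empty_construct, "')")
  raw <- wells$firefly / wells$renilla
  wells$activity <- raw / mean(raw[empty])
  agg <- stats::aggregate(activity ~ construct, data = wells,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  by_construct <- data.frame(construct = agg$construct,
                             mean = agg$activity[, "mean"],
                             sd = agg$activity[, "sd"],
                             n = agg$activity[, "n"])
  contrasts <- list()
  for (ori in unique(stats::na.omit(wells$orientation))) {
    a_c <- wells$activity[!empty & wells$orientation %in% ori & wells$allele %in% "C"]
    a_g <- wells$activity[!empty & wells$orientation %in% ori & wells$allele %in% "G"]
    if (length(a_c) >= 2 && length(a_g) >= 2) {
      tst <- allele_contrast_test(a_c, a_g, paired = FALSE)
      contrasts[[ori]] <- list(fold_c_over_g = mean(a_c) / mean(a_g),
                               t = tst$t, df = tst$df, p_value = tst$p_value)
    }
  }
  list(activities = wells, by_construct = by_construct, contrasts = contrasts)
}
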