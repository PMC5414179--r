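#' Simulate case-control phenotypes under a multiplicative-odds model
#'
#' Draws a binary phenotype from the logistic model
#' \deqn{\mathrm{logit}\, P(y=1) = \beta_0 + \sum_j \log(\mathrm{OR}_j)\, g_j
#'   + Z\gamma}
#' over the individuals of a genotype matrix. In `"cohort"` mode every
#' individual is returned with a phenotype draw; in `"retrospective"` mode
#' the matrix is treated as a source cohort from which the requested numbers
#' of cases and controls are subsampled (mirroring case-control ascertainment),
#' and an error is raised when the cohort does not contain enough cases.
#'
#' @param G a [genotype_matrix()].
#' @param or named vector of per-allele odds ratios (> 0) for the causal
#'   variants; names must be variant ids in `G`. Variants not named have
#'   OR 1.
#' @param baseline baseline log-odds \eqn{\beta_0}.
#' @param covariates optional numeric matrix (rows = samples of `G`).
#' @param covariate_effects coefficients for `covariates`.
#' @param mode `"cohort"` or `"retrospective"`.
#' @param n_cases,n_controls required in retrospective mode.
#' @param seed integer seed.
#' @return list with `phenotype` (0/1), `sample_idx` (rows of `G` used),
#'   `covariates` (subset, or NULL) and `mode`.
#' @export
simulate_case_control <- function(G, or = numeric(0), baseline = 0,
                                  covariates = NULL, covariate_effects = NULL,
                                  mode = c("cohort", "retrospective"),
                                  n_cases = NULL, n_controls = NULL,
                                  seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  mode <- match.arg(mode)
  if (length(or)) {
    if (is.null(names(or))) stop("odds ratios must be named by variant id")
    if (any(or <= 0)) stop("odds ratios must be > 0")
    missing_ids <- setdiff(names(or), G$variants$id)
    if (length(missing_ids)) {
      stop("causal variant(s) not in genotype matrix: ",
           paste(missing_ids, collapse = ", "))
    }
  }
  n <- nrow(G$genotypes)
  eta <- rep(baseline, n)
  for (v in names(or)) {
    eta <- eta + log(or[[v]]) * G$genotypes[, v]
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n, length(covariate_effects) == ncol(covariates))
    eta <- eta + drop(covariates %*% covariate_effects)
  }
  # one seed, one sequential stream: phenotype draw then (if retrospective)
  # the case/control subsample, so datasets at different seeds never share
  # random numbers
  run <- function() {
    y <- stats::rbinom(n, 1L, stats::plogis(eta))
    if (mode == "cohort") {
      return(list(phenotype = y, sample_idx = seq_len(n),
                  covariates = covariates, mode = mode))
    }
    if (is.null(n_cases) || is.null(n_controls) || n_cases < 1 || n_controls < 1) {
      stop("retrospective mode requires n_cases >= 1 and n_controls >= 1")
    }
    cases <- which(y == 1L); controls <- which(y == 0L)
    if (length(cases) < n_cases) {
      stop(sprintf("cohort produced only %d cases but %d were requested; enlarge the cohort or raise the baseline log-odds",
                   length(cases), n_cases))
    }
    if (length(controls) < n_controls) {
      stop(sprintf("cohort produced only %d controls but %d were requested",
                   length(controls), n_controls))
    }
    idx <- c(sample(cases, n_cases), sample(controls, n_controls))
    list(phenotype = y[idx], sample_idx = idx,
         covariates = if (is.null(covariates)) NULL
         else covariates[idx, , drop = FALSE],
         mode = mode)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' One-call GWAS dataset: pool -> cohort -> ascertained case-control sample
#'
#' Convenience wrapper: samples a source cohort of
#' `cohort_multiplier * (n_cases + n_controls)` individuals from a haplotype
#' pool, draws phenotypes under the logistic model, and subsamples the
#' requested cases and controls.
#'
#' @inheritParams simulate_case_control
#' @param pool a [make_haplotype_pool()] object.
#' @param cohort_multiplier size of the source cohort relative to the
#'   requested sample (default 20).
#' @return list with `G` (genotype_matrix of the ascertained sample) and
#'   `phenotype`.
#' @export
simulate_gwas <- function(pool, n_cases, n_controls, or = numeric(0),
                          baseline = 0, cohort_multiplier = 20, seed = NULL) {
  run <- function() {
    n_cohort <- ceiling(cohort_multiplier * (n_cases + n_controls))
    G <- sample_genotypes(pool, n_cohort)
    cc <- simulate_case_control(G, or = or, baseline = baseline,
                                mode = "retrospective",
                                n_cases = n_cases, n_controls = n_controls)
    list(G = G[cc$sample_idx, ], phenotype = cc$phenotype)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Haplotype pool emulating a tightly correlated risk-region block
#'
#' An index (causal) variant of MAF 0.19 followed by proxies in strong LD,
#' emulating a fine-mapping block in which a group of highly correlated SNPs
#' collectively marks one signal: conditioning on the index variant should
#' collapse every proxy's association. Variants are arranged as a
#' positionally ordered Markov chain (index -- proxy1 -- proxy2 -- ...) with
#' a per-step r-squared, the first-order model of LD decay along a haplotype
#' block: unlike a hub-and-spokes layout this keeps the proxies mutually
#' correlated even after conditioning on the index, as neighbouring variants
#' of a real block are. With the default step r-squared of 0.98 the marginal
#' index-proxy r-squared runs from 0.98 down to about 0.85, a tight block of
#' the kind whose members are all individually genome-wide significant and
#' all collapse under conditioning.
#'
#' @param n_proxies number of proxy variants (default 8).
#' @param maf shared minor-allele frequency (default 0.19).
#' @param r2_step per-edge r-squared between positional neighbours.
#' @return a [make_haplotype_pool()] with variants `index`, `proxy1`, ...
#' @export
make_risk_region_pool <- function(n_proxies = 8, maf = 0.19, r2_step = 0.98) {
  ids <- c("index", sprintf("proxy%d", seq_len(n_proxies)))
  make_haplotype_pool(stats::setNames(rep(maf, n_proxies + 1), ids),
                      ld_targets = data.frame(i = ids[-length(ids)],
                                              j = ids[-1],
                                              r2 = r2_step))
}

#' Two-variant scenario in which the marginal signal at one variant is masked
#'
#' Constructs a dataset with two causal variants A and B in positive LD with
#' effects in opposite directions, so that the marginal (single-SNP)
#' association at A is attenuated relative to its association conditional on
#' B. This is the classical masking pattern in which a variant looks null in
#' single-SNP analysis but becomes significant after conditioning on the
#' region's top SNP. The default preset uses a masked variant of modest
#' protective effect (OR 0.72) hidden by a risk variant (OR 1.45) at
#' r-squared 0.5.
#'
#' @param n cohort size (default 6000).
#' @param or_a,or_b per-allele odds ratios at the masked variant A and the
#'   masking variant B.
#' @param r2 LD between A and B (positive D).
#' @param maf minor-allele frequencies of A and B.
#' @param seed integer seed.
#' @return list with `G`, `phenotype` and `meta` (the parameters; when
#'   `r2 = 0`, `meta$warning` records that no attenuation is possible).
#' @export
make_masked_pair_scenario <- function(n = 6000, or_a = 0.72, or_b = 1.45,
                                      r2 = 0.5, maf = c(0.3, 0.3),
                                      seed = NULL) {
  pool <- make_haplotype_pool(
    stats::setNames(maf, c("snpA", "snpB")),
    ld_targets = if (r2 > 0) data.frame(i = "snpA", j = "snpB", r2 = r2) else NULL)
  run <- function() {
    G <- sample_genotypes(pool, n)
    cc <- simulate_case_control(G, or = c(snpA = or_a, snpB = or_b),
                                baseline = 0, mode = "cohort")
    list(G = G, phenotype = cc$phenotype)
  }
  dat <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  G <- dat$G; cc <- dat
  meta <- list(or_a = or_a, or_b = or_b, r2 = r2, maf = maf, n = n)
  if (r2 == 0) {
    meta$warning <- "LD r2 is 0: marginal and conditional associations at A coincide in distribution; no masking is possible"
  }
  list(G = G, phenotype = cc$phenotype, meta = meta)
}
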