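#' Simulate a long-format qPCR Ct table from latent template amounts
#'
#' Each design row specifies a latent relative template amount for one
#' (sample, target, allele, condition, template) combination; replicate
#' threshold cycles are drawn as
#' \deqn{Ct = \mathrm{offset} - \log_2(\mathrm{amount}) + N(0, \sigma)}
#' i.e. perfectly efficient amplification (one doubling per cycle), the model
#' under which 2^-ddCt quantification is exact.
#'
#' @param design data.frame with columns `sample`, `target`, `condition`,
#'   `amount` (> 0) and optionally `allele` (NA for non-allelic assays) and
#'   `template` (`"cDNA"` or `"gDNA"`, default `"cDNA"`).
#' @param replicates technical replicates per design row (>= 1).
#' @param ct_offset cycle count of one unit of template (default 25).
#' @param noise_sd replicate Ct noise SD (>= 0).
#' @param seed integer seed.
#' @return long data.frame: `sample`, `target`, `allele`, `condition`,
#'   `template`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(design, replicates = 3, ct_offset = 25,
                          noise_sd = 0.1, seed = NULL) {
  stopifnot(is.data.frame(design),
            all(c("sample", "target", "condition", "amount") %in% names(design)))
  if (any(design$amount <= 0)) stop("latent template amounts must be > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!"allele" %in% names(design)) design$allele <- NA_character_
  if (!"template" %in% names(design)) design$template <- "cDNA"
  gen <- function() {
    idx <- rep(seq_len(nrow(design)), each = replicates)
    out <- design[idx, c("sample", "target", "allele", "condition", "template")]
    out$replicate <- rep(seq_len(replicates), nrow(design))
    out$ct <- ct_offset - log2(design$amount[idx]) +
      stats::rnorm(length(idx), 0, noise_sd)
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Design helpers for common qPCR experiments
#'
#' Build `design` data.frames for [simulate_qpcr()]:
#' \describe{
#'   \item{`qpcr_expression_design`}{target + reference gene across
#'     conditions; `fold` gives each condition's expression relative to the
#'     calibrator condition.}
#'   \item{`qpcr_allelic_design`}{an allelic-discrimination assay: cDNA
#'     template split between the C and G alleles according to
#'     `expression_ratio` (C/G) and, on genomic DNA, `copy_ratio`; plus a
#'     reference gene.}
#'   \item{`qpcr_telomere_design`}{paired telomere (`TEL`) and single-copy
#'     gene (`SCG`) wells; `relative_length` scales the telomere template
#'     per condition relative to the calibrator.}
#' }
#'
#' @param samples character vector of sample ids.
#' @param fold named numeric vector: expression of the target per condition
#'   relative to the calibrator (include the calibrator itself at 1).
#' @param target,reference target and reference-gene names.
#' @param base_level,ref_level latent amounts of target (at fold 1) and
#'   reference.
#' @return a design data.frame for [simulate_qpcr()].
#' @name qpcr_designs
NULL

#' @rdname qpcr_designs
#' @export
qpcr_expression_design <- function(samples, fold, target = "TERT",
                                   reference = "GAPDH", base_level = 1,
                                   ref_level = 1) {
  stopifnot(!is.null(names(fold)), all(fold > 0))
  grid <- expand.grid(sample = samples, condition = names(fold),
                      stringsAsFactors = FALSE)
  rbind(
    data.frame(grid, target = target,
               amount = base_level * fold[grid$condition],
               row.names = NULL),
    data.frame(grid, target = reference, amount = ref_level, row.names = NULL)
  )
}

#' @rdname qpcr_designs
#' @param expression_ratio C/G expression ratio on cDNA.
#' @param copy_ratio C/G genomic copy-number ratio (gDNA template split).
#' @param total_expression total target template on cDNA.
#' @export
qpcr_allelic_design <- function(samples, expression_ratio = 1,
                                copy_ratio = 1, total_expression = 1,
                                target = "TERT_allelic", reference = "GAPDH",
                                ref_level = 1) {
  stopifnot(expression_ratio > 0, copy_ratio > 0)
  split2 <- function(ratio, total) {
    c(C = total * ratio / (1 + ratio), G = total / (1 + ratio))
  }
  expr <- split2(expression_ratio, total_expression)
  gdna <- split2(copy_ratio, 2)  # diploid: two genomic copies
  rows <- list()
  for (s in samples) {
    rows[[length(rows) + 1]] <- data.frame(
      sample = s, target = target, allele = c("C", "G"), condition = "baseline",
      template = "cDNA", amount = unname(expr))
    rows[[length(rows) + 1]] <- data.frame(
      sample = s, target = target, allele = c("C", "G"), condition = "baseline",
      template = "gDNA", amount = unname(gdna))
    rows[[length(rows) + 1]] <- data.frame(
      sample = s, target = reference, allele = NA_character_,
      condition = "baseline", template = "cDNA", amount = ref_level)
  }
  do.call(rbind, rows)
}

#' @rdname qpcr_designs
#' @param relative_length named vector: telomere content per condition
#'   relative to the calibrator condition (include the calibrator at 1).
#' @param scg_level single-copy-gene template amount.
#' @export
qpcr_telomere_design <- function(samples, relative_length,
                                 scg_level = 1, base_tel = 4) {
  stopifnot(!is.null(names(relative_length)), all(relative_length > 0))
  grid <- expand.grid(sample = samples, condition = names(relative_length),
                      stringsAsFactors = FALSE)
  rbind(
    data.frame(grid, target = "TEL",
               amount = base_tel * relative_length[grid$condition],
               template = "gDNA", row.names = NULL),
    data.frame(grid, target = "SCG", amount = scg_level, template = "gDNA",
               row.names = NULL)
  )
}
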