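#' Relative telomere length from telomere / single-copy-gene qPCR
#'
#' For each (sample, condition), dCt = mean Ct(telomere target) - mean
#' Ct(single-copy gene) and T/S = 2^-dCt, proportional to average telomere
#' length. Relative length is T/S divided by the same sample's T/S under the
#' calibrator condition (so the calibrator itself is exactly 1). SEM is
#' propagated from replicate Ct variances by the delta method.
#'
#' @param ct long Ct table with columns `sample`, `target`, `condition`,
#'   `replicate`, `ct`; telomere and single-copy-gene wells identified by
#'   `tel_target` and `scg_target`.
#' @param calibrator_condition condition defining relative length 1.
#' @param tel_target,scg_target target labels (defaults `"TEL"`, `"SCG"`).
#' @return data.frame per (sample, condition): `ts_ratio`,
#'   `relative_length`, `relative_length_sem`, `n_tel`, `n_scg`.
#' @export
ts_ratio <- function(ct, calibrator_condition, tel_target = "TEL",
                     scg_target = "SCG") {
  .check_ct(ct)
  sub <- ct[ct$target %in% c(tel_target, scg_target), ]
  groups <- unique(sub[, c("sample", "condition")])
  if (!calibrator_condition %in% groups$condition) {
    stop("calibrator condition not present: ", calibrator_condition)
  }
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    s <- groups$sample[k]; cond <- groups$condition[k]
    tel <- sub$ct[sub$sample == s & sub$condition == cond & sub$target == tel_target]
    scg <- sub$ct[sub$sample == s & sub$condition == cond & sub$target == scg_target]
    if (!length(tel)) stop(sprintf("missing telomere wells for sample '%s', condition '%s'", s, cond))
    if (!length(scg)) stop(sprintf("missing single-copy-gene wells for sample '%s', condition '%s'", s, cond))
    dct <- mean(tel) - mean(scg)
    dct_var <- .nz(stats::var(tel)) / length(tel) + .nz(stats::var(scg)) / length(scg)
    data.frame(sample = s, condition = cond, ts_ratio = 2^(-dct),
               dct_var = dct_var, n_tel = length(tel), n_scg = length(scg),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  cal <- res[res$condition == calibrator_condition, ]
  ci <- match(res$sample, cal$sample)
  if (anyNA(ci)) {
    stop("calibrator condition missing for sample(s): ",
         paste(unique(res$sample[is.na(ci)]), collapse = ", "))
  }
  res$relative_length <- res$ts_ratio / cal$ts_ratio[ci]
  rel_var <- res$dct_var + ifelse(res$condition == calibrator_condition,
                                  0, cal$dct_var[ci])
  res$relative_length_sem <- res$relative_length * log(2) * sqrt(rel_var)
  res$dct_var <- NULL
  res
}
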