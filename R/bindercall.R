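#' Allele-oriented log2 ratios from one pulldown run
#'
#' Maps isotope channels to alleles using the run's label orientation and
#' returns log2(C/G) per protein, so that a positive ratio always means
#' C-preference regardless of which physical channel carried the C bait.
#' Proteins quantified in neither channel (both intensities zero) are dropped
#' and logged; a single zero intensity is floored at half the smallest
#' positive intensity in the run (MaxQuant-style tables contain zeros).
#'
#' @param run data.frame with columns `protein`, `intensity_heavy`,
#'   `intensity_light`; non-negative intensities.
#' @param orientation `"forward"` (heavy channel = C-allele bait) or
#'   `"reverse"`; defaults to the run's `orientation` attribute.
#' @param floor optional explicit replacement for zero intensities.
#' @return data.frame `protein`, `log2_c_over_g`; attribute `dropped` lists
#'   proteins removed with reasons.
#' @export
compute_log_ratios <- function(run, orientation = attr(run, "orientation"),
                               floor = NULL) {
  stopifnot(is.data.frame(run),
            all(c("protein", "intensity_heavy", "intensity_light") %in% names(run)))
  if (is.null(orientation) || !orientation %in% c("forward", "reverse")) {
    stop("run orientation must be 'forward' or 'reverse'")
  }
  if (any(run$intensity_heavy < 0 | run$intensity_light < 0)) {
    stop("intensities must be non-negative")
  }
  int_c <- if (orientation == "forward") run$intensity_heavy else run$intensity_light
  int_g <- if (orientation == "forward") run$intensity_light else run$intensity_heavy
  both_zero <- int_c == 0 & int_g == 0
  dropped <- data.frame(protein = run$protein[both_zero],
                        reason = rep("zero intensity in both channels",
                                     sum(both_zero)),
                        stringsAsFactors = FALSE)
  int_c <- int_c[!both_zero]; int_g <- int_g[!both_zero]
  protein <- run$protein[!both_zero]
  if (is.null(floor)) {
    pos <- c(int_c[int_c > 0], int_g[int_g > 0])
    floor <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  }
  int_c[int_c == 0] <- floor
  int_g[int_g == 0] <- floor
  out <- data.frame(protein = protein, log2_c_over_g = log2(int_c / int_g),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Median-centre a vector of log ratios
#'
#' Centres ratios so their median is zero, removing any global channel bias
#' of a run; shift-invariant in the sense that adding a constant to the
#' input leaves the output unchanged.
#'
#' @param ratios numeric vector with at least 2 finite values.
#' @return centred numeric vector.
#' @export
normalize_ratios <- function(ratios) {
  finite <- is.finite(ratios)
  if (sum(finite) < 2) stop("need at least 2 finite ratios to normalize")
  ratios - stats::median(ratios[finite])
}

#' Tukey-fence outlier flags for log ratios
#'
#' Flags each ratio as an upper outlier (`> Q3 + k*IQR`), lower outlier
#' (`< Q1 - k*IQR`) or neither. Quartiles use linear interpolation of order
#' statistics at position `(n - 1) p + 1` (R's default type-7 convention);
#' the fences use strict inequality, so values exactly on a fence are not
#' flagged (a constant vector yields no flags).
#'
#' @param ratios numeric vector, length >= 4.
#' @param k fence multiplier in IQR units (default 1.5).
#' @return data.frame `ratio`, `flag` (factor upper/lower/none); attribute
#'   `fences` = c(lower, upper) and `quartiles`.
#' @export
call_outliers <- function(ratios, k = 1.5) {
  if (length(ratios) < 4) stop("need at least 4 ratios to set IQR fences")
  q <- stats::quantile(ratios, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  flag <- ifelse(ratios > fences["upper"], "upper",
                 ifelse(ratios < fences["lower"], "lower", "none"))
  out <- data.frame(ratio = ratios,
                    flag = factor(flag, levels = c("upper", "lower", "none")))
  attr(out, "fences") <- fences
  attr(out, "quartiles") <- c(q1 = q[1], q3 = q[2])
  out
}

#' Classify allele-preferential binders from two label-swap runs
#'
#' Applies the concordance rule: a protein is called C-preferential only when
#' it is an upper outlier (toward C, in allele-oriented coordinates) in both
#' the forward and the reverse run, G-preferential only when a lower outlier
#' in both; every other overlapping protein is non-differential. Proteins
#' present in only one run are reported non-differential with a
#' `"single-run"` note. Output is sorted by mean absolute log2 ratio,
#' descending.
#'
#' @param fwd,rev data.frames with columns `protein`, `ratio`, `flag`
#'   (as produced by [call_outliers()] joined to protein ids; see
#'   [call_binders()] for the one-call pipeline).
#' @return data.frame `protein`, `ratio_fwd`, `ratio_rev`, `flag_fwd`,
#'   `flag_rev`, `classification`, `note`.
#' @export
classify_binders <- function(fwd, rev) {
  stopifnot(all(c("protein", "ratio", "flag") %in% names(fwd)),
            all(c("protein", "ratio", "flag") %in% names(rev)))
  common <- intersect(fwd$protein, rev$protein)
  if (!length(common)) stop("no overlapping proteins between the two runs")
  fi <- match(common, fwd$protein); ri <- match(common, rev$protein)
  flag_f <- as.character(fwd$flag[fi]); flag_r <- as.character(rev$flag[ri])
  classification <- ifelse(flag_f == "upper" & flag_r == "upper", "C-preferential",
                           ifelse(flag_f == "lower" & flag_r == "lower",
                                  "G-preferential", "non-differential"))
  out <- data.frame(protein = common,
                    ratio_fwd = fwd$ratio[fi], ratio_rev = rev$ratio[ri],
                    flag_fwd = flag_f, flag_rev = flag_r,
                    classification = classification,
                    note = "", stringsAsFactors = FALSE)
  singles <- c(setdiff(fwd$protein, common), setdiff(rev$protein, common))
  if (length(singles)) {
    sf <- match(singles, fwd$protein); sr <- match(singles, rev$protein)
    out <- rbind(out, data.frame(
      protein = singles,
      ratio_fwd = ifelse(is.na(sf), NA_real_, fwd$ratio[sf]),
      ratio_rev = ifelse(is.na(sr), NA_real_, rev$ratio[sr]),
      flag_fwd = ifelse(is.na(sf), NA_character_, as.character(fwd$flag)[sf]),
      flag_rev = ifelse(is.na(sr), NA_character_, as.character(rev$flag)[sr]),
      classification = "non-differential", note = "single-run",
      stringsAsFactors = FALSE))
  }
  mean_abs <- rowMeans(cbind(abs(out$ratio_fwd), abs(out$ratio_rev)), na.rm = TRUE)
  out[order(-mean_abs), , drop = FALSE]
}

#' Full binder-calling pipeline for a pair of label-swap runs
#'
#' Runs [compute_log_ratios()], [normalize_ratios()] and [call_outliers()]
#' on each run, then [classify_binders()] on the pair.
#'
#' @param fwd_run,rev_run run tables as in [compute_log_ratios()].
#' @param k IQR fence multiplier (default 1.5).
#' @param floor zero-intensity replacement; see [compute_log_ratios()].
#' @return list with `calls` (the [classify_binders()] table), `fences`
#'   (per run) and `counts` (calls per class).
#' @export
call_binders <- function(fwd_run, rev_run, k = 1.5, floor = NULL) {
  one <- function(run) {
    lr <- compute_log_ratios(run, floor = floor)
    lr$ratio <- normalize_ratios(lr$log2_c_over_g)
    fl <- call_outliers(lr$ratio, k = k)
    data.frame(protein = lr$protein, ratio = lr$ratio, flag = fl$flag,
               stringsAsFactors = FALSE) |>
      structure(fences = attr(fl, "fences"))
  }
  f <- one(fwd_run); r <- one(rev_run)
  calls <- classify_binders(f, r)
  counts <- table(factor(calls$classification,
                         levels = c("C-preferential", "G-preferential",
                                    "non-differential")))
  list(calls = calls,
       fences = list(forward = attr(f, "fences"), reverse = attr(r, "fences")),
       counts = as.list(counts))
}
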