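#' Simulate a paired label-swap DNA-pulldown proteomics experiment
#'
#' Generates per-protein channel intensities for a forward and a reverse
#' label-swap run of an allele-specific DNA pulldown. Background proteins
#' bind both allele baits equally in expectation; planted allele-preferential
#' binders carry a log2 allele effect that follows the allele (not the
#' isotope channel) across the swap, as a true binder would. Intensities are
#' log-normal; per-run noise is independent between the two runs.
#'
#' In the forward run the heavy channel carries the C-allele bait; in the
#' reverse run the channels are swapped. Tables therefore report
#' `intensity_heavy` / `intensity_light` plus an `orientation` attribute,
#' exactly what the ratio computation must resolve.
#'
#' @param n_proteins total proteins (background + planted).
#' @param n_c_binders,n_g_binders planted C- and G-preferential binders.
#' @param effect log2(C/G) allele effect for planted binders (>= 0).
#' @param noise_sd per-run log2-intensity noise SD (> 0).
#' @param background_log2_mean,background_log2_sd distribution of baseline
#'   log2 abundance across proteins.
#' @param competitor metadata string carried on the runs (e.g.
#'   `"poly-dAdT"`).
#' @param seed integer seed.
#' @return list with `forward`, `reverse` (data.frames: `protein`,
#'   `intensity_heavy`, `intensity_light`, with attribute `orientation`) and
#'   `truth` (data.frame: `protein`, `class` in C-preferential /
#'   G-preferential / non-differential).
#' @export
simulate_pulldown <- function(n_proteins = 1000, n_c_binders = 5,
                              n_g_binders = 0, effect = 2.0, noise_sd = 0.3,
                              background_log2_mean = 23,
                              background_log2_sd = 2,
                              competitor = "poly-dAdT", seed = NULL) {
  if (n_c_binders + n_g_binders > n_proteins) {
    stop("n_c_binders + n_g_binders must not exceed n_proteins")
  }
  if (effect < 0) stop("effect size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  gen <- function() {
    protein <- sprintf("P%04d", seq_len(n_proteins))
    class <- rep("non-differential", n_proteins)
    if (n_c_binders) class[seq_len(n_c_binders)] <- "C-preferential"
    if (n_g_binders) class[n_c_binders + seq_len(n_g_binders)] <- "G-preferential"
    delta <- ifelse(class == "C-preferential", effect,
                    ifelse(class == "G-preferential", -effect, 0))
    base <- stats::rnorm(n_proteins, background_log2_mean, background_log2_sd)
    one_run <- function(orientation) {
      log_c <- base + delta / 2 + stats::rnorm(n_proteins, 0, noise_sd)
      log_g <- base - delta / 2 + stats::rnorm(n_proteins, 0, noise_sd)
      if (orientation == "forward") {
        run <- data.frame(protein = protein, intensity_heavy = 2^log_c,
                          intensity_light = 2^log_g, stringsAsFactors = FALSE)
      } else {
        run <- data.frame(protein = protein, intensity_heavy = 2^log_g,
                          intensity_light = 2^log_c, stringsAsFactors = FALSE)
      }
      attr(run, "orientation") <- orientation
      attr(run, "competitor") <- competitor
      run
    }
    list(forward = one_run("forward"), reverse = one_run("reverse"),
         truth = data.frame(protein = protein, class = class,
                            stringsAsFactors = FALSE))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
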