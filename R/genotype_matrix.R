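#' Genotype matrix container
#'
#' Samples-by-variants additive-coded genotypes (count of the alternate /
#' minor allele, 0/1/2, `NA` for missing) together with per-variant metadata:
#' id, chromosome, 1-based position, ref/alt alleles, minor-allele frequency
#' and (optionally) an imputation INFO score in `[0, 1]`.
#'
#' @param genotypes integer matrix, rows = samples, columns = variants;
#'   values in {0, 1, 2, NA}.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf` and optionally `info`.
#' @param sample_ids character vector; defaults to `rownames(genotypes)` or
#'   `sample1, ...`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, variants, sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt", "maf") %in% names(variants)),
            ncol(genotypes) == nrow(variants))
  if (is.null(sample_ids)) {
    sample_ids <- rownames(genotypes)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(genotypes)))
  }
  stopifnot(length(sample_ids) == nrow(genotypes), !anyDuplicated(sample_ids),
            !anyDuplicated(variants$id))
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("genotype values must be 0, 1, 2 or NA")
  if (any(variants$maf < 0 | variants$maf > 0.5)) {
    stop("variant MAF must lie in [0, 0.5]")
  }
  if (!is.null(variants$info) &&
      any(variants$info < 0 | variants$info > 1, na.rm = TRUE)) {
    stop("INFO scores must lie in [0, 1]")
  }
  for (ch in unique(variants$chrom)) {
    pos <- variants$pos[variants$chrom == ch]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("variant positions must be strictly increasing within a chromosome")
    }
  }
  dimnames(genotypes) <- list(sample_ids, variants$id)
  structure(list(genotypes = genotypes, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d samples x %d variants (%s:%s-%s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              x$variants$chrom[1], format(min(x$variants$pos), big.mark = ","),
              format(max(x$variants$pos), big.mark = ",")))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$genotypes))
  if (missing(j)) j <- seq_len(ncol(x$genotypes))
  genotype_matrix(x$genotypes[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  sample_ids = x$sample_ids[i])
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Sample diploid genotypes from a haplotype pool
#'
#' Each individual is formed from two independent haplotype draws from the
#' pool; genotypes are additive-coded counts of the minor allele.
#'
#' @param pool a [make_haplotype_pool()] object.
#' @param n number of individuals (>= 1).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param chrom chromosome label for the variant metadata.
#' @param positions 1-based positions; defaults to an evenly spaced grid
#'   starting at 1,306,281 (a chr5p15.33-like window).
#' @param info per-variant INFO scores carried into the metadata (default 1).
#' @return a [genotype_matrix()].
#' @export
sample_genotypes <- function(pool, n, seed = NULL, chrom = "chr5",
                             positions = NULL, info = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  m <- length(pool$variant_ids)
  if (is.null(positions)) positions <- 1306281L + 1000L * (seq_len(m) - 1L)
  if (is.null(info)) info <- rep(1, m)
  draw <- function() {
    idx <- sample.int(nrow(pool$haplotypes), 2L * n, replace = TRUE,
                      prob = pool$freq)
    h1 <- pool$haplotypes[idx[seq_len(n)], , drop = FALSE]
    h2 <- pool$haplotypes[idx[n + seq_len(n)], , drop = FALSE]
    list(genotypes = h1 + h2, haplotypes = rbind(h1, h2))
  }
  drawn <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  variants <- data.frame(id = pool$variant_ids, chrom = chrom,
                         pos = positions, ref = "G", alt = "C",
                         maf = unname(pool$allele_freqs), info = info,
                         stringsAsFactors = FALSE)
  G <- genotype_matrix(drawn$genotypes, variants)
  attr(G, "haplotypes") <- drawn$haplotypes  # phased truth, for LD checks
  G
}
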