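#' Linkage disequilibrium between two variants
#'
#' Computes r-squared and D' for a pair of biallelic variants, either from
#' phased haplotypes (frequencies counted directly) or from unphased
#' genotypes (two-locus haplotype frequencies estimated by EM, the classic
#' gene-counting algorithm: the only ambiguous class is the double
#' heterozygote, split between cis and trans configurations by its expected
#' fraction under the current frequencies). With
#' \eqn{D = p_{AB} - p_A p_B}: \eqn{r^2 = D^2 / (p_A q_A p_B q_B)} and
#' \eqn{D' = |D| / D_{max}} where \eqn{D_{max} = \min(p_A q_B, q_A p_B)} for
#' \eqn{D > 0} and \eqn{\min(p_A p_B, q_A q_B)} otherwise.
#'
#' @param x a [genotype_matrix()] (unphased path), a two-column 0/1 haplotype
#'   matrix (phased path, one row per haplotype), or a [make_haplotype_pool()]
#'   object (exact population frequencies).
#' @param i,j variant ids (genotype matrix / pool) or column indices.
#' @param phased for a plain matrix input: treat rows as haplotypes
#'   (`TRUE`) or as unphased genotypes (`FALSE`).
#' @return list of class `ld_pair`: `r2`, `d_prime`, `D`, haplotype
#'   frequencies `p11`, `p10`, `p01`, `p00`, allele frequencies, `phase`
#'   (`"known"` or `"EM"`) and for EM the number of iterations.
#' @examples
#' haps <- rbind(matrix(1, 50, 2), matrix(0, 50, 2))
#' ld_pair(haps, 1, 2, phased = TRUE)$r2  # 1: perfect LD
#' @export
ld_pair <- function(x, i, j, phased = FALSE) {
  if (inherits(x, "haplotype_pool")) {
    out <- pool_ld(x, i, j)
    out$phase <- "known"
    class(out) <- "ld_pair"
    return(out)
  }
  if (inherits(x, "genotype_matrix")) {
    ii <- match(i, x$variants$id); jj <- match(j, x$variants$id)
    if (is.na(ii) || is.na(jj)) stop("unknown variant id")
    g <- x$genotypes[, c(ii, jj), drop = FALSE]
    return(.ld_unphased(g[, 1], g[, 2]))
  }
  x <- as.matrix(x)
  a <- x[, i]; b <- x[, j]
  if (phased) {
    if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
      stop("phased input must be 0/1 haplotypes")
    }
    n <- length(a)
    out <- .ld_from_hap_freqs(sum(a == 1 & b == 1) / n, sum(a == 1 & b == 0) / n,
                              sum(a == 0 & b == 1) / n, sum(a == 0 & b == 0) / n)
    out$phase <- "known"
    class(out) <- "ld_pair"
    return(out)
  }
  .ld_unphased(a, b)
}

.ld_unphased <- function(gA, gB, tol = 1e-10, max_iter = 1000L) {
  keep <- !is.na(gA) & !is.na(gB)
  gA <- gA[keep]; gB <- gB[keep]
  n <- length(gA)
  if (!n) stop("no complete genotype pairs")
  cnt <- matrix(0, 3, 3)  # cnt[a+1, b+1] = # individuals with genotypes (a, b)
  for (a in 0:2) for (b in 0:2) cnt[a + 1, b + 1] <- sum(gA == a & gB == b)
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("LD undefined: monomorphic locus")
  }
  # start at linkage equilibrium
  f <- c(p11 = pA * pB, p10 = pA * (1 - pB), p01 = (1 - pA) * pB,
         p00 = (1 - pA) * (1 - pB))
  loglik <- -Inf
  iters <- 0L
  repeat {
    iters <- iters + 1L
    cis <- f["p11"] * f["p00"]
    trans <- f["p10"] * f["p01"]
    cshare <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    n11 <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3] + cshare * cnt[2, 2]
    n10 <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1] + (1 - cshare) * cnt[2, 2]
    n01 <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2] + (1 - cshare) * cnt[2, 2]
    n00 <- 2 * cnt[1, 1] + cnt[2, 1] + cnt[1, 2] + cshare * cnt[2, 2]
    f <- stats::setNames(c(n11, n10, n01, n00) / (2 * n),
                         c("p11", "p10", "p01", "p00"))
    ll <- .ld_em_loglik(cnt, f)
    if (abs(ll - loglik) < tol || iters >= max_iter) break
    loglik <- ll
  }
  out <- .ld_from_hap_freqs(f["p11"], f["p10"], f["p01"], f["p00"])
  out$phase <- "EM"
  out$iterations <- iters
  class(out) <- "ld_pair"
  out
}

# multinomial log-likelihood of the 3x3 genotype table under HWE hap freqs,
# by direct enumeration of the two gametes
.ld_em_loglik <- function(cnt, f) {
  pg <- matrix(0, 3, 3)
  hap_p <- function(a, b) f[[c("p00", "p01", "p10", "p11")[1 + 2 * a + b]]]
  for (a in 0:2) for (b in 0:2) {
    acc <- 0
    for (a1 in 0:1) for (b1 in 0:1) {
      a2 <- a - a1; b2 <- b - b1
      if (a2 >= 0 && a2 <= 1 && b2 >= 0 && b2 <= 1) {
        acc <- acc + hap_p(a1, b1) * hap_p(a2, b2)
      }
    }
    pg[a + 1, b + 1] <- acc
  }
  sum(cnt[cnt > 0] * log(pg[cnt > 0]))
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("LD pair (%s): r2 = %.4g, D' = %.4g, D = %.4g\n",
              x$phase, x$r2, x$d_prime, x$D))
  invisible(x)
}
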