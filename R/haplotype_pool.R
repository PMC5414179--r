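#' Construct a haplotype pool with exact pairwise linkage disequilibrium
#'
#' Builds a population haplotype frequency table over biallelic variants such
#' that each variant's minor-allele frequency and every requested pairwise
#' r-squared are met exactly at the population level. LD is imposed by a
#' conditional-independence construction along the edges of the target graph,
#' with the two-locus haplotype frequencies solved in closed form from
#' \eqn{D = r \sqrt{p_A q_A p_B q_B}}. The target graph must therefore be
#' acyclic (a forest); a typical fine-mapping block is a "star" of proxies
#' around an index variant, which is a forest.
#'
#' @param allele_freqs numeric vector of minor-allele frequencies, each in
#'   (0, 0.5]. Names, if present, are used as variant ids.
#' @param ld_targets `NULL`, or a data.frame with columns `i`, `j` (variant
#'   ids or indices) and `r2` in `[0, 1]`; an optional `sign` column (+1/-1,
#'   default +1) gives the sign of the allelic correlation (positive means
#'   minor alleles co-occur).
#' @param variant_ids character vector of ids; defaults to
#'   `names(allele_freqs)` or `snp1, snp2, ...`.
#'
#' @return An object of class `haplotype_pool`: a list with `haplotypes`
#'   (0/1 matrix, one row per distinct haplotype), `freq` (summing to 1),
#'   `variant_ids` and `allele_freqs`.
#'
#' @details Each requested r-squared must be achievable given the two allele
#'   frequencies: the implied `D` must satisfy
#'   `-min(pA*pB, qA*qB) <= D <= min(pA*qB, qA*pB)`. Infeasible targets raise
#'   an error naming the pair. At most 16 variants are supported because the
#'   pool is enumerated exhaustively.
#'
#' @examples
#' pool <- make_haplotype_pool(c(a = 0.2, b = 0.2),
#'                             ld_targets = data.frame(i = "a", j = "b", r2 = 1))
#' pool$freq  # 0.2, 0.8: perfect LD forces co-segregation
#' @export
make_haplotype_pool <- function(allele_freqs, ld_targets = NULL,
                                variant_ids = NULL) {
  if (is.null(variant_ids)) {
    variant_ids <- names(allele_freqs)
    if (is.null(variant_ids)) {
      variant_ids <- paste0("snp", seq_along(allele_freqs))
    }
  }
  m <- length(allele_freqs)
  stopifnot(length(variant_ids) == m, !anyDuplicated(variant_ids))
  if (any(allele_freqs <= 0 | allele_freqs > 0.5)) {
    stop("allele_freqs must lie strictly in (0, 0.5]")
  }
  if (m > 16L) {
    stop("haplotype pools are enumerated exhaustively; at most 16 variants supported")
  }
  p <- unname(allele_freqs)

  edges <- .normalize_ld_targets(ld_targets, variant_ids)
  # validate feasibility and forest-ness, then root each tree by BFS; the
  # signed two-locus correlation is symmetric so edges may be rooted either way
  adj <- vector("list", m)
  if (nrow(edges)) {
    comp <- seq_len(m)
    for (k in seq_len(nrow(edges))) {
      i <- edges$i[k]; j <- edges$j[k]
      if (comp[i] == comp[j]) {
        stop(sprintf("LD target graph has a cycle involving '%s' and '%s'; only acyclic (forest) target sets are supported",
                     variant_ids[i], variant_ids[j]))
      }
      comp[comp == comp[j]] <- comp[i]
      r <- edges$sign[k] * sqrt(edges$r2[k])
      D <- r * sqrt(p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
      Dmax <- min(p[i] * (1 - p[j]), (1 - p[i]) * p[j])
      Dmin <- -min(p[i] * p[j], (1 - p[i]) * (1 - p[j]))
      if (D > Dmax + 1e-12 || D < Dmin - 1e-12) {
        stop(sprintf("infeasible r2 target %.4g between '%s' (MAF %.3g) and '%s' (MAF %.3g): implied D=%.4g outside [%.4g, %.4g]",
                     edges$r2[k], variant_ids[i], p[i], variant_ids[j], p[j],
                     D, Dmin, Dmax))
      }
      adj[[i]] <- c(adj[[i]], list(list(to = j, r = r)))
      adj[[j]] <- c(adj[[j]], list(list(to = i, r = r)))
    }
  }
  parent <- rep(NA_integer_, m)
  edge_r <- rep(NA_real_, m)
  visited <- rep(FALSE, m)
  for (root in seq_len(m)) {
    if (visited[root]) next
    queue <- root; visited[root] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (e in adj[[u]]) {
        if (!visited[e$to]) {
          visited[e$to] <- TRUE
          parent[e$to] <- u
          edge_r[e$to] <- e$r
          queue <- c(queue, e$to)
        }
      }
    }
  }

  haps <- as.matrix(expand.grid(rep(list(c(0L, 1L)), m))[, seq_len(m), drop = FALSE])
  dimnames(haps) <- list(NULL, variant_ids)
  freq <- rep(1, nrow(haps))
  ord <- .topo_order(parent)
  for (v in ord) {
    if (is.na(parent[v])) {
      freq <- freq * ifelse(haps[, v] == 1L, p[v], 1 - p[v])
    } else {
      u <- parent[v]
      D <- edge_r[v] * sqrt(p[u] * (1 - p[u]) * p[v] * (1 - p[v]))
      p1g1 <- (p[u] * p[v] + D) / p[u]          # P(child=1 | parent=1)
      p1g0 <- ((1 - p[u]) * p[v] - D) / (1 - p[u])
      p1g1 <- min(max(p1g1, 0), 1)
      p1g0 <- min(max(p1g0, 0), 1)
      cond <- ifelse(haps[, u] == 1L,
                     ifelse(haps[, v] == 1L, p1g1, 1 - p1g1),
                     ifelse(haps[, v] == 1L, p1g0, 1 - p1g0))
      freq <- freq * cond
    }
  }
  keep <- freq > 0
  pool <- structure(list(haplotypes = haps[keep, , drop = FALSE],
                         freq = freq[keep],
                         variant_ids = variant_ids,
                         allele_freqs = stats::setNames(p, variant_ids)),
                    class = "haplotype_pool")
  # construction-level self checks: marginals and targeted r2 are exact
  marg <- drop(crossprod(pool$haplotypes, pool$freq))
  stopifnot(all(abs(marg - p) < 1e-9))
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      got <- pool_ld(pool, variant_ids[edges$i[k]], variant_ids[edges$j[k]])$r2
      stopifnot(abs(got - edges$r2[k]) < 1e-6)
    }
  }
  pool
}

.normalize_ld_targets <- function(ld_targets, variant_ids) {
  if (is.null(ld_targets) || (is.data.frame(ld_targets) && !nrow(ld_targets))) {
    return(data.frame(i = integer(), j = integer(), r2 = numeric(),
                      sign = numeric()))
  }
  stopifnot(is.data.frame(ld_targets), all(c("i", "j", "r2") %in% names(ld_targets)))
  to_idx <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    idx <- match(x, variant_ids)
    if (anyNA(idx)) stop("unknown variant id in ld_targets: ",
                         paste(x[is.na(idx)], collapse = ", "))
    idx
  }
  out <- data.frame(i = to_idx(ld_targets$i), j = to_idx(ld_targets$j),
                    r2 = as.numeric(ld_targets$r2))
  out$sign <- if ("sign" %in% names(ld_targets)) sign(ld_targets$sign) else 1
  if (any(out$r2 < 0 | out$r2 > 1)) stop("r2 targets must lie in [0, 1]")
  if (any(out$i == out$j)) stop("ld_targets must pair distinct variants")
  out[out$r2 > 0, , drop = FALSE]  # r2 = 0 is the default (independence)
}

.topo_order <- function(parent) {
  m <- length(parent)
  ord <- integer(0)
  placed <- rep(FALSE, m)
  while (length(ord) < m) {
    ok <- vapply(seq_len(m),
                 function(v) !placed[v] && (is.na(parent[v]) || placed[parent[v]]),
                 logical(1))
    ready <- which(ok)
    if (!length(ready)) stop("internal error: cyclic parent structure")
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  ord
}

#' Population LD between two variants of a haplotype pool
#'
#' Exact r-squared and D' computed from the pool's haplotype frequency table.
#'
#' @param pool a [make_haplotype_pool()] object.
#' @param i,j variant ids or indices.
#' @return list with `r2`, `d_prime`, `D` and the two-locus haplotype
#'   frequencies `p11`, `p10`, `p01`, `p00`.
#' @export
pool_ld <- function(pool, i, j) {
  ii <- if (is.character(i)) match(i, pool$variant_ids) else as.integer(i)
  jj <- if (is.character(j)) match(j, pool$variant_ids) else as.integer(j)
  if (is.na(ii) || is.na(jj)) stop("unknown variant id")
  a <- pool$haplotypes[, ii]; b <- pool$haplotypes[, jj]
  p11 <- sum(pool$freq[a == 1 & b == 1])
  p10 <- sum(pool$freq[a == 1 & b == 0])
  p01 <- sum(pool$freq[a == 0 & b == 1])
  p00 <- sum(pool$freq[a == 0 & b == 0])
  .ld_from_hap_freqs(p11, p10, p01, p00)
}

# shared two-locus arithmetic: D, D', r2 from the four haplotype frequencies
.ld_from_hap_freqs <- function(p11, p10, p01, p00) {
  p11 <- unname(p11); p10 <- unname(p10); p01 <- unname(p01); p00 <- unname(p00)
  tot <- p11 + p10 + p01 + p00
  p11 <- p11 / tot; p10 <- p10 / tot; p01 <- p01 / tot; p00 <- p00 / tot
  pA <- p11 + p10; pB <- p11 + p01
  qA <- 1 - pA; qB <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("LD undefined: monomorphic locus")
  }
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  d_prime <- if (dmax == 0) 0 else abs(D) / dmax
  r2 <- D^2 / (pA * qA * pB * qB)
  list(r2 = r2, d_prime = d_prime, D = D,
       p11 = p11, p10 = p10, p01 = p01, p00 = p00,
       pA = pA, pB = pB)
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype pool: %d variants, %d distinct haplotypes\n",
              length(x$variant_ids), nrow(x$haplotypes)))
  cat("MAF:", paste(sprintf("%s=%.3g", x$variant_ids, x$allele_freqs),
                    collapse = ", "), "\n")
  invisible(x)
}
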