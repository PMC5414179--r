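#' Variant quality-control filter
#'
#' Retains variants with minor-allele frequency at or above `maf_min` and,
#' when an imputation INFO score is present, INFO at or above `info_min`;
#' variants with no INFO score pass the INFO criterion. Thresholds are
#' inclusive at the boundary. Default thresholds (MAF 0.01, INFO 0.5) are the
#' standard post-imputation filters for fine-mapping.
#'
#' @param variants data.frame with columns `id`, `maf` and optionally `info`
#'   (NA = absent), e.g. the `$variants` slot of a [genotype_matrix()].
#' @param maf_min,info_min inclusive thresholds.
#' @return list with `retained` (subset of `variants`) and `excluded`
#'   (dropped rows plus a `reason` column: `"low_maf"`, `"low_info"` or
#'   `"low_maf;low_info"`).
#' @export
variant_qc_filter <- function(variants, maf_min = 0.01, info_min = 0.5) {
  stopifnot(is.data.frame(variants))
  if (!nrow(variants)) {
    return(list(retained = variants,
                excluded = cbind(variants, reason = character(0))))
  }
  stopifnot(all(c("id", "maf") %in% names(variants)))
  info <- if ("info" %in% names(variants)) variants$info else rep(NA_real_, nrow(variants))
  low_maf <- variants$maf < maf_min
  low_info <- !is.na(info) & info < info_min
  reason <- ifelse(low_maf & low_info, "low_maf;low_info",
                   ifelse(low_maf, "low_maf",
                          ifelse(low_info, "low_info", NA_character_)))
  keep <- !(low_maf | low_info)
  excluded <- variants[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(retained = variants[keep, , drop = FALSE], excluded = excluded)
}

#' Logistic score test of a log-additive genetic effect
#'
#' Tests a single additive-coded genotype against a binary phenotype using
#' the 1-df efficient score test evaluated at the covariate-only null fit:
#' with null fitted probabilities \eqn{\hat p} and weights
#' \eqn{w = \hat p (1 - \hat p)}, the score is
#' \eqn{U = g^\top (y - \hat p)} and the efficient variance is the variance of
#' the genotype's score after projection onto the covariate space,
#' \eqn{V = g^\top W g - g^\top W X (X^\top W X)^{-1} X^\top W g}.
#' \eqn{U^2 / V} is referred to chi-square with 1 df. The effect estimate
#' (log OR) and its SE are taken from the alternative-model logistic fit.
#'
#' Rows with a missing genotype or covariate are dropped pairwise for this
#' test. Conditioning on other variants is done by passing their genotype
#' columns in `X`.
#'
#' @param g additive-coded genotype vector (0/1/2, NA allowed).
#' @param y binary phenotype (0/1), both classes present.
#' @param X optional covariate matrix (no intercept column; an intercept is
#'   always included).
#' @param alt_fit fit the alternative model for beta/SE? Set `FALSE` to
#'   return the score statistic and p-value only (faster in large
#'   simulation loops).
#' @return list of class `score_test` with `beta`, `se`, `score_stat`,
#'   `p_value`, `n`, and `beta_reliable` (FALSE when the alternative fit
#'   shows signs of separation; the score p-value is unaffected).
#' @examples
#' score_test(c(0, 1, 2, 0, 1, 2), c(0, 0, 1, 0, 1, 1))  # statistic 4, p 0.0455
#' @export
score_test <- function(g, y, X = NULL, alt_fit = TRUE) {
  keep <- !is.na(g) & !is.na(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    keep <- keep & stats::complete.cases(X)
    X <- X[keep, , drop = FALSE]
  }
  g <- g[keep]; y <- y[keep]
  if (length(unique(y)) < 2) stop("degenerate phenotype: y must contain both classes")
  if (length(unique(g)) < 2) stop("monomorphic variant: genotype is constant")
  null <- .fit_null(y, X)
  res <- .score_from_null(g, y, X, null)
  out <- list(beta = NA_real_, se = NA_real_, score_stat = res$stat,
              p_value = res$p, n = length(y), beta_reliable = NA)
  if (alt_fit) {
    alt <- .fit_alternative(g, y, X)
    out$beta <- alt$beta; out$se <- alt$se; out$beta_reliable <- alt$reliable
  }
  class(out) <- "score_test"
  out
}

# covariate-only null fit; intercept-only has the closed-form MLE mean(y)
.fit_null <- function(y, X) {
  if (is.null(X) || ncol(X) == 0) {
    p <- rep(mean(y), length(y))
    return(list(p = p, Xfull = matrix(1, length(y), 1)))
  }
  Xfull <- cbind(1, X)
  fit <- stats::glm.fit(Xfull, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("null logistic model did not converge")
  list(p = fit$fitted.values, Xfull = Xfull)
}

.score_from_null <- function(g, y, X, null) {
  p <- null$p; w <- p * (1 - p)
  Xf <- null$Xfull
  U <- sum(g * (y - p))
  A <- crossprod(Xf, Xf * w)             # X'WX
  q <- drop(crossprod(Xf, g * w))        # X'Wg
  V <- sum(w * g^2) - drop(crossprod(q, solve(A, q)))
  if (V <= 0) stop("monomorphic variant: genotype is constant after covariate projection")
  stat <- U^2 / V
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE), U = U, V = V)
}

.fit_alternative <- function(g, y, X) {
  Xalt <- if (is.null(X)) cbind(1, g) else cbind(1, X, g)
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xalt, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
  k <- ncol(Xalt)
  beta <- fit$coefficients[k]
  se <- tryCatch({
    wts <- fit$weights
    cov <- solve(crossprod(Xalt, Xalt * wts))
    sqrt(cov[k, k])
  }, error = function(e) NA_real_)
  reliable <- fit$converged && !warned && is.finite(se) && abs(beta) < 15
  list(beta = unname(beta), se = unname(se), reliable = reliable)
}

#' @export
print.score_test <- function(x, ...) {
  cat(sprintf("score test: chi2(1) = %.4g, p = %.4g, n = %d\n",
              x$score_stat, x$p_value, x$n))
  if (!is.na(x$beta)) {
    cat(sprintf("  log OR = %.4g (SE %.4g)%s\n", x$beta, x$se,
                if (isFALSE(x$beta_reliable)) " [unreliable: possible separation]" else ""))
  }
  invisible(x)
}

#' Single-SNP and conditional association scan over a region
#'
#' Runs the logistic score test for every variant of a genotype matrix,
#' optionally conditioning on a set of variants by appending their genotypes
#' to the covariates. Conditioning variants are reported with `p_value = NA`.
#'
#' @param G a [genotype_matrix()].
#' @param y binary phenotype aligned to the rows of `G`.
#' @param X optional covariate matrix (no intercept).
#' @param condition_on character vector of variant ids to condition on.
#' @param alt_fit fit alternative models for beta/SE (see [score_test()]).
#' @return data.frame with one row per variant: `variant`, `beta`, `se`,
#'   `score_stat`, `p_value`, `n`, `conditioned_on` (comma-separated ids).
#' @export
association_scan <- function(G, y, X = NULL, condition_on = character(0),
                             alt_fit = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- G$variants$id
  absent <- setdiff(condition_on, ids)
  if (length(absent)) {
    stop("conditioning variant(s) not in genotype matrix: ",
         paste(absent, collapse = ", "))
  }
  Xc <- X
  if (length(condition_on)) {
    Gc <- G$genotypes[, condition_on, drop = FALSE]
    Xc <- if (is.null(X)) Gc else cbind(as.matrix(X), Gc)
  }
  cond_label <- paste(condition_on, collapse = ",")
  rows <- lapply(ids, function(v) {
    if (v %in% condition_on) {
      return(data.frame(variant = v, beta = NA_real_, se = NA_real_,
                        score_stat = NA_real_, p_value = NA_real_,
                        n = NA_integer_, conditioned_on = cond_label,
                        stringsAsFactors = FALSE))
    }
    st <- score_test(G$genotypes[, v], y, X = Xc, alt_fit = alt_fit)
    data.frame(variant = v, beta = st$beta, se = st$se,
               score_stat = st$score_stat, p_value = st$p_value,
               n = st$n, conditioned_on = cond_label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Variants correlated with an index variant above an r-squared threshold
#'
#' Computes unphased (EM-based) r-squared between the index variant and every
#' other variant of the matrix and returns the ids with r-squared strictly
#' greater than the threshold, sorted by position. The index itself is
#' excluded by convention even though its self r-squared is 1.
#'
#' @param G a [genotype_matrix()].
#' @param index_variant variant id.
#' @param r2_threshold strict lower bound (default 0.6).
#' @return character vector of variant ids.
#' @export
correlated_set <- function(G, index_variant, r2_threshold = 0.6) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- G$variants$id
  if (!index_variant %in% ids) {
    stop("index variant not in genotype matrix: ", index_variant)
  }
  others <- setdiff(ids, index_variant)
  r2 <- vapply(others, function(v) {
    tryCatch(ld_pair(G, index_variant, v)$r2, error = function(e) NA_real_)
  }, numeric(1))
  hits <- others[!is.na(r2) & r2 > r2_threshold]
  hits[order(G$variants$pos[match(hits, ids)])]
}
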