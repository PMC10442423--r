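# Per-SNP covariate-adjusted association, genomic inflation, and greedy LD
# clumping.
#
# Linear association is computed for all SNPs at once by Frisch-Waugh
# residualization (equivalent to per-SNP OLS of y on dosage + covariates);
# logistic association runs a compact IRLS per SNP warm-started from the
# covariate-only fit. Both are checked in the test suite against stats::lm,
# stats::glm and a generic optimizer as independent oracles.

# Build the covariate design (intercept + covariates) and its thin Q.
covar_q <- function(n, covariates) {
  X <- if (is.null(covariates)) {
    matrix(1, nrow = n, ncol = 1)
  } else {
    cbind(1, as.matrix(covariates))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("covariate matrix is rank deficient")
  list(X = X, Q = qr.Q(qr_x))
}

new_assoc_result <- function(map, beta, se, p, n_used, phenotype, excluded) {
  out <- data.frame(
    snp = map$snp, chrom = map$chrom, pos = map$pos,
    beta = beta, se = se, p = p, chi2 = (beta / se)^2,
    stringsAsFactors = FALSE
  )
  attr(out, "phenotype") <- phenotype
  attr(out, "n_used") <- n_used
  attr(out, "excluded") <- excluded
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Per-SNP linear association of a quantitative trait
#'
#' For each SNP, ordinary least squares of `y` on dosage plus covariates
#' (with intercept); two-sided p from the t statistic, floored at the
#' smallest positive double. SNPs below the MAF filter or monomorphic in
#' sample are excluded and listed in attribute `"excluded"`.
#'
#' @param panel A `genotype_panel`.
#' @param y Quantitative phenotype vector.
#' @param covariates Optional numeric data.frame/matrix of covariates.
#' @param min_maf Minimum in-sample minor allele frequency.
#' @param phenotype Tag stored on the result.
#' @return An `assoc_result` data.frame (snp, chrom, pos, beta, se, p, chi2).
#' @export
linear_assoc <- function(panel, y, covariates = NULL, min_maf = 0,
                         phenotype = "quantitative") {
  stopifnot(inherits(panel, "genotype_panel"), length(y) == panel$n_subjects)
  n <- panel$n_subjects
  cq <- covar_q(n, covariates)
  Q <- cq$Q
  k <- ncol(cq$X)

  G <- panel$dosages
  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= min_maf & maf > 0
  excluded <- panel$map$snp[!keep]
  G <- G[, keep, drop = FALSE]
  map <- panel$map[keep, , drop = FALSE]

  yr <- y - Q %*% crossprod(Q, y)
  Gr <- G - Q %*% crossprod(Q, G)
  gss <- colSums(Gr^2)
  beta <- colSums(Gr * as.vector(yr)) / gss
  df <- n - k - 1
  rss <- pmax(sum(yr^2) - beta^2 * gss, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gss)
  tstat <- beta / se
  p <- pmax(2 * stats::pt(-abs(tstat), df), P_FLOOR)
  new_assoc_result(map, beta, se, p, n, phenotype, excluded)
}

# IRLS logistic fit of y on fixed design X; returns coef, covariance and
# convergence/separation flags. Warm start keeps per-SNP cost low.
irls_logistic <- function(X, y, start = NULL, maxit = 30, tol = 1e-9) {
  p <- ncol(X)
  beta <- start %||% numeric(p)
  dev_old <- Inf
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(ok = FALSE, reason = "singular"))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, w * z)))
    eta <- as.vector(X %*% beta)
    dev <- -2 * sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  mu <- plogis(as.vector(X %*% beta))
  separated <- any(mu < 1e-10 | mu > 1 - 1e-10) || any(abs(beta) > 50)
  vcov <- chol2inv(chol(XtWX))
  list(ok = TRUE, beta = as.vector(beta), vcov = vcov,
       converged = converged, separated = separated)
}

#' Per-SNP logistic association of a binary trait
#'
#' IRLS maximum-likelihood logistic regression of case status on dosage plus
#' covariates for each SNP; Wald beta/SE/p. Monomorphic, non-converged or
#' separated SNPs are excluded from the result and listed with reasons in
#' attribute `"excluded"`.
#'
#' @inheritParams linear_assoc
#' @param case_flags Logical (or 0/1) case vector; both classes required.
#' @export
logistic_assoc <- function(panel, case_flags, covariates = NULL, min_maf = 0,
                           phenotype = "binary") {
  stopifnot(inherits(panel, "genotype_panel"))
  y <- as.numeric(as.logical(case_flags))
  if (length(y) != panel$n_subjects) stop("case_flags length mismatch")
  if (sum(y) == 0 || sum(y) == length(y)) stop("both classes must be present")
  n <- panel$n_subjects
  cq <- covar_q(n, covariates)
  C <- cq$X

  null_fit <- irls_logistic(C, y)
  if (!null_fit$ok) stop("covariate-only logistic fit failed")
  start <- c(null_fit$beta, 0)

  G <- panel$dosages
  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  M <- panel$n_snps
  beta <- se <- rep(NA_real_, M)
  reason <- character(M)
  X <- cbind(C, 0)
  jcol <- ncol(X)
  for (j in seq_len(M)) {
    if (maf[j] < min_maf || maf[j] == 0) {
      reason[j] <- "maf"
      next
    }
    X[, jcol] <- G[, j]
    fit <- irls_logistic(X, y, start = start)
    if (!fit$ok || !fit$converged) {
      reason[j] <- "nonconverged"
      next
    }
    if (fit$separated) {
      reason[j] <- "separation"
      next
    }
    beta[j] <- fit$beta[jcol]
    se[j] <- sqrt(fit$vcov[jcol, jcol])
  }
  keep <- is.na(reason) | reason == ""
  excluded <- data.frame(snp = panel$map$snp[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  map <- panel$map[keep, , drop = FALSE]
  beta <- beta[keep]
  se <- se[keep]
  z <- beta / se
  p <- pmax(2 * stats::pnorm(-abs(z)), P_FLOOR)
  new_assoc_result(map, beta, se, p, n, phenotype, excluded)
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` (the null median, ~0.4549).
#'
#' @param results An `assoc_result`, or a numeric vector of chi-square
#'   statistics.
#' @export
lambda_gc <- function(results) {
  chi2 <- if (inherits(results, "assoc_result")) results$chi2 else results
  if (length(chi2) == 0) stop("no test statistics supplied")
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Clumping parameters
#'
#' Defaults follow the standard genome-wide clumping configuration: index
#' threshold `p1 = 5e-8`, secondary threshold `p2 = 1e-4`, `r2 >= 0.1`,
#' 250 kb window.
#' @param p1,p2 Index and member p-value thresholds (`p1 <= p2`).
#' @param r2_max LD threshold at or above which a SNP is absorbed.
#' @param window_kb Physical window around the index SNP.
#' @export
clump_params <- function(p1 = 5e-8, p2 = 1e-4, r2_max = 0.1, window_kb = 250) {
  stopifnot(p1 <= p2, r2_max > 0, r2_max < 1, window_kb > 0)
  structure(list(p1 = p1, p2 = p2, r2_max = r2_max, window_kb = window_kb),
            class = "clump_params")
}

#' Greedy LD clumping of association results
#'
#' Index SNPs are taken in ascending p (ties by position, then id) among
#' SNPs with `p <= p1`; each index absorbs the not-yet-assigned SNPs with
#' `p <= p2` on the same chromosome, within `window_kb`, and with dosage
#' `r^2 >=` `r2_max` of the index. The locus count is the number of indices.
#'
#' @param results An `assoc_result`.
#' @param panel The `genotype_panel` the r^2 values are computed on.
#' @param params A [clump_params()].
#' @return A list of class `locus_set`: `indices` data.frame (index SNP row
#'   plus `n_members`, `min_p`), `members` list of member SNP ids, `count`.
#' @export
greedy_clump <- function(results, panel, params = clump_params()) {
  stopifnot(inherits(results, "assoc_result"), inherits(panel, "genotype_panel"))
  if (anyNA(results$pos)) stop("missing positions in results")
  res <- as.data.frame(results)
  res$col <- match(res$snp, panel$map$snp)
  if (anyNA(res$col)) stop("results contain SNPs absent from the panel")

  cand <- res[res$p <= params$p1, , drop = FALSE]
  cand <- cand[order(cand$p, cand$pos, cand$snp), , drop = FALSE]
  pool <- res[res$p <= params$p2, , drop = FALSE]

  assigned <- character(0)
  idx_rows <- list()
  members <- list()
  Gs <- NULL
  for (i in seq_len(nrow(cand))) {
    s <- cand[i, ]
    if (s$snp %in% assigned) next
    near <- pool[
      !(pool$snp %in% c(assigned, s$snp)) &
        pool$chrom == s$chrom &
        abs(pool$pos - s$pos) <= params$window_kb * 1000,
      , drop = FALSE
    ]
    mem <- character(0)
    if (nrow(near) > 0) {
      g0 <- panel$dosages[, s$col]
      r2 <- as.vector(stats::cor(g0, panel$dosages[, near$col, drop = FALSE]))^2
      mem <- near$snp[!is.na(r2) & r2 >= params$r2_max]
    }
    assigned <- c(assigned, s$snp, mem)
    idx_rows[[length(idx_rows) + 1L]] <- data.frame(
      snp = s$snp, chrom = s$chrom, pos = s$pos, p = s$p,
      beta = s$beta, n_members = length(mem), stringsAsFactors = FALSE
    )
    members[[s$snp]] <- mem
  }
  indices <- if (length(idx_rows)) do.call(rbind, idx_rows) else
    data.frame(snp = character(0), chrom = integer(0), pos = numeric(0),
               p = numeric(0), beta = numeric(0), n_members = integer(0))
  structure(list(indices = indices, members = members, count = nrow(indices),
                 params = params),
            class = "locus_set")
}

#' Reference clumping implementation
#'
#' A deliberately plain transcription of the clumping definition, used to
#' validate [greedy_clump()]: the full pairwise r^2 matrix is computed up
#' front and the candidate list walked literally. Quadratic in SNP count;
#' intended for panels of a few hundred SNPs.
#'
#' @inheritParams greedy_clump
#' @export
reference_clump <- function(results, panel, params = clump_params()) {
  res <- as.data.frame(results)
  R2 <- stats::cor(panel$dosages)^2
  rownames(R2) <- colnames(R2) <- panel$map$snp
  cand <- res[res$p <= params$p1, , drop = FALSE]
  cand <- cand[order(cand$p, cand$pos, cand$snp), , drop = FALSE]
  pool <- res[res$p <= params$p2, , drop = FALSE]
  assigned <- character(0)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    s <- cand[i, ]
    if (s$snp %in% assigned) next
    mem <- character(0)
    for (j in seq_len(nrow(pool))) {
      q <- pool[j, ]
      if (q$snp == s$snp || q$snp %in% assigned || q$snp %in% mem) next
      if (q$chrom != s$chrom) next
      if (abs(q$pos - s$pos) > params$window_kb * 1000) next
      if (is.na(R2[s$snp, q$snp]) || R2[s$snp, q$snp] < params$r2_max) next
      mem <- c(mem, q$snp)
    }
    assigned <- c(assigned, s$snp, mem)
    out[[s$snp]] <- mem
  }
  list(indices = names(out), members = out, count = length(out))
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d independent loci (p1 = %g)\n",
              x$count, x$params$p1))
  invisible(x)
}
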