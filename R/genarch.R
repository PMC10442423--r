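# LD scores, LD score regression (heritability and cross-trait genetic
# correlation), and clumping-and-thresholding polygenic scores.

#' Per-SNP LD scores
#'
#' `l_j = sum over SNPs k on the same chromosome within `window_kb` of
#' `r^2(j, k)`, including the self term, so `l_j >= 1`. A physical window in
#' kb stands in for the genetic-map window of the canonical estimator (the
#' simulated panels have no genetic map).
#'
#' @param panel A `genotype_panel`.
#' @param window_kb Window half-width in kb; 0 gives `l_j = 1` exactly.
#' @return Numeric vector of LD scores, one per SNP.
#' @export
ld_scores <- function(panel, window_kb = 1000) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$n_snps == 0) stop("empty panel")
  map <- panel$map
  l <- rep(1, panel$n_snps)
  if (window_kb <= 0) return(l)
  win <- window_kb * 1000
  n <- panel$n_subjects
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    m <- length(ix)
    if (m < 2) next
    ord <- ix[order(map$pos[ix])]
    pos <- map$pos[ord]
    Gs <- standardize_dosages(panel$dosages[, ord, drop = FALSE])
    lc <- rep(0, m)
    chunk <- 512L
    for (st in seq.int(1L, m, by = chunk)) {
      en <- min(st + chunk - 1L, m)
      lo <- findInterval(pos[st] - win - 0.5, pos) + 1L
      lo <- min(lo, st)
      hi <- max(findInterval(pos[en] + win, pos), en)
      R <- crossprod(Gs[, st:en, drop = FALSE],
                     Gs[, lo:hi, drop = FALSE]) / (n - 1)
      inwin <- abs(outer(pos[st:en], pos[lo:hi], "-")) <= win
      lc[st:en] <- rowSums(R^2 * inwin)
    }
    # self term is included in the banded sums (r^2 = 1 at zero distance)
    l[ord] <- lc
  }
  l
}

# Delete-one-block jackknife SE for a statistic computed from per-SNP data.
# est_fun(keep_idx) must return the statistic on the retained SNPs.
block_jackknife <- function(m, n_blocks, est_fun) {
  n_blocks <- max(2L, min(n_blocks, m))
  blk <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  est <- vapply(seq_len(n_blocks), function(b) est_fun(which(blk != b)), numeric(1))
  sqrt((n_blocks - 1) / n_blocks * sum((est - mean(est))^2))
}

#' LD score regression heritability
#'
#' OLS of per-SNP chi-square statistics on LD scores with a free intercept;
#' under the polygenic model E[chi2_j] = 1 + N h2 l_j / M, so
#' `h2_hat = slope * M / N`. The SE is a leave-one-block-out jackknife over
#' contiguous SNP blocks. Estimates outside [0, 1] are reported but flagged.
#'
#' @param chi2 Per-SNP chi-square statistics.
#' @param l Per-SNP LD scores (same length).
#' @param N GWAS sample size.
#' @param M Number of SNPs the heritability is spread over.
#' @param n_blocks Jackknife blocks (default 20).
#' @return A list of class `h2_estimate`: `h2_hat`, `se`, `intercept`, `n`,
#'   `m`, `flagged`.
#' @export
ldsc_h2 <- function(chi2, l, N, M, n_blocks = 20) {
  stopifnot(length(chi2) == length(l), N > 0, M > 0)
  if (stats::sd(l) == 0) stop("constant LD scores: slope unidentifiable")
  slope_of <- function(idx) {
    co <- stats::coef(stats::lm.fit(cbind(1, l[idx]), chi2[idx]))
    co[2] * M / N
  }
  fit <- stats::lm.fit(cbind(1, l), chi2)
  h2_hat <- unname(stats::coef(fit)[2]) * M / N
  se <- block_jackknife(length(chi2), n_blocks, slope_of)
  structure(
    list(h2_hat = h2_hat, se = se,
         intercept = unname(stats::coef(fit)[1]),
         n = N, m = M, flagged = h2_hat < 0 || h2_hat > 1),
    class = "h2_estimate"
  )
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("LDSC h2 = %.3f (SE %.3f), intercept %.3f%s\n",
              x$h2_hat, x$se, x$intercept,
              if (x$flagged) " [outside [0,1]]" else ""))
  invisible(x)
}

#' Cross-trait LD score regression genetic correlation
#'
#' Regresses the per-SNP z-score products on LD scores: under the bivariate
#' polygenic model E[z1 z2] ~ sqrt(N1 N2) gencov l / M + intercept, so the
#' slope yields the genetic covariance and
#' `rg = gencov / sqrt(h2_1 * h2_2)`. SE by block jackknife.
#'
#' @param z1,z2 Per-SNP z-scores of the two traits (same SNPs, same order).
#' @param l LD scores.
#' @param N1,N2 Sample sizes.
#' @param h2_1,h2_2 Heritability estimates of the traits (positive).
#' @param M Number of SNPs.
#' @param n_blocks Jackknife blocks.
#' @return A list of class `rg_estimate`: `rg_hat`, `se`, `gencov`,
#'   `intercept`, `clipped` (TRUE when |rg| > 1).
#' @export
ldsc_rg <- function(z1, z2, l, N1, N2, h2_1, h2_2, M = length(l),
                    n_blocks = 20) {
  stopifnot(length(z1) == length(l), length(z2) == length(l))
  if (h2_1 <= 0 || h2_2 <= 0) stop("heritability inputs must be positive")
  if (stats::sd(l) == 0) stop("constant LD scores: slope unidentifiable")
  zz <- z1 * z2
  denom <- sqrt(h2_1 * h2_2)
  rg_of <- function(idx) {
    co <- stats::coef(stats::lm.fit(cbind(1, l[idx]), zz[idx]))
    (co[2] * M / sqrt(N1 * N2)) / denom
  }
  fit <- stats::lm.fit(cbind(1, l), zz)
  gencov <- unname(stats::coef(fit)[2]) * M / sqrt(N1 * N2)
  rg_hat <- gencov / denom
  se <- block_jackknife(length(zz), n_blocks, rg_of)
  structure(
    list(rg_hat = rg_hat, se = se, gencov = gencov,
         intercept = unname(stats::coef(fit)[1]),
         clipped = abs(rg_hat) > 1),
    class = "rg_estimate"
  )
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("LDSC rg = %.3f (SE %.3f)%s\n", x$rg_hat, x$se,
              if (x$clipped) " [|rg| > 1]" else ""))
  invisible(x)
}

#' Build a clumping-and-thresholding PRS model
#'
#' Summary statistics are clumped once with the index/member thresholds
#' relaxed to the loosest p-value threshold; each threshold then retains the
#' index SNPs with `p <=` that threshold, weighted by their GWAS betas.
#' Selections are nested across thresholds by construction.
#'
#' @param sumstats An `assoc_result`.
#' @param panel `genotype_panel` used for clumping LD.
#' @param thresholds P-value thresholds (default the standard seven:
#'   1, 0.1, 1e-2, ..., 1e-6).
#' @param clump A [clump_params()] supplying `r2_max` and `window_kb`.
#' @return A list of class `prs_model`: per-threshold `snps` and `weights`,
#'   plus the clumped index table.
#' @export
build_prs <- function(sumstats, panel,
                      thresholds = c(1, 0.1, 1e-2, 1e-3, 1e-4, 1e-5, 1e-6),
                      clump = clump_params()) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  loose <- clump_params(p1 = max(thresholds), p2 = max(thresholds),
                        r2_max = clump$r2_max, window_kb = clump$window_kb)
  loci <- greedy_clump(sumstats, panel, loose)
  idx <- loci$indices
  sel <- lapply(thresholds, function(t) {
    keep <- idx$p <= t
    list(snps = idx$snp[keep], weights = idx$beta[keep],
         empty = !any(keep))
  })
  names(sel) <- format(thresholds, scientific = TRUE)
  structure(
    list(thresholds = thresholds, selections = sel, indices = idx,
         clump = clump),
    class = "prs_model"
  )
}

#' Score a PRS model on a panel and evaluate it against an outcome
#'
#' For each threshold, the score is the beta-weighted dosage sum over the
#' selected SNPs, z-scored within the evaluation sample, then entered into a
#' covariate-adjusted logistic regression of the outcome. Significance is
#' Bonferroni at `alpha / n_tests` (default 21 tests: 3 phenotypes x 7
#' thresholds). Zero-variance (e.g. empty) scores are flagged and skipped.
#'
#' @param model A [build_prs()] model.
#' @param holdout_panel `genotype_panel` disjoint from the GWAS sample.
#' @param outcome_flags Logical outcome in the hold-out sample.
#' @param covariates Optional covariate data.frame/matrix.
#' @param n_tests Bonferroni denominator (default 21).
#' @param alpha Family-wise level (default 0.05).
#' @return A data.frame of class `prs_evaluation`: one row per threshold
#'   with `threshold`, `n_snps`, `estimate`, `se`, `p`, `significant`,
#'   `skipped`.
#' @export
score_and_evaluate <- function(model, holdout_panel, outcome_flags,
                               covariates = NULL, n_tests = 21, alpha = 0.05) {
  stopifnot(inherits(model, "prs_model"), inherits(holdout_panel, "genotype_panel"))
  y <- as.numeric(as.logical(outcome_flags))
  stopifnot(length(y) == holdout_panel$n_subjects)
  cq <- covar_q(holdout_panel$n_subjects, covariates)
  C <- cq$X

  zscores <- list()
  rows <- lapply(seq_along(model$thresholds), function(i) {
    sel <- model$selections[[i]]
    row <- data.frame(
      threshold = model$thresholds[i], n_snps = length(sel$snps),
      estimate = NA_real_, se = NA_real_, p = NA_real_,
      significant = FALSE, skipped = FALSE
    )
    cols <- match(sel$snps, holdout_panel$map$snp)
    if (length(cols) == 0 || anyNA(cols)) {
      row$skipped <- TRUE
      return(row)
    }
    score <- as.vector(holdout_panel$dosages[, cols, drop = FALSE] %*% sel$weights)
    if (stats::sd(score) == 0) {
      row$skipped <- TRUE
      return(row)
    }
    z <- (score - mean(score)) / stats::sd(score)
    zscores[[as.character(model$thresholds[i])]] <<- z
    fit <- irls_logistic(cbind(C, z), y)
    if (!fit$ok || fit$separated) {
      row$skipped <- TRUE
      return(row)
    }
    j <- ncol(C) + 1L
    row$estimate <- fit$beta[j]
    row$se <- sqrt(fit$vcov[j, j])
    row$p <- max(2 * stats::pnorm(-abs(row$estimate / row$se)), P_FLOOR)
    row$significant <- row$p < alpha / n_tests
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "scores") <- zscores
  class(out) <- c("prs_evaluation", "data.frame")
  out
}
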