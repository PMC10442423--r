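# Independent oracles and fixture builders used across the test suite.
# These deliberately avoid the package's own code paths.

# Exhaustive per-column row scan of a label mask: for each column holding
# both femur (1) and tibia (2), count rows strictly between the lowest femur
# pixel and the highest tibia pixel (floored at zero).
oracle_gap_scan <- function(mask) {
  cols <- integer(0)
  gaps <- integer(0)
  for (x in seq_len(ncol(mask))) {
    fr <- which(mask[, x] == 1L)
    tr <- which(mask[, x] == 2L)
    if (length(fr) == 0 || length(tr) == 0) next
    cols <- c(cols, x)
    gaps <- c(gaps, max(0L, min(tr) - max(fr) - 1L))
  }
  list(columns = cols, gaps_px = gaps)
}

# Enumerate the nine sampled indices straight from the sampling definition:
# three equal contiguous thirds, each sampled at the columns nearest its
# 25/50/75% positions.
oracle_nine_indices <- function(n) {
  bounds <- c(0, floor(n / 3), floor(2 * n / 3), n)
  out <- integer(0)
  for (k in 1:3) {
    len <- bounds[k + 1] - bounds[k]
    for (q in c(0.25, 0.5, 0.75)) {
      out <- c(out, bounds[k] + 1 + round(q * (len - 1)))
    }
  }
  out
}

# Literal clumping oracle: walk candidates in (p, pos, id) order and absorb
# unassigned secondary SNPs by window and r2, using a precomputed pairwise
# r2 matrix.
oracle_clump <- function(res, dosages, snp_ids, p1, p2, r2_min, window_bp) {
  r2m <- suppressWarnings(stats::cor(dosages))^2
  ord <- order(res$p, res$pos, res$snp)
  res <- res[ord, , drop = FALSE]
  taken <- setNames(rep(FALSE, length(snp_ids)), snp_ids)
  loci <- list()
  for (i in seq_len(nrow(res))) {
    row <- res[i, ]
    if (row$p > p1 || taken[[row$snp]]) next
    mem <- character(0)
    for (j in seq_len(nrow(res))) {
      other <- res[j, ]
      if (other$snp == row$snp || taken[[other$snp]] || other$p > p2) next
      if (other$chrom != row$chrom) next
      if (abs(other$pos - row$pos) > window_bp) next
      a <- match(row$snp, snp_ids)
      b <- match(other$snp, snp_ids)
      if (is.na(r2m[a, b]) || r2m[a, b] < r2_min) next
      mem <- c(mem, other$snp)
    }
    taken[c(row$snp, mem)] <- TRUE
    loci[[row$snp]] <- mem
  }
  loci
}

# Monte-Carlo oracle for the expected dosage r2 of two SNPs whose latent
# normals share correlation rho, both discretized at the HWE thresholds of
# minor allele frequency p.
oracle_copula_r2 <- function(maf, rho, n_draws = 1e6, seed = 424242) {
  set.seed(seed)
  z1 <- rnorm(n_draws)
  z2 <- rho_mix <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_draws)
  t1 <- qnorm((1 - maf)^2)
  t2 <- qnorm(1 - maf^2)
  d1 <- (z1 > t1) + (z1 > t2)
  d2 <- (z2 > t1) + (z2 > t2)
  stats::cor(d1, d2)^2
}

# Minimal genotype panel from explicit dosages and positions.
make_panel <- function(D, pos = NULL, chrom = NULL, maf = NULL) {
  M <- ncol(D)
  map <- data.frame(
    chrom = chrom %||% rep(1L, M),
    snp = sprintf("s%03d", seq_len(M)),
    pos = pos %||% (seq_len(M) * 1000),
    maf = maf %||% (pmin(colMeans(D) / 2, 1 - colMeans(D) / 2)),
    block = seq_len(M),
    stringsAsFactors = FALSE
  )
  colnames(D) <- map$snp
  structure(list(dosages = D, map = map, n_subjects = nrow(D), n_snps = M),
            class = "genotype_panel")
}

# Assemble an assoc_result-shaped table from explicit per-SNP values.
make_assoc <- function(panel, p, beta = NULL, se = NULL) {
  M <- panel$n_snps
  beta <- beta %||% rep(1, M)
  se <- se %||% rep(1, M)
  out <- data.frame(
    snp = panel$map$snp, chrom = panel$map$chrom, pos = panel$map$pos,
    beta = beta, se = se, p = p, chi2 = (beta / se)^2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
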