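# LD-blocked genotype simulation.
#
# Dosages in {0,1,2} are produced by thresholding a block-exchangeable
# Gaussian copula at the Hardy-Weinberg genotype probabilities of each SNP's
# minor allele frequency: within a block the latent normals share a common
# factor with loading sqrt(rho), between blocks they are independent. Blocks
# are contiguous in position, which makes LD clumping and LD-score tests
# analyzable.

#' Configure a genotype panel simulation
#'
#' @param n_subjects,n_snps Panel dimensions.
#' @param block_size SNPs per LD block (>= 1).
#' @param rho Within-block latent correlation: a single value in `[0, 1)`,
#'   or a length-2 range from which each block's correlation is drawn
#'   uniformly (LD heterogeneity across blocks, as in real genomes).
#' @param maf_range Range the per-SNP minor allele frequency is drawn from
#'   (uniform); must lie in (0, 0.5].
#' @param spacing_bp Base-pair spacing between adjacent SNPs.
#' @param n_chrom Number of chromosomes the SNPs are split across (blocks
#'   never straddle a chromosome boundary).
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_subjects, n_snps, block_size = 10, rho = 0.8,
                         maf_range = c(0.05, 0.5), spacing_bp = 10000,
                         n_chrom = 1) {
  stopifnot(n_subjects >= 1, n_snps >= 1, block_size >= 1, spacing_bp > 0,
            length(rho) %in% 1:2)
  if (any(rho < 0) || any(rho >= 1)) {
    stop("within-block correlation rho must be in [0, 1)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must lie in (0, 0.5]")
  }
  structure(as.list(environment()), class = "panel_config")
}

#' Simulate an LD-blocked genotype panel
#'
#' @param config A [panel_config()].
#' @param seed RNG seed.
#' @param variant_map Optional variant map from a previous panel with the
#'   same `n_snps`; reusing it (same SNPs, MAFs and blocks) yields a second
#'   sample from the same population, e.g. a PRS hold-out set.
#' @return A list of class `genotype_panel` with elements `dosages`
#'   (`n_subjects` x `n_snps` numeric matrix of 0/1/2), `map` (data.frame
#'   with `chrom`, `snp`, `pos`, `maf`, `block`), `n_subjects`, `n_snps`.
#' @export
simulate_genotypes <- function(config, seed = 1L, variant_map = NULL) {
  stopifnot(inherits(config, "panel_config"))
  N <- config$n_subjects
  M <- config$n_snps
  with_seed(seed, {
    if (is.null(variant_map)) {
      maf <- runif(M, config$maf_range[1], config$maf_range[2])
      chrom <- rep(seq_len(config$n_chrom), each = ceiling(M / config$n_chrom))[seq_len(M)]
      pos <- unlist(lapply(split(seq_len(M), chrom), function(ix) {
        seq_along(ix) * config$spacing_bp
      }), use.names = FALSE)
      # blocks are contiguous within chromosome
      block <- integer(M)
      nb <- 0L
      for (ch in unique(chrom)) {
        ix <- which(chrom == ch)
        b <- (seq_along(ix) - 1L) %/% config$block_size + 1L
        block[ix] <- nb + b
        nb <- nb + max(b)
      }
      rho_block <- if (length(config$rho) == 1L) {
        rep(config$rho, max(block))
      } else {
        runif(max(block), config$rho[1], config$rho[2])
      }
      map <- data.frame(
        chrom = chrom,
        snp = sprintf("rs%06d", seq_len(M)),
        pos = pos,
        maf = maf,
        block = block,
        rho = rho_block[block],
        stringsAsFactors = FALSE
      )
    } else {
      map <- variant_map
      if (nrow(map) != M) stop("variant_map does not match n_snps")
    }

    # Latent block-exchangeable normals with per-block correlation.
    S <- matrix(rnorm(N * max(map$block)), nrow = N)
    E <- matrix(rnorm(N * M), nrow = N)
    rho_snp <- map$rho
    Z <- S[, map$block, drop = FALSE] * rep(sqrt(rho_snp), each = N) +
      E * rep(sqrt(1 - rho_snp), each = N)

    # HWE thresholds per SNP: P(0) = (1-p)^2, P(0 or 1) = 1 - p^2.
    p <- map$maf
    t1 <- qnorm((1 - p)^2)
    t2 <- qnorm(1 - p^2)
    D <- (Z > rep(t1, each = N)) + (Z > rep(t2, each = N))
    dimnames(D) <- list(NULL, map$snp)

    structure(
      list(dosages = D, map = map, n_subjects = N, n_snps = M),
      class = "genotype_panel"
    )
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d subjects x %d SNPs, %d LD blocks, %d chromosome(s)\n",
    x$n_subjects, x$n_snps, max(x$map$block), length(unique(x$map$chrom))
  ))
  invisible(x)
}

# Column-standardized dosages (monomorphic columns become 0).
standardize_dosages <- function(G) {
  n <- nrow(G)
  mu <- colMeans(G)
  v <- (colSums(G * G) - n * mu^2) / (n - 1)
  s <- sqrt(pmax(v, 0))
  s[s == 0] <- Inf
  (G - rep(mu, each = n)) * rep(1 / s, each = n)
}

#' Squared Pearson correlation between two SNPs' dosages
#'
#' @param panel A `genotype_panel`.
#' @param i,j SNP column indices or ids.
#' @export
snp_r2 <- function(panel, i, j) {
  G <- panel$dosages
  if (is.character(i)) i <- match(i, panel$map$snp)
  if (is.character(j)) j <- match(j, panel$map$snp)
  stats::cor(G[, i], G[, j])^2
}
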