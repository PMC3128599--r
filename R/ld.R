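## Two-locus linkage disequilibrium from unphased diploid genotypes.
##
## Haplotype frequencies are estimated by EM over the double-heterozygote
## phase ambiguity (all other genotype classes contribute gametes
## deterministically); r-squared and D-prime follow from the estimated
## frequencies. This mirrors what Haploview-style LD displays compute
## internally from genotype data.

#' Two-locus genotype counts
#'
#' Cross-tabulates two SNP columns of a genotype matrix into a 3x3 grid over
#' `homRef`/`het`/`homAlt` (homRef = `homA`). Individuals with a no-call at
#' either locus are excluded.
#'
#' @param m a [genotype_matrix()].
#' @param snp1,snp2 SNP names or 1-based column indices.
#' @return A `two_locus_counts` object: 3x3 integer matrix `counts` plus `n`.
#' @export
two_locus_counts <- function(m, snp1, snp2) {
  ix <- function(s) {
    if (is.character(s)) {
      i <- match(s, m$map$snp_name)
      if (is.na(i)) stop("SNP not in map: ", s)
      i
    } else as.integer(s)
  }
  g1 <- m$calls[, ix(snp1)]
  g2 <- m$calls[, ix(snp2)]
  keep <- g1 != "nocall" & g2 != "nocall"
  lev <- c("homA", "het", "homB")
  counts <- table(factor(g1[keep], levels = lev), factor(g2[keep], levels = lev))
  counts <- matrix(as.integer(counts), 3L, 3L,
                   dimnames = list(locus1 = c("homRef", "het", "homAlt"),
                                   locus2 = c("homRef", "het", "homAlt")))
  structure(list(counts = counts, n = sum(counts)), class = "two_locus_counts")
}

## multinomial log-likelihood of the 3x3 genotype table given haplotype freqs
## h = c(pAB, pAb, paB, pab); "A"/"B" are the reference alleles at locus 1/2
two_locus_loglik <- function(counts, h) {
  pAB <- h[1L]; pAb <- h[2L]; paB <- h[3L]; pab <- h[4L]
  P <- matrix(c(pAB^2,             2 * pAB * pAb,             pAb^2,
                2 * pAB * paB, 2 * (pAB * pab + pAb * paB), 2 * pAb * pab,
                paB^2,             2 * paB * pab,             pab^2),
              3L, 3L, byrow = TRUE)
  use <- counts > 0L
  sum(counts[use] * log(pmax(P[use], 1e-300)))
}

#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies (AB, Ab, aB, ab; upper case =
#' reference allele) from unphased genotype counts. Only the double
#' heterozygote is phase-ambiguous; the E-step splits it between AB/ab and
#' Ab/aB in proportion to the current products of frequencies. Initialization
#' is at linkage equilibrium (products of observed allele frequencies), so the
#' procedure is deterministic.
#'
#' @param g a [two_locus_counts()] (or a plain 3x3 matrix).
#' @param tol convergence tolerance on the max absolute frequency change.
#' @param max_iter iteration cap.
#' @return A `haplotype_freqs` list: `p_AB`, `p_Ab`, `p_aB`, `p_ab`,
#'   `log_likelihood`, `iterations`, `converged`, and the per-iteration
#'   log-likelihood trace `loglik_trace`.
#' @export
em_haplotypes <- function(g, tol = 1e-8, max_iter = 1000L) {
  counts <- if (inherits(g, "two_locus_counts")) g$counts else as.matrix(g)
  stopifnot(all(dim(counts) == c(3L, 3L)), all(counts >= 0L))
  n <- sum(counts)
  if (n == 0L) stop("no individuals with calls at both loci")
  ## deterministic gamete counts from the nine cells (double het handled in EM)
  ## rows locus1: homRef/het/homAlt; cols locus2 likewise
  cAB <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1]
  cAb <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3]
  caB <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1]
  cab <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
  ndh <- counts[2, 2]
  total <- 2 * n
  ## observed allele frequencies (double hets contribute one of each allele)
  pA <- (2 * sum(counts[1, ]) + sum(counts[2, ])) / total
  pB <- (2 * sum(counts[, 1]) + sum(counts[, 2])) / total
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  ll_trace <- two_locus_loglik(counts, h)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ## E-step: expected phase split of the double heterozygotes
    denom <- h[1L] * h[4L] + h[2L] * h[3L]
    w <- if (denom > 0) h[1L] * h[4L] / denom else 0.5
    e <- c(cAB + ndh * w, cAb + ndh * (1 - w),
           caB + ndh * (1 - w), cab + ndh * w)
    h_new <- e / total
    ll_trace <- c(ll_trace, two_locus_loglik(counts, h_new))
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(p_AB = h[1L], p_Ab = h[2L], p_aB = h[3L], p_ab = h[4L],
                 log_likelihood = ll_trace[length(ll_trace)],
                 iterations = iter, converged = converged,
                 loglik_trace = ll_trace),
            class = "haplotype_freqs")
}

#' LD statistics from haplotype frequencies
#'
#' `D = p_AB - pA * pB`; `D' = |D| / Dmax` where Dmax is the admissible bound
#' given the allele frequencies; `r2 = D^2 / (pA * pa * pB * pb)`. A
#' monomorphic locus makes all three undefined; they are returned as NA with
#' `monomorphic = TRUE`, never as 0.
#'
#' @param h a `haplotype_freqs` from [em_haplotypes()].
#' @return An `ld_stats` list: `D`, `D_prime`, `r2`, `monomorphic`.
#' @export
ld_stats <- function(h) {
  pA <- h$p_AB + h$p_Ab
  pB <- h$p_AB + h$p_aB
  pa <- 1 - pA; pb <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(structure(list(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                          monomorphic = TRUE), class = "ld_stats"))
  }
  D <- h$p_AB - pA * pB
  Dmax <- if (D >= 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  D_prime <- if (Dmax > 0) abs(D) / Dmax else 0
  r2 <- D^2 / (pA * pa * pB * pb)
  structure(list(D = D, D_prime = min(D_prime, 1), r2 = min(r2, 1),
                 monomorphic = FALSE), class = "ld_stats")
}

#' Pairwise LD matrix over a SNP subset
#'
#' Estimates haplotype frequencies by EM for every SNP pair (no-calls dropped
#' pairwise) and reports r2, D' and D grids. Diagonal r2 is 1 for polymorphic
#' loci and NA for monomorphic ones.
#'
#' @param m a [genotype_matrix()].
#' @param snp_subset character vector of >= 2 SNP names (must be in the map).
#' @return An `ld_matrix` list of symmetric matrices `r2`, `D_prime`, `D`, `n`
#'   plus a long-format data.frame `pairs` (snp_i, snp_j, n, D, Dprime, r2).
#' @export
ld_matrix <- function(m, snp_subset) {
  if (length(snp_subset) < 2L) stop("need at least 2 SNPs")
  missing_snps <- setdiff(snp_subset, m$map$snp_name)
  if (length(missing_snps)) {
    stop("SNP(s) not in map: ", paste(missing_snps, collapse = ", "))
  }
  k <- length(snp_subset)
  r2 <- Dp <- D <- matrix(NA_real_, k, k, dimnames = list(snp_subset, snp_subset))
  n <- matrix(0L, k, k, dimnames = list(snp_subset, snp_subset))
  pairs <- vector("list", k * (k - 1L) / 2L)
  p <- 0L
  for (i in seq_len(k)) {
    gi <- m$calls[, match(snp_subset[i], m$map$snp_name)]
    called <- gi[gi != "nocall"]
    polymorphic <- any(called == "het") ||
      (any(called == "homA") && any(called == "homB"))
    r2[i, i] <- if (polymorphic) 1 else NA_real_
    n[i, i] <- length(called)
    for (j in seq_len(i - 1L)) {
      tc <- two_locus_counts(m, snp_subset[i], snp_subset[j])
      st <- ld_stats(em_haplotypes(tc))
      r2[i, j] <- r2[j, i] <- st$r2
      Dp[i, j] <- Dp[j, i] <- st$D_prime
      D[i, j] <- D[j, i] <- st$D
      n[i, j] <- n[j, i] <- tc$n
      p <- p + 1L
      pairs[[p]] <- data.frame(snp_i = snp_subset[j], snp_j = snp_subset[i],
                               n = tc$n, D = st$D, Dprime = st$D_prime,
                               r2 = st$r2, stringsAsFactors = FALSE)
    }
  }
  structure(list(r2 = r2, D_prime = Dp, D = D, n = n,
                 pairs = do.call(rbind, pairs)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix over ", nrow(x$r2), " SNPs; r2 (2 dp):\n", sep = "")
  print(round(x$r2, 2))
  invisible(x)
}
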