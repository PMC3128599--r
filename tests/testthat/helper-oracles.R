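# Independent oracles and small fixtures shared across tests.

# map with evenly spaced positions on the given chromosomes
toy_map <- function(n, chromosomes = "1") {
  chr <- rep(chromosomes, length.out = n)
  chr <- sort(chr)  # keep blocks contiguous
  pos <- unlist(lapply(unique(chr), function(c) seq_len(sum(chr == c)) * 1000L))
  snp_map(paste0("snp", seq_len(n)), chr, pos)
}

# build a genotype_matrix from a plain character matrix of calls
toy_matrix <- function(calls, statuses, map = NULL, qc = NULL) {
  if (is.null(map)) map <- toy_map(ncol(calls))
  ids <- if (nrow(calls)) paste0("S", seq_len(nrow(calls))) else character(0)
  samples <- data.frame(sample_id = ids, status = statuses,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, map, qc = qc)
}

# exhaustive-window oracle for the run finder: enumerate every (a, b) window,
# keep qualifying ones, then drop windows contained in a larger qualifying one
oracle_runs <- function(states, map, min_snps = 10L, strict = TRUE) {
  n <- length(states)
  informative <- states %in% c("consensus_homA", "consensus_homB")
  qualifies <- function(a, b) {
    w <- a:b
    if (length(unique(map$chromosome[w])) != 1L) return(FALSE)
    if (any(states[w] == "non_consensus")) return(FALSE)
    if (!informative[a] || !informative[b]) return(FALSE)
    n_inf <- sum(informative[w])
    if (strict) n_inf > min_snps else n_inf >= min_snps
  }
  wins <- list()
  for (a in seq_len(n)) {
    for (b in a:n) if (qualifies(a, b)) wins[[length(wins) + 1L]] <- c(a, b)
  }
  if (!length(wins)) {
    return(data.frame(start_row = integer(), end_row = integer(),
                      n_informative = integer()))
  }
  w <- do.call(rbind, wins)
  maximal <- vapply(seq_len(nrow(w)), function(i) {
    !any(w[, 1L] <= w[i, 1L] & w[, 2L] >= w[i, 2L] &
           (w[, 1L] < w[i, 1L] | w[, 2L] > w[i, 2L]))
  }, logical(1))
  w <- w[maximal, , drop = FALSE]
  w <- w[order(w[, 1L]), , drop = FALSE]
  data.frame(start_row = w[, 1L], end_row = w[, 2L],
             n_informative = vapply(seq_len(nrow(w)), function(i)
               sum(informative[w[i, 1L]:w[i, 2L]]), integer(1)))
}

random_states <- function(n, p = c(0.35, 0.1, 0.35, 0.2)) {
  sample(c("consensus_homA", "consensus_homB", "non_consensus", "uninformative"),
         n, replace = TRUE, prob = p)
}

# brute-force closed-interval overlap oracle
oracle_overlap <- function(chromosome, start_bp, end_bp, genes) {
  hit <- genes$chromosome == chromosome &
    genes$start_bp <= end_bp & genes$end_bp >= start_bp
  g <- genes[hit, , drop = FALSE]
  g <- g[order(g$start_bp), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# naive overlapping-occurrence scanner for a motif (digest oracle)
naive_occurrences <- function(seq, motif) {
  k <- nchar(motif)
  if (nchar(seq) < k) return(integer())
  which(vapply(seq_len(nchar(seq) - k + 1L),
               function(i) substr(seq, i, i + k - 1L) == motif, logical(1)))
}

# independent two-locus genotype log-likelihood (written from the nine HWE
# cell probabilities, not shared with the package internals)
oracle_loglik <- function(counts, pAB, pA, pB) {
  pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
  h <- c(pAB, pAb, paB, pab)
  if (any(h < -1e-12)) return(-Inf)
  h <- pmax(h, 0)
  P <- matrix(c(h[1]^2, 2 * h[1] * h[2], h[2]^2,
                2 * h[1] * h[3], 2 * (h[1] * h[4] + h[2] * h[3]), 2 * h[2] * h[4],
                h[3]^2, 2 * h[3] * h[4], h[4]^2), 3, 3, byrow = TRUE)
  sum(counts[counts > 0] * log(pmax(P[counts > 0], 1e-300)))
}

# grid-search maximum-likelihood r2 (resolution 1e-4), the EM cross-check
oracle_grid_r2 <- function(counts, res = 1e-4) {
  n <- sum(counts)
  pA <- (2 * sum(counts[1, ]) + sum(counts[2, ])) / (2 * n)
  pB <- (2 * sum(counts[, 1]) + sum(counts[, 2])) / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = res)
  ll <- vapply(grid, function(p) oracle_loglik(counts, p, pA, pB), numeric(1))
  pAB <- grid[which.max(ll)]
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# random unphased two-locus genotype counts from a phased population; rejects
# monomorphic draws
random_two_locus_counts <- function(n = 60L) {
  repeat {
    h <- as.vector(stats::rmultinom(1L, 1000L, runif(4, 0.05, 1)))
    h <- h / sum(h)
    hap <- sample(1:4, 2L * n, replace = TRUE, prob = h)
    a1 <- hap[seq_len(n)]; a2 <- hap[n + seq_len(n)]
    g1 <- (a1 > 2) + (a2 > 2)              # locus 1 allele a count
    g2 <- (a1 %in% c(2, 4)) + (a2 %in% c(2, 4))  # locus 2 allele b count
    counts <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
    counts <- matrix(as.integer(counts), 3L, 3L)
    pA <- (2 * sum(counts[1, ]) + sum(counts[2, ])) / (2 * n)
    pB <- (2 * sum(counts[, 1]) + sum(counts[, 2])) / (2 * n)
    if (pA > 0 && pA < 1 && pB > 0 && pB < 1) return(counts)
  }
}

# compact simulation configuration for module-level tests
small_sim_config <- function(...) {
  sim_config(n_snps = 1200L, n_chromosomes = 4L, n_affected = 6L,
             n_carrier = 2L, n_normal_related = 8L, n_controls = 10L,
             planted_segments = data.frame(chromosome = c("2", "3"),
                                           start_index = c(40L, 25L),
                                           n_snps = c(30L, 12L)),
             causal_segment = 1L, n_founder_ewes = 12L, n_dams = 3L, ...)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
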