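## Consensus-homozygosity scan.
##
## The mapping logic: at each SNP, count the four genotype classes within the
## affected group; the genotype frequency denominator excludes no-calls. A SNP
## is a consensus-homozygous locus when the top genotype frequency equals 1 and
## that genotype is homozygous. Maximal stretches of such loci (over the
## contiguous map index, never crossing a chromosome) longer than a threshold
## are candidate autozygous regions; each is then re-checked in the carrier
## group, which must NOT be consensus-homozygous for the identical allele
## across the whole region.

CONSENSUS_STATES <- c("consensus_homA", "consensus_homB", "non_consensus",
                      "uninformative")

#' Genotype counts at one SNP
#'
#' @param group a [genotype_matrix()] (one disease-status group).
#' @param snp_index 1-based SNP column index.
#' @return Named integer vector `n_homA`, `n_het`, `n_homB`, `n_nocall`.
#' @export
genotype_counts <- function(group, snp_index) {
  if (length(snp_index) != 1L || snp_index < 1L || snp_index > ncol(group$calls)) {
    stop("snp_index out of range")
  }
  x <- group$calls[, snp_index]
  c(n_homA = sum(x == "homA"), n_het = sum(x == "het"),
    n_homB = sum(x == "homB"), n_nocall = sum(x == "nocall"))
}

#' Consensus state from genotype counts
#'
#' The top genotype frequency uses the called total (no-calls excluded from the
#' denominator). State is `consensus_homA`/`consensus_homB` iff that frequency
#' equals 1 and the genotype is homozygous; `uninformative` iff no sample was
#' called.
#'
#' @param counts named vector as returned by [genotype_counts()].
#' @return list with `state` and `top_frequency` (NA when uninformative).
#' @export
consensus_state <- function(counts) {
  nA <- counts[["n_homA"]]; nH <- counts[["n_het"]]; nB <- counts[["n_homB"]]
  called <- nA + nH + nB
  if (called == 0L) {
    return(list(state = "uninformative", top_frequency = NA_real_))
  }
  top <- max(nA, nH, nB)
  state <- if (nA == called) "consensus_homA"
  else if (nB == called) "consensus_homB"
  else "non_consensus"
  list(state = state, top_frequency = top / called)
}

#' Per-SNP consensus states for a group
#'
#' Vectorized [consensus_state()] across all SNPs of a group.
#'
#' @param group a [genotype_matrix()].
#' @return data.frame with `state` and `top_frequency` per SNP, map-aligned.
#' @export
consensus_states <- function(group) {
  cm <- group$calls
  nA <- colSums(cm == "homA")
  nH <- colSums(cm == "het")
  nB <- colSums(cm == "homB")
  called <- nA + nH + nB
  state <- rep("non_consensus", ncol(cm))
  state[called > 0L & nA == called] <- "consensus_homA"
  state[called > 0L & nB == called] <- "consensus_homB"
  state[called == 0L] <- "uninformative"
  topf <- ifelse(called > 0L, pmax(nA, nH, nB) / called, NA_real_)
  data.frame(state = state, top_frequency = topf, stringsAsFactors = FALSE)
}

empty_runs <- function() {
  r <- data.frame(chromosome = character(), start_index = integer(),
                  end_index = integer(), start_bp = integer(),
                  end_bp = integer(), n_snps = integer(),
                  n_informative = integer(), span_bp = integer(),
                  carrier_pass = logical(), stringsAsFactors = FALSE)
  class(r) <- c("roh_runs", "data.frame")
  r
}

#' Find maximal runs of consensus-homozygous SNPs
#'
#' A run is a maximal stretch of consensus-homozygous SNPs between
#' non-consensus SNPs (or chromosome ends). Uninformative (all-no-call) SNPs
#' neither break a run nor count toward its qualification; run boundaries are
#' trimmed to informative SNPs. A run qualifies when its informative count is
#' `> min_snps` (`strict = TRUE`, the "more than 10 loci" reading) or
#' `>= min_snps` (`strict = FALSE`, the "at least 10" reading). Runs never
#' cross a chromosome boundary. The consensus allele may switch between
#' adjacent SNPs within one run: the criterion is per-SNP homozygosity, not a
#' shared haplotype allele.
#'
#' @param states character vector of consensus states (or the data.frame from
#'   [consensus_states()]), aligned to `map`.
#' @param map a [snp_map()].
#' @param min_snps qualification threshold on informative SNPs (default 10).
#' @param strict if TRUE require strictly more than `min_snps`.
#' @return A `roh_runs` data.frame: `chromosome`, `start_index`/`end_index`
#'   (0-based contiguous map indices, inclusive), `start_bp`/`end_bp`,
#'   `n_snps` (all SNPs between boundaries), `n_informative` (consensus calls
#'   only), `span_bp`, `carrier_pass` (NA until [carrier_filter()] is run).
#' @export
find_runs <- function(states, map, min_snps = 10L, strict = TRUE) {
  if (is.data.frame(states)) states <- states$state
  if (length(states) != nrow(map)) stop("states must align to the map")
  if (!all(states %in% CONSENSUS_STATES)) stop("invalid consensus state value")
  if (min_snps < 1L) stop("min_snps must be >= 1")
  out <- vector("list", 0L)
  consensus <- states %in% c("consensus_homA", "consensus_homB")
  blocker <- states == "non_consensus"
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    ## segment id between blockers
    seg <- cumsum(blocker[idx])
    open <- !blocker[idx]
    for (s in split(idx[open], seg[open])) {
      inf <- s[consensus[s]]
      n_inf <- length(inf)
      qual <- if (strict) n_inf > min_snps else n_inf >= min_snps
      if (!qual) next
      a <- min(inf); b <- max(inf)  # trim boundaries to informative SNPs
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr,
        start_index = map$contiguous_index[a],
        end_index = map$contiguous_index[b],
        start_bp = map$position_bp[a],
        end_bp = map$position_bp[b],
        n_snps = b - a + 1L,
        n_informative = n_inf,
        span_bp = map$position_bp[b] - map$position_bp[a] + 1L,
        carrier_pass = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_runs())
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  class(r) <- c("roh_runs", "data.frame")
  r
}

#' Carrier-heterozygosity re-check of candidate runs
#'
#' A run passes when the carrier group is NOT consensus-homozygous for the same
#' allele as the affecteds at every informative SNP of the run, i.e. at least
#' one SNP inside the run where the carriers are non-consensus (heterozygous or
#' discordant) or consensus for the other homozygote. With an empty carrier
#' group the verdict is undetermined (NA) and the run is retained.
#'
#' @param runs a `roh_runs` data.frame from [find_runs()].
#' @param affected_states per-SNP states of the affected group (map-aligned).
#' @param carrier_states per-SNP states of the carrier group (map-aligned), or
#'   NULL for an empty carrier group.
#' @param map the [snp_map()] both state vectors are aligned to.
#' @return `runs` with `carrier_pass` filled in.
#' @export
carrier_filter <- function(runs, affected_states, carrier_states, map) {
  if (is.data.frame(affected_states)) affected_states <- affected_states$state
  if (is.data.frame(carrier_states)) carrier_states <- carrier_states$state
  if (is.null(carrier_states)) {
    runs$carrier_pass <- NA
    return(runs)
  }
  if (length(affected_states) != nrow(map) || length(carrier_states) != nrow(map)) {
    stop("state vectors must align to the map")
  }
  pass <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    pos <- which(map$contiguous_index >= runs$start_index[i] &
                   map$contiguous_index <= runs$end_index[i])
    inf <- pos[affected_states[pos] %in% c("consensus_homA", "consensus_homB")]
    pass[i] <- !all(carrier_states[inf] == affected_states[inf])
  }
  runs$carrier_pass <- pass
  runs
}

#' Genome-wide consensus-homozygosity scan
#'
#' Runs the whole pipeline on a genotyped cohort: split samples by disease
#' status, call per-SNP consensus states in the affected group, extract maximal
#' qualifying runs, and re-check each run in the carrier group. Output is
#' sorted largest-first: by SNP count, then bp span, then genomic order.
#'
#' @inheritParams find_runs
#' @param m a [genotype_matrix()] containing at least one affected sample.
#' @return A `roh_runs` data.frame (see [find_runs()]) with `carrier_pass`
#'   verdicts.
#' @export
scan_roh <- function(m, min_snps = 10L, strict = TRUE) {
  groups <- split_by_status(m)
  aff <- consensus_states(groups$affected)
  runs <- find_runs(aff, m$map, min_snps = min_snps, strict = strict)
  car <- if (nrow(groups$carrier$samples) > 0L) consensus_states(groups$carrier) else NULL
  runs <- carrier_filter(runs, aff, car, m$map)
  if (nrow(runs) > 1L) {
    o <- order(-runs$n_snps, -runs$span_bp, chrom_rank(runs$chromosome),
               runs$start_bp)
    runs <- runs[o, , drop = FALSE]
    rownames(runs) <- NULL
    class(runs) <- c("roh_runs", "data.frame")
  }
  runs
}

#' @export
print.roh_runs <- function(x, ...) {
  cat("roh_runs: ", nrow(x), " run(s)\n", sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
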