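state_fixture <- function(spec) {
  # spec: character shorthand, A/B = consensus hom, n = non-consensus, u = uninformative
  key <- c(A = "consensus_homA", B = "consensus_homB", n = "non_consensus",
           u = "uninformative")
  unname(key[strsplit(spec, "")[[1L]]])
}

test_that("genotype counts tally the four symbols exactly", {
  m <- toy_matrix(matrix("homA", 17L, 1L), rep("affected", 17L))
  expect_equal(unname(genotype_counts(m, 1L)), c(17L, 0L, 0L, 0L))
  calls <- matrix(c(rep("homA", 16L), "nocall"), 17L, 1L)
  m2 <- toy_matrix(calls, rep("affected", 17L))
  expect_equal(unname(genotype_counts(m2, 1L)), c(16L, 0L, 0L, 1L))
  empty <- toy_matrix(matrix(character(), 0L, 1L), character())
  expect_equal(unname(genotype_counts(empty, 1L)), c(0L, 0L, 0L, 0L))
  expect_error(genotype_counts(m, 2L), "range")
})

test_that("consensus excludes no-calls from the denominator", {
  s <- consensus_state(c(n_homA = 17L, n_het = 0L, n_homB = 0L, n_nocall = 0L))
  expect_equal(s$state, "consensus_homA")
  expect_equal(s$top_frequency, 1)
  s <- consensus_state(c(n_homA = 16L, n_het = 0L, n_homB = 0L, n_nocall = 1L))
  expect_equal(s$state, "consensus_homA")  # denominator 16, no-call excluded
  expect_equal(s$top_frequency, 1)
  s <- consensus_state(c(n_homA = 16L, n_het = 1L, n_homB = 0L, n_nocall = 0L))
  expect_equal(s$state, "non_consensus")
  expect_equal(s$top_frequency, 16 / 17, tolerance = 1e-12)
  s <- consensus_state(c(n_homA = 0L, n_het = 0L, n_homB = 0L, n_nocall = 17L))
  expect_equal(s$state, "uninformative")
  expect_true(is.na(s$top_frequency))
})

test_that("vectorized consensus states agree with the scalar definition", {
  set.seed(11)
  calls <- matrix(sample(c("homA", "het", "homB", "nocall"), 6L * 40L,
                         replace = TRUE, prob = c(0.5, 0.1, 0.2, 0.2)),
                  6L, 40L)
  m <- toy_matrix(calls, rep("affected", 6L))
  vec <- consensus_states(m)
  for (j in seq_len(40L)) {
    s <- consensus_state(genotype_counts(m, j))
    expect_equal(vec$state[j], s$state)
    expect_equal(vec$top_frequency[j], s$top_frequency)
  }
})

test_that("a 125-locus consensus stretch is reported as a single maximal run", {
  states <- state_fixture(paste0("n", strrep("A", 125L), "n"))
  map <- toy_map(127L)
  runs <- find_runs(states, map)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_snps, 125L)
  expect_equal(runs$n_informative, 125L)
  expect_equal(runs$start_index, 1L)
  expect_equal(runs$end_index, 125L)
})

test_that("the strict flag separates the more-than-10 and at-least-10 readings", {
  states <- state_fixture(paste0("n", strrep("A", 10L), "n"))
  map <- toy_map(12L)
  expect_equal(nrow(find_runs(states, map, min_snps = 10L, strict = TRUE)), 0L)
  runs <- find_runs(states, map, min_snps = 10L, strict = FALSE)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_snps, 10L)
  expect_error(find_runs(states, map, min_snps = 0L), "min_snps")
})

test_that("alternating consensus and non-consensus yields no runs", {
  states <- rep(c("consensus_homA", "non_consensus"), 20L)
  expect_equal(nrow(find_runs(states, toy_map(40L), min_snps = 2L,
                              strict = FALSE)), 0L)
})

test_that("uninformative loci neither break runs nor count toward the threshold", {
  states <- state_fixture("nAAAuAAAn")
  map <- toy_map(9L)
  runs <- find_runs(states, map, min_snps = 6L, strict = FALSE)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_snps, 7L)        # spans the uninformative locus
  expect_equal(runs$n_informative, 6L) # but does not count it
  # with the threshold at 7 informative loci the run no longer qualifies
  expect_equal(nrow(find_runs(states, map, min_snps = 7L, strict = FALSE)), 0L)
  # boundaries trim to informative loci
  states2 <- state_fixture("uAAAAun")
  runs2 <- find_runs(states2, toy_map(7L), min_snps = 4L, strict = FALSE)
  expect_equal(runs2$start_index, 1L)
  expect_equal(runs2$end_index, 4L)
})

test_that("runs never span a chromosome boundary and consensus may switch allele", {
  map <- toy_map(12L, chromosomes = c("1", "2"))
  states <- rep(c("consensus_homA", "consensus_homB"), 6L)
  runs <- find_runs(states, map, min_snps = 3L, strict = FALSE)
  expect_equal(nrow(runs), 2L)  # one run per chromosome, allele switches allowed
  expect_equal(runs$n_snps, c(6L, 6L))
})

test_that("the run finder matches the exhaustive-window oracle on random sequences", {
  set.seed(42)
  for (i in seq_len(50L)) {
    n <- sample(10:60, 1L)
    k <- sample(c(1L, 2L), 1L)
    map <- toy_map(n, chromosomes = as.character(seq_len(k)))
    states <- random_states(n)
    min_snps <- sample(2:4, 1L)
    strict <- sample(c(TRUE, FALSE), 1L)
    got <- find_runs(states, map, min_snps = min_snps, strict = strict)
    want <- oracle_runs(states, map, min_snps = min_snps, strict = strict)
    expect_equal(got$start_index + 1L, want$start_row)
    expect_equal(got$end_index + 1L, want$end_row)
    expect_equal(got$n_informative, want$n_informative)
  }
})

test_that("raising the threshold never adds runs and preserves surviving ones", {
  set.seed(99)
  for (i in seq_len(20L)) {
    states <- random_states(50L)
    map <- toy_map(50L)
    lo <- find_runs(states, map, min_snps = 3L, strict = FALSE)
    hi <- find_runs(states, map, min_snps = 4L, strict = FALSE)
    expect_lte(nrow(hi), nrow(lo))
    if (nrow(hi)) {
      key <- function(r) paste(r$start_index, r$end_index)
      expect_true(all(key(hi) %in% key(lo)))
    }
  }
})

test_that("sample order within a group never changes consensus states", {
  set.seed(5)
  calls <- matrix(sample(c("homA", "het", "homB", "nocall"), 8L * 30L,
                         replace = TRUE), 8L, 30L)
  m <- toy_matrix(calls, rep("affected", 8L))
  perm <- sample(8L)
  m2 <- toy_matrix(calls[perm, , drop = FALSE], rep("affected", 8L))
  expect_equal(consensus_states(m), consensus_states(m2))
})

test_that("converting one called genotype to nocall never shortens a run", {
  set.seed(21)
  n <- 40L
  map <- toy_map(n)
  calls <- matrix("homA", 8L, n)
  calls[, c(5L, 30L)] <- "het"  # blockers delimiting a run at 6..29
  m <- toy_matrix(calls, rep("affected", 8L))
  base <- find_runs(consensus_states(m), map, min_snps = 5L, strict = FALSE)
  for (i in seq_len(20L)) {
    j <- sample(setdiff(7:28, NA), 1L)  # non-boundary SNP inside the run
    s <- sample(2:8, 1L)                # any sample; keep one informative call
    mm <- m
    mm$calls[s, j] <- "nocall"
    perturbed <- find_runs(consensus_states(mm), map, min_snps = 5L,
                           strict = FALSE)
    expect_gte(perturbed$n_snps[1L], base$n_snps[1L])
  }
})

test_that("the carrier filter rejects only runs fully consensus for the same allele", {
  map <- toy_map(10L)
  aff <- state_fixture("nAAAAAAAAn")
  runs <- find_runs(aff, map, min_snps = 5L, strict = FALSE)
  # carriers heterozygous at one SNP inside the run: pass
  car <- state_fixture("nAAAnAAAAn")
  expect_true(carrier_filter(runs, aff, car, map)$carrier_pass)
  # carriers consensus for the identical allele at every SNP: fail
  expect_false(carrier_filter(runs, aff, aff, map)$carrier_pass)
  # carriers consensus but for the other homozygote somewhere: pass
  car2 <- state_fixture("nAAABAAAAn")
  expect_true(carrier_filter(runs, aff, car2, map)$carrier_pass)
  # empty carrier group: undetermined, run retained
  out <- carrier_filter(runs, aff, NULL, map)
  expect_equal(nrow(out), 1L)
  expect_true(is.na(out$carrier_pass))
})

test_that("the genome scan composes the pipeline and sorts largest-first", {
  sim <- simulate_cohort(small_sim_config(), seed = 3L)
  runs <- scan_roh(sim$genotypes, min_snps = 10L, strict = TRUE)
  tr <- sim$truth$segments
  expect_equal(nrow(runs), 2L)
  expect_true(all(runs$carrier_pass))
  expect_equal(runs$n_snps, sort(tr$n_snps, decreasing = TRUE))
  expect_equal(runs$chromosome, tr$chromosome[order(-tr$n_snps)])
  # no affected consensus anywhere: empty result
  flat <- sim$genotypes
  flat$calls[, ] <- "het"
  expect_equal(nrow(scan_roh(flat)), 0L)
})

test_that("a segment homozygous in carriers too is reported but fails the filter", {
  n <- 30L
  map <- toy_map(n)
  calls <- matrix("het", 6L, n)
  calls[, 5:20] <- "homA"  # shared homozygous stretch in everyone
  m <- toy_matrix(calls, c(rep("affected", 4L), rep("carrier", 2L)))
  runs <- scan_roh(m, min_snps = 10L, strict = TRUE)
  expect_equal(nrow(runs), 1L)
  expect_false(runs$carrier_pass)
})
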