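test_that("translation stops at the first stop codon and flags premature ones", {
  r <- translate_cds("ATGTGA")
  expect_equal(r$protein, "M")
  expect_false(r$terminated_early)  # stop at the final codon is normal
  expect_equal(r$stop_codon_number, 2L)
  r <- translate_cds("ATGAAA")
  expect_equal(r$protein, "MK")
  expect_true(is.na(r$stop_codon_number))
  r <- translate_cds("ATGTAAAAA")
  expect_true(r$terminated_early)
  expect_equal(r$stop_codon_number, 2L)
  expect_error(translate_cds("ATGXGA"), "position 4")
  expect_error(translate_cds("AT"), "at least one codon")
})

test_that("translating a prefix is a prefix of translating an extension", {
  set.seed(13)
  pool <- setdiff(names(Biostrings::GENETIC_CODE),
                  c("TAA", "TAG", "TGA"))
  for (i in seq_len(10L)) {
    s <- paste(sample(pool, 10L, replace = TRUE), collapse = "")
    ext <- paste0(s, random_dna(12L))
    p1 <- translate_cds(s)$protein
    p2 <- translate_cds(ext)$protein
    expect_equal(substr(p2, 1L, nchar(p1)), p1)
  }
})

test_that("the exon-6 offset-250 C>T lands on codon 145 as a nonsense R145X", {
  fx <- make_gene_fixture(seed = 1L)
  ve <- classify_variant(fx$model, 6L, 250L, "C", "T")
  expect_equal(ve$cds_position, 433L)        # 183 coding nt in exons 1-5 + 250
  expect_equal(ve$codon_number, 145L)
  expect_equal(ve$ref_codon, "CGA")
  expect_equal(ve$alt_codon, "TGA")
  expect_equal(ve$effect_class, "nonsense")
  expect_equal(ve$label, "R145X")
  # the truncated product has 144 residues
  alt_cds <- fx$cds
  substr(alt_cds, ve$cds_position, ve$cds_position) <- "T"
  tr <- translate_cds(alt_cds)
  expect_equal(nchar(tr$protein), 144L)
  expect_true(tr$terminated_early)
  expect_equal(tr$stop_codon_number, 145L)
})

test_that("variant classification validates its inputs", {
  fx <- make_gene_fixture(seed = 1L)
  expect_error(classify_variant(fx$model, 6L, 250L, "C", "C"), "identical")
  expect_error(classify_variant(fx$model, 6L, 250L, "A", "T"), "model has 'C'")
  expect_error(classify_variant(fx$model, 7L, 1L, "A", "T"), "exon_number")
})

test_that("third-position degeneracy is labelled synonymous", {
  model <- gene_model("ATGGCTAAATAA",
                      exons = data.frame(start_bp = 1L, end_bp = 12L))
  ve <- classify_variant(model, 1L, 6L, "T", "C")  # GCT -> GCC, both Ala
  expect_equal(ve$effect_class, "synonymous")
  expect_equal(ve$label, "A2=")
  ve2 <- classify_variant(model, 1L, 7L, "A", "C")  # AAA -> CAA, Lys -> Gln
  expect_equal(ve2$effect_class, "missense")
  expect_equal(ve2$label, "K3Q")
})

test_that("classification and translation agree on nonsense calls", {
  set.seed(77)
  pool <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (i in seq_len(15L)) {
    cds <- paste(c("ATG", sample(pool, 8L, replace = TRUE), "TAA"),
                 collapse = "")
    model <- gene_model(cds, data.frame(start_bp = 1L, end_bp = nchar(cds)))
    pos <- sample(4:27, 1L)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    ve <- classify_variant(model, 1L, pos, ref, alt)
    alt_cds <- cds
    substr(alt_cds, pos, pos) <- alt
    tr <- translate_cds(alt_cds)
    expect_equal(ve$effect_class == "nonsense",
                 !is.na(tr$stop_codon_number) &&
                   tr$stop_codon_number == ve$codon_number)
  }
})

test_that("digestion cuts after the motif offset and conserves length", {
  expect_equal(digest_dna("AAACATGAAA"), c(7L, 3L))
  expect_equal(digest_dna("AAAAAA"), 6L)
  expect_equal(digest_dna("CATG"), 4L)  # cut at the end produces no empty fragment
  expect_equal(digest_dna("CATGCATG"), c(4L, 4L))
  expect_error(digest_dna("ACGT", motif = ""), "non-empty")
  expect_error(digest_dna("ACGT", cut_offset = 5L), "cut_offset")
})

test_that("fragment counts match an independent occurrence scanner", {
  set.seed(3)
  for (i in seq_len(50L)) {
    s <- random_dna(sample(20:200, 1L))
    frags <- digest_dna(s)
    expect_equal(sum(frags), nchar(s))
    occ <- naive_occurrences(s, "CATG")
    cuts <- unique(occ + 3L)
    cuts <- cuts[cuts < nchar(s)]
    expect_equal(length(frags), length(cuts) + 1L)
  }
})

test_that("the amplicon fixture gives the diagnostic 2/3/4 band patterns", {
  fx <- make_gene_fixture(seed = 1L)
  amp <- fx$amplicon
  cc <- band_pattern(amp$sequence, amp$variant_pos, amp$ref, amp$alt, "CC")
  tt <- band_pattern(amp$sequence, amp$variant_pos, amp$ref, amp$alt, "TT")
  ct <- band_pattern(amp$sequence, amp$variant_pos, amp$ref, amp$alt, "CT")
  expect_equal(cc$n_bands, 2L)  # normal
  expect_equal(tt$n_bands, 3L)  # affected
  expect_equal(ct$n_bands, 4L)  # carrier
  expect_true(all(vapply(tt$allele_fragments,
                         function(f) sum(f) == nchar(amp$sequence), logical(1))))
})

test_that("heterozygote bands are the union of the homozygote bands", {
  set.seed(17)
  for (i in seq_len(20L)) {
    s <- random_dna(150L)
    pos <- sample(10:140, 1L)
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    hom_ref <- band_pattern(s, pos, ref, alt, paste0(ref, ref))
    hom_alt <- band_pattern(s, pos, ref, alt, paste0(alt, alt))
    het <- band_pattern(s, pos, ref, alt, paste0(ref, alt))
    expect_setequal(het$band_lengths,
                    union(hom_ref$band_lengths, hom_alt$band_lengths))
  }
})

test_that("band prediction rejects mismatched references and genotypes", {
  expect_error(band_pattern("AAAA", 2L, "C", "T", "CT"), "expected ref")
  expect_error(band_pattern("ACAA", 2L, "C", "T", "CG"), "genotype")
})

test_that("the printed genotyping table is fully concordant with recessive inheritance", {
  tab <- concordance_table(
    group = c("affected", "carrier", "normal_related", "normal_related",
              "control"),
    genotype = c("TT", "CT", "CT", "CC", "CC"),
    count = c(17L, 3L, 10L, 14L, 46L))
  res <- concordance(tab)
  expect_equal(unname(res$per_group),
               c(1, 1, 1, 1))
  expect_equal(res$overall, 1)
})

test_that("discordant individuals lower the group and pooled rates", {
  tab <- concordance_table(c("affected", "affected"), c("TT", "CT"),
                           c(16L, 1L))
  res <- concordance(tab)
  expect_equal(res$per_group[["affected"]], 16 / 17, tolerance = 1e-12)
  expect_equal(res$overall, 16 / 17, tolerance = 1e-12)
  expect_true(is.na(res$per_group[["control"]]))  # empty group: n/a
  expect_error(concordance(concordance_table(character(), character(),
                                             integer())), "empty")
})

test_that("genotype strings are order-insensitive in concordance scoring", {
  tab <- concordance_table("carrier", "TC", 3L)
  expect_equal(concordance(tab)$per_group[["carrier"]], 1)
})

test_that("gene models round-trip through FASTA plus sidecar", {
  fx <- make_gene_fixture(seed = 2L, out_dir = withr::local_tempdir())
  back <- read_gene_model(fx$paths[["gene_model"]])
  expect_equal(back$sequence, fx$model$sequence)
  expect_equal(back$exons$start_bp, fx$model$exons$start_bp)
  expect_equal(model_cds(back), fx$cds)
})
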