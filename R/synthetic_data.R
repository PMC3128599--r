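## Synthetic study generator: founder haplotypes, an outcross (F1) / backcross
## (F2) pedigree around one carrier sire, planted autozygous segments shared by
## all affected offspring with a causal risk allele private to the founder
## haplotype, chip-style genotypes with no-calls and per-SNP QC metadata, a
## six-exon gene/amplicon fixture for the mutation analyses, and the
## genotyping summary table for concordance scoring.

## stylized ovine-like autosome lengths (Mb), 27 chromosomes
OVINE_LIKE_MB <- c(275, 250, 224, 120, 110, 122, 100, 91, 94, 86, 62, 79, 83,
                   63, 81, 71, 72, 68, 61, 51, 50, 51, 62, 42, 45, 44, 135)

#' Simulation configuration
#'
#' Defaults mirror the study design being emulated: 54,241 mapped SNPs on 27
#' chromosomes, a cohort of 17 affected + 3 carrier chip-typed animals plus 24
#' phenotype-normal relatives and 46 unrelated controls scored at the causal
#' locus only, and three planted autozygous segments of 125, 19 and 11
#' consecutive SNPs (the causal site inside the first).
#'
#' @param n_snps total SNPs on the map.
#' @param n_chromosomes number of chromosomes (stylized lengths are recycled /
#'   truncated from a built-in ovine-like profile).
#' @param n_affected,n_carrier,n_normal_related,n_controls cohort sizes.
#' @param planted_segments data.frame with columns `chromosome`, `n_snps` and
#'   either `target_bp` (segment starts at the mapped SNP nearest this
#'   position) or `start_index` (chromosome-local 1-based SNP index). NULL
#'   uses the default three segments.
#' @param causal_segment which planted segment carries the causal SNP (at its
#'   midpoint).
#' @param maf_range range of the uniform per-SNP minor-allele frequency.
#' @param nocall_rate per-cell no-call probability on the chip.
#' @param qc_fail_rate fraction of SNPs given failing QC metadata (outside the
#'   planted segments), split between low GenTrain and low call rate.
#' @param recomb_rate_per_mb expected crossovers per Mb per meiosis.
#' @param n_founder_ewes number of unrelated founder ewes mated to the carrier
#'   ram; each contributes one carrier F1. Affected individuals are bred from
#'   carrier x carrier matings between F1 half-sibs through different ewes
#'   (consanguineous matings descending from the one carrier ram), so at least
#'   `2 * n_affected` ewes keep the affected parents distinct.
#' @param n_dams number of carrier F1 daughters also backcrossed to the ram
#'   (the backcross arm of the pedigree).
#' @param n_backcross_per_dam backcross offspring per dam.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 54241L, n_chromosomes = 27L,
                       n_affected = 17L, n_carrier = 3L,
                       n_normal_related = 24L, n_controls = 46L,
                       planted_segments = NULL, causal_segment = 1L,
                       maf_range = c(0.05, 0.5), nocall_rate = 0.01,
                       qc_fail_rate = 0.02, recomb_rate_per_mb = 0.013,
                       n_founder_ewes = 36L, n_dams = 10L,
                       n_backcross_per_dam = 2L) {
  if (is.null(planted_segments)) {
    planted_segments <- data.frame(
      chromosome = c("6", "6", "15"),
      target_bp = c(109334543, 118884834, 1131166),
      n_snps = c(125L, 19L, 11L), stringsAsFactors = FALSE)
  }
  planted_segments <- as.data.frame(planted_segments)
  stopifnot(n_affected >= 1L, n_carrier >= 0L, n_carrier <= 3L,
            n_normal_related >= 0L, n_controls >= 0L,
            all(planted_segments$n_snps >= 1L),
            causal_segment >= 1L, causal_segment <= nrow(planted_segments),
            n_founder_ewes >= 2L, n_dams >= 1L, n_backcross_per_dam >= 1L)
  structure(list(n_snps = as.integer(n_snps),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_affected = as.integer(n_affected),
                 n_carrier = as.integer(n_carrier),
                 n_normal_related = as.integer(n_normal_related),
                 n_controls = as.integer(n_controls),
                 planted_segments = planted_segments,
                 causal_segment = as.integer(causal_segment),
                 maf_range = maf_range, nocall_rate = nocall_rate,
                 qc_fail_rate = qc_fail_rate,
                 recomb_rate_per_mb = recomb_rate_per_mb,
                 n_founder_ewes = as.integer(n_founder_ewes),
                 n_dams = as.integer(n_dams),
                 n_backcross_per_dam = as.integer(n_backcross_per_dam)),
            class = "sim_config")
}

## chromosome bp lengths for a config
sim_chrom_lengths <- function(cfg) {
  mb <- rep_len(OVINE_LIKE_MB, cfg$n_chromosomes)
  stats::setNames(as.numeric(mb) * 1e6, as.character(seq_len(cfg$n_chromosomes)))
}

## jittered-grid SNP positions: strictly increasing, roughly uniform
sim_map <- function(cfg) {
  len <- sim_chrom_lengths(cfg)
  alloc <- floor(cfg$n_snps * len / sum(len))
  short <- cfg$n_snps - sum(alloc)
  if (short > 0L) {
    frac <- cfg$n_snps * len / sum(len) - alloc
    alloc[order(-frac)[seq_len(short)]] <- alloc[order(-frac)[seq_len(short)]] + 1L
  }
  chr <- character(0); pos <- numeric(0)
  for (c in names(len)) {
    n_c <- alloc[[c]]
    if (n_c == 0L) next
    spacing <- len[[c]] / (n_c + 1)
    p <- round(seq_len(n_c) * spacing + runif(n_c, -0.45, 0.45) * spacing)
    chr <- c(chr, rep(c, n_c))
    pos <- c(pos, pmax(1, p))
  }
  snp_map(paste0("OAR", chr, "_", pos, ".1"), chr, pos)
}

## resolve planted segments to global map rows; returns data.frame with
## chromosome, start_row, end_row, start_bp, end_bp, n_snps
resolve_segments <- function(cfg, map) {
  segs <- cfg$planted_segments
  out <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    rows <- which(map$chromosome == as.character(segs$chromosome[k]))
    if (!length(rows)) stop("planted segment ", k, ": chromosome ",
                            segs$chromosome[k], " has no SNPs")
    n_k <- segs$n_snps[k]
    if (n_k > length(rows)) {
      stop("planted segment ", k, " (", n_k, " SNPs) longer than chromosome ",
           segs$chromosome[k], " (", length(rows), " SNPs)")
    }
    start_local <- if (!is.null(segs$start_index) && !is.na(segs$start_index[k])) {
      as.integer(segs$start_index[k])
    } else {
      which.min(abs(map$position_bp[rows] - segs$target_bp[k]))
    }
    start_local <- max(1L, min(start_local, length(rows) - n_k + 1L))
    r <- rows[start_local:(start_local + n_k - 1L)]
    out[[k]] <- data.frame(segment = k,
                           chromosome = as.character(segs$chromosome[k]),
                           start_row = r[1L], end_row = r[n_k],
                           start_bp = map$position_bp[r[1L]],
                           end_bp = map$position_bp[r[n_k]],
                           n_snps = n_k, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  o <- order(out$start_row)
  s <- out[o, ]
  overlap <- s$start_row[-1L] <= s$end_row[-nrow(s)] + 2L &
    s$chromosome[-1L] == s$chromosome[-nrow(s)]
  if (nrow(s) > 1L && any(overlap)) {
    stop("planted segments overlap or are separated by fewer than 3 SNPs")
  }
  out
}

## one meiosis: recombinant gamete from a parent's two haplotypes.
## chrom_rows: list of global row indices per chromosome; force_rows: rows to
## overwrite from strand 1 (the founder-haplotype strand, stored first).
make_gamete <- function(h1, h2, map, chrom_rows, chrom_len, rate,
                        force_rows = NULL) {
  g <- integer(length(h1))
  for (c in names(chrom_rows)) {
    idx <- chrom_rows[[c]]
    n_x <- rpois(1L, rate * chrom_len[[c]] / 1e6)
    breaks <- if (n_x > 0L) sort(runif(n_x, 0, chrom_len[[c]])) else numeric(0)
    strand <- (sample(0:1, 1L) + findInterval(map$position_bp[idx], breaks)) %% 2L
    g[idx] <- ifelse(strand == 0L, h1[idx], h2[idx])
  }
  if (length(force_rows)) g[force_rows] <- h1[force_rows]
  g
}

#' Simulate a chip-genotyped cohort with planted autozygous segments
#'
#' Builds the full synthetic study under a single seed: founder haplotypes in
#' linkage equilibrium, a carrier-ram outcross/backcross pedigree, affected F2
#' individuals homozygous for the founder haplotype across every planted
#' segment, carriers heterozygous at the causal site (which is private to the
#' founder haplotype), chip genotypes with random no-calls, and per-SNP QC
#' metadata with a configurable fraction of failing SNPs.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return A `sim_cohort` list: `genotypes` (a [genotype_matrix()] of the
#'   chip-typed affected + carrier samples), `pedigree` (all individuals with
#'   sire/dam/generation/status/causal genotype), `truth` (planted segment
#'   coordinates, causal SNP, group membership, carrier heterozygosity per
#'   segment) and `haplotypes` (per-individual haplotype matrices, for
#'   inheritance checks).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  map <- sim_map(cfg)
  n_snps <- nrow(map)
  segs <- resolve_segments(cfg, map)
  seg_rows_all <- unlist(mapply(seq, segs$start_row, segs$end_row,
                                SIMPLIFY = FALSE))
  planted_chrom_rows <- which(map$chromosome %in% unique(segs$chromosome))
  causal_seg <- segs[segs$segment == cfg$causal_segment, ]
  causal_row <- causal_seg$start_row + (causal_seg$n_snps - 1L) %/% 2L

  chrom_len <- sim_chrom_lengths(cfg)
  chrom_rows <- split(seq_len(n_snps), map$chromosome)[unique(map$chromosome)]
  rate <- cfg$recomb_rate_per_mb
  q <- runif(n_snps, cfg$maf_range[1L], cfg$maf_range[2L])  # B-allele freq

  draw_hap <- function() {
    h <- rbinom(n_snps, 1L, q)
    h[causal_row] <- 0L  # risk allele is private to the founder haplotype
    h
  }

  ## founders: carrier ram (strand 1 = the founder causal haplotype) + ewes
  ids <- character(0); sire <- character(0); dam <- character(0)
  generation <- character(0); sex <- character(0); status <- character(0)
  H1 <- list(); H2 <- list()
  add_ind <- function(id, s, d, gen, sx, st, h1, h2) {
    ids <<- c(ids, id); sire <<- c(sire, s); dam <<- c(dam, d)
    generation <<- c(generation, gen); sex <<- c(sex, sx)
    status <<- c(status, st)
    H1[[id]] <<- h1; H2[[id]] <<- h2
  }
  hstar <- draw_hap()
  hstar[causal_row] <- 1L
  add_ind("RAM", NA, NA, "founder", "M", "carrier", hstar, draw_hap())
  for (e in seq_len(cfg$n_founder_ewes)) {
    add_ind(paste0("EWE", e), NA, NA, "founder", "F", "normal",
            draw_hap(), draw_hap())
  }

  ## F1 outcross: each unrelated ewe contributes one carrier F1 (the ram
  ## gamete is forced to carry the founder haplotype across every planted
  ## segment, so the F1 can pass it on intact); odd-numbered F1 are rams,
  ## even-numbered are ewes
  cF1 <- character(0)
  for (e in seq_len(cfg$n_founder_ewes)) {
    ewe <- paste0("EWE", e)
    id <- paste0("F1_", e)
    gp <- make_gamete(H1[["RAM"]], H2[["RAM"]], map, chrom_rows, chrom_len,
                      rate, force_rows = seg_rows_all)
    gm <- make_gamete(H1[[ewe]], H2[[ewe]], map, chrom_rows, chrom_len, rate)
    add_ind(id, "RAM", ewe, "F1", if (e %% 2L == 0L) "F" else "M", "carrier",
            gp, gm)
    cF1 <- c(cF1, id)
  }
  pairs <- cbind(sire = cF1[seq(1L, length(cF1) - 1L, by = 2L)],
                 dam = cF1[seq(2L, length(cF1), by = 2L)])

  ## consanguineous carrier x carrier matings between half-sib F1 pairs (the
  ## common ancestor is the ram); each mating is continued until it yields an
  ## affected (homozygous founder-haplotype) lamb
  affected_ids <- character(0)
  consang_normal <- character(0)
  n_child <- 0L
  for (a in seq_len(cfg$n_affected)) {
    p <- pairs[(a - 1L) %% nrow(pairs) + 1L, ]
    for (k in seq_len(60L)) {
      n_child <- n_child + 1L
      gp <- make_gamete(H1[[p[["sire"]]]], H2[[p[["sire"]]]], map, chrom_rows,
                        chrom_len, rate)
      gm <- make_gamete(H1[[p[["dam"]]]], H2[[p[["dam"]]]], map, chrom_rows,
                        chrom_len, rate)
      geno <- gp[causal_row] + gm[causal_row]
      id <- paste0("F2_", n_child)
      if (geno == 2L) {
        ## affected: homozygous for the founder haplotype across every planted
        ## segment. Outside the segments (on the planted chromosomes) the
        ## gamete switches to the non-founder parental strand: the shared
        ## segment is delimited by ancestral recombination that the
        ## three-generation pedigree cannot otherwise represent.
        gp[planted_chrom_rows] <- H2[[p[["sire"]]]][planted_chrom_rows]
        gm[planted_chrom_rows] <- H2[[p[["dam"]]]][planted_chrom_rows]
        gp[seg_rows_all] <- H1[[p[["sire"]]]][seg_rows_all]
        gm[seg_rows_all] <- H1[[p[["dam"]]]][seg_rows_all]
        add_ind(id, p[["sire"]], p[["dam"]], "F2", sample(c("F", "M"), 1L),
                "affected", gp, gm)
        affected_ids <- c(affected_ids, id)
        break
      }
      add_ind(id, p[["sire"]], p[["dam"]], "F2", sample(c("F", "M"), 1L),
              "normal", gp, gm)
      consang_normal <- c(consang_normal, id)
      if (k == 60L) stop("failed to generate the affected quota")
    }
  }

  ## backcross arm: carrier F1 daughters mated back to the ram
  backcross_normal <- character(0)
  backcross_ids <- character(0)
  dams <- head(pairs[, "dam"], cfg$n_dams)
  for (d in dams) {
    for (k in seq_len(cfg$n_backcross_per_dam)) {
      n_child <- n_child + 1L
      gp <- make_gamete(H1[["RAM"]], H2[["RAM"]], map, chrom_rows, chrom_len, rate)
      gm <- make_gamete(H1[[d]], H2[[d]], map, chrom_rows, chrom_len, rate)
      geno <- gp[causal_row] + gm[causal_row]
      id <- paste0("F2_", n_child)
      add_ind(id, "RAM", d, "F2", sample(c("F", "M"), 1L),
              if (geno == 2L) "affected" else "normal", gp, gm)
      backcross_ids <- c(backcross_ids, id)
      if (geno < 2L) backcross_normal <- c(backcross_normal, id)
    }
  }

  ## chip carriers: the ram plus the (obligate-carrier) parents of the first
  ## affected lamb
  carrier_ids <- head(c("RAM", pairs[1L, "sire"], pairs[1L, "dam"]),
                      cfg$n_carrier)
  normal_pool <- c(backcross_normal, consang_normal)
  normal_related_ids <- head(sample(normal_pool), cfg$n_normal_related)

  ## chip genotypes for the affected + carrier samples
  chip_ids <- c(affected_ids, carrier_ids)
  chip_status <- c(rep("affected", length(affected_ids)),
                   rep("carrier", length(carrier_ids)))
  G <- t(vapply(chip_ids, function(id) H1[[id]] + H2[[id]],
                integer(n_snps)))
  calls <- matrix(c("homA", "het", "homB")[G + 1L], nrow = nrow(G))

  ## QC metadata: a small fraction of off-segment SNPs fail GenTrain or call
  ## rate; call-rate failures get extra no-calls so the metric is observed
  off_segment <- setdiff(seq_len(n_snps), seg_rows_all)
  n_fail <- round(cfg$qc_fail_rate * n_snps)
  fail_rows <- if (n_fail > 0L) {
    sample(off_segment, min(n_fail, length(off_segment)))
  } else integer(0)
  half <- length(fail_rows) %/% 2L
  gt_fail <- fail_rows[seq_len(half)]
  cr_fail <- setdiff(fail_rows, gt_fail)
  gentrain <- round(runif(n_snps, 0.26, 0.99), 4)
  gentrain[gt_fail] <- round(runif(length(gt_fail), 0.02, 0.24), 4)
  nocall_mask <- matrix(rbinom(length(calls), 1L, cfg$nocall_rate) == 1L,
                        nrow = nrow(calls))
  if (length(cr_fail)) {
    nocall_mask[, cr_fail] <- nocall_mask[, cr_fail] |
      matrix(rbinom(nrow(calls) * length(cr_fail), 1L, 0.6) == 1L,
             nrow = nrow(calls))
  }
  calls[nocall_mask] <- "nocall"
  call_rate <- round(colSums(calls != "nocall") / nrow(calls), 4)
  qc <- data.frame(snp_name = map$snp_name, call_rate = call_rate,
                   gentrain = gentrain, stringsAsFactors = FALSE)

  samples <- data.frame(sample_id = chip_ids, status = chip_status,
                        stringsAsFactors = FALSE)
  gm_out <- genotype_matrix(calls, samples, map, qc = qc)

  causal_geno <- vapply(ids, function(id)
    H1[[id]][causal_row] + H2[[id]][causal_row], integer(1))
  control_ids <- if (cfg$n_controls > 0L) {
    paste0("CTRL", seq_len(cfg$n_controls))
  } else character(0)
  pedigree <- data.frame(
    id = c(ids, control_ids),
    sire = c(sire, rep(NA_character_, length(control_ids))),
    dam = c(dam, rep(NA_character_, length(control_ids))),
    generation = c(generation, rep("founder", length(control_ids))),
    sex = c(sex, rep(NA_character_, length(control_ids))),
    status = c(status, rep("normal", length(control_ids))),
    causal_genotype = c(causal_geno, rep(0L, length(control_ids))),
    stringsAsFactors = FALSE)
  rownames(pedigree) <- NULL

  ## carrier heterozygosity per planted segment (observed, not asserted)
  carrier_het <- matrix(FALSE, length(carrier_ids), nrow(segs),
                        dimnames = list(carrier_ids, paste0("segment", segs$segment)))
  for (ci in seq_along(carrier_ids)) {
    id <- carrier_ids[ci]
    for (k in seq_len(nrow(segs))) {
      r <- segs$start_row[k]:segs$end_row[k]
      carrier_het[ci, k] <- any(H1[[id]][r] != H2[[id]][r])
    }
  }

  truth <- list(
    segments = data.frame(segs,
                          start_index = map$contiguous_index[segs$start_row],
                          end_index = map$contiguous_index[segs$end_row],
                          causal = segs$segment == cfg$causal_segment),
    causal = list(row = causal_row, snp_name = map$snp_name[causal_row],
                  chromosome = map$chromosome[causal_row],
                  position_bp = map$position_bp[causal_row],
                  risk_allele = "T", ref_allele = "C"),
    groups = list(affected = affected_ids, carrier = carrier_ids,
                  normal_related = normal_related_ids, control = control_ids),
    backcross_ids = backcross_ids,
    carrier_het_by_segment = carrier_het)

  structure(list(genotypes = gm_out, pedigree = pedigree, truth = truth,
                 haplotypes = list(H1 = H1, H2 = H2), config = cfg,
                 seed = as.integer(seed)),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort (seed ", x$seed, "): ", nrow(x$pedigree),
      " pedigree members, ", nrow(x$genotypes$samples), " chip-typed\n", sep = "")
  cat("planted segments:\n")
  print.data.frame(x$truth$segments, row.names = FALSE)
  invisible(x)
}

#' Causal-locus genotyping summary table
#'
#' Tallies causal-site genotypes (C = wild-type, T = risk allele) by study
#' group from a simulated cohort, in the layout of a PCR-RFLP genotyping
#' summary: affected, obligate carriers, phenotype-normal relatives, unrelated
#' controls.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @return A [concordance_table()].
#' @export
make_concordance_table <- function(sim) {
  geno_str <- c("CC", "CT", "TT")
  grp <- sim$truth$groups
  rows <- do.call(rbind, lapply(names(grp), function(g) {
    ids <- grp[[g]]
    if (!length(ids)) return(NULL)
    cg <- sim$pedigree$causal_genotype[match(ids, sim$pedigree$id)]
    data.frame(group = g, genotype = geno_str[cg + 1L],
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(list(count = rep(1L, nrow(rows))),
                          by = rows[c("group", "genotype")], FUN = sum)
  concordance_table(agg$group, agg$genotype, agg$count)
}

#' Write a simulated cohort in the chip-report dialects
#'
#' Writes the map, long-format genotype report, sample sheet and QC table that
#' [read_snp_map()], [read_genotype_report()] and [read_sample_sheet()] read.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- sim$genotypes
  paths <- c(map = file.path(dir, "map.tsv"),
             report = file.path(dir, "report.tsv"),
             samples = file.path(dir, "samples.csv"),
             qc = file.path(dir, "qc.csv"))
  write_snp_map(m$map, paths[["map"]])
  write_genotype_report(m, paths[["report"]])
  data.table::fwrite(m$samples, paths[["samples"]])
  data.table::fwrite(m$qc, paths[["qc"]])
  paths
}

## non-stop codons of the standard code
non_stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Generate the six-exon gene and amplicon fixture
#'
#' Builds a synthetic six-exon gene model whose first five exons carry 183
#' coding nt and whose last exon carries the remaining 1341 nt (~88% of the
#' 1524-nt open reading frame), with an arginine codon (CGA) at codon 145 so
#' that a C-to-T substitution at offset +250 of exon 6 creates a premature TGA
#' stop. The companion 400-bp amplicon around the variant carries one
#' constitutive CATG restriction site, the variant site CACG -> CATG created
#' by the T allele strictly inside one constitutive-digest fragment, and no
#' other CATG on either allele, so all digest fragment lengths are pairwise
#' distinct.
#'
#' @param seed integer seed for the random filler codons.
#' @param out_dir optional directory; when given, the gene model (FASTA + JSON
#'   sidecar) and amplicon FASTA are written there.
#' @return A `gene_fixture` list: `model` (a [gene_model()]), `cds`,
#'   `amplicon` (sequence, `variant_pos`, `ref`, `alt`, `constitutive_site`),
#'   `variant` (`exon`, `offset`, `ref`, `alt`) and any written `paths`.
#' @export
make_gene_fixture <- function(seed = 1L, out_dir = NULL) {
  set.seed(as.integer(seed))
  pool <- non_stop_codons()
  n_codons <- 508L  # 507 amino acids + terminal stop; CDS 1524 nt
  fixed <- c(`1` = "ATG", `111` = "AGC", `112` = "ATG", `144` = "GCA",
             `145` = "CGA", `508` = "TAA")
  amp_cds_start <- 244L; amp_cds_end <- 643L  # 400-bp amplicon window in CDS
  amp_codons <- ((amp_cds_start - 1L) %/% 3L + 1L):((amp_cds_end - 1L) %/% 3L + 1L)
  build <- function(codons) paste(codons, collapse = "")
  codons <- sample(pool, n_codons, replace = TRUE)
  codons[as.integer(names(fixed))] <- fixed
  for (try in seq_len(200L)) {
    cds <- build(codons)
    amp_ref <- substr(cds, amp_cds_start, amp_cds_end)
    amp_alt <- amp_ref
    substr(amp_alt, 190L, 190L) <- "T"
    site_ref <- Biostrings::start(Biostrings::matchPattern("CATG",
                                                           Biostrings::DNAString(amp_ref)))
    site_alt <- Biostrings::start(Biostrings::matchPattern("CATG",
                                                           Biostrings::DNAString(amp_alt)))
    if (identical(as.integer(site_ref), 90L) &&
        identical(sort(as.integer(site_alt)), c(90L, 188L))) break
    ## resample free codons in the amplicon window and retry
    bad <- setdiff(amp_codons, as.integer(names(fixed)))
    codons[bad] <- sample(pool, length(bad), replace = TRUE)
    if (try == 200L) stop("could not realize a clean amplicon fixture")
  }
  ## assemble genomic sequence: six exons separated by 2.9-kb random introns
  exon_cds_len <- c(48L, 30L, 36L, 33L, 36L, 1341L)
  stopifnot(sum(exon_cds_len) == nchar(cds))
  bounds <- cumsum(exon_cds_len)
  exon_seqs <- substring(cds, c(1L, head(bounds, -1L) + 1L), bounds)
  intron_len <- 2900L
  introns <- vapply(seq_len(5L), function(i)
    paste(sample(c("A", "C", "G", "T"), intron_len, replace = TRUE),
          collapse = ""), character(1))
  genomic <- paste0(exon_seqs[1L], introns[1L], exon_seqs[2L], introns[2L],
                    exon_seqs[3L], introns[3L], exon_seqs[4L], introns[4L],
                    exon_seqs[5L], introns[5L], exon_seqs[6L])
  starts <- integer(6L); ends <- integer(6L); pos <- 1L
  for (i in seq_len(6L)) {
    starts[i] <- pos
    ends[i] <- pos + exon_cds_len[i] - 1L
    pos <- ends[i] + 1L + if (i < 6L) intron_len else 0L
  }
  model <- gene_model(genomic, data.frame(start_bp = starts, end_bp = ends))
  fixture <- list(model = model, cds = cds,
                  amplicon = list(sequence = amp_ref, variant_pos = 190L,
                                  ref = "C", alt = "T",
                                  constitutive_site = 90L),
                  variant = list(exon = 6L, offset = 250L, ref = "C", alt = "T"))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    gm_path <- file.path(out_dir, "gene_model_synthetic.fa")
    write_gene_model(model, gm_path)
    amp <- Biostrings::DNAStringSet(amp_ref)
    names(amp) <- "amplicon_synthetic"
    amp_path <- file.path(out_dir, "amplicon_synthetic.fa")
    Biostrings::writeXStringSet(amp, amp_path)
    fixture$paths <- c(gene_model = gm_path, amplicon = amp_path)
  }
  class(fixture) <- "gene_fixture"
  fixture
}

#' Simulate a nine-SNP exon panel with a perfect LD block
#'
#' Generates unphased genotypes at nine tightly linked SNPs from three
#' haplotype backgrounds: SNPs 1-4 share one background split (a perfect
#' mutual-LD block), SNP 5 is the causal site segregating on a distinct
#' haplotype (within one of the block backgrounds, so block-vs-causal r2 < 1),
#' and SNPs 6-9 segregate independently.
#'
#' @param n individuals.
#' @param seed integer seed.
#' @return A [genotype_matrix()] of `n` samples x 9 SNPs; the causal SNP is
#'   `DMP1ex6_5`.
#' @export
simulate_exon6_panel <- function(n = 50L, seed = 1L) {
  set.seed(as.integer(seed))
  n_hap <- 2L * n
  cls <- sample(c("A", "B", "C"), n_hap, replace = TRUE,
                prob = c(0.40, 0.35, 0.25))
  block <- as.integer(cls == "A")
  causal <- as.integer(cls == "C")
  hap <- cbind(block, block, block, block, causal,
               matrix(rbinom(n_hap * 4L, 1L, 0.3), ncol = 4L))
  g <- hap[seq_len(n), ] + hap[n + seq_len(n), ]
  calls <- matrix(c("homA", "het", "homB")[g + 1L], nrow = n)
  map <- snp_map(paste0("DMP1ex6_", 1:9), rep("6", 9L),
                 112213500 + (1:9) * 40L)
  samples <- data.frame(sample_id = paste0("S", seq_len(n)),
                        status = "unknown", stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, map)
}
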