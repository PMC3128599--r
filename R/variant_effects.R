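## Mutation analyses: CDS translation, substitution-effect classification
## (synonymous / missense / nonsense) under an exon gene model, in-silico
## PCR-RFLP digestion (NlaIII-style motif cutting) with gel-band prediction,
## and genotype-phenotype concordance scoring under a recessive model.

check_dna <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGT]", seq)
  if (bad != -1L) {
    stop(what, " contains non-ACGT character '", substr(seq, bad, bad),
         "' at position ", bad)
  }
  invisible(seq)
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Translate a coding sequence
#'
#' Standard genetic code, reading frame starting at position 1. Translation
#' stops at the first stop codon; a stop at the final codon is normal
#' termination, an earlier one is premature.
#'
#' @param cds DNA string (character), length >= 3, alphabet ACGT. A trailing
#'   incomplete codon is dropped with a warning.
#' @return list with `protein` (amino acids up to but excluding the stop),
#'   `terminated_early` (TRUE iff a stop codon occurs before the final codon)
#'   and `stop_codon_number` (1-based codon index of the first stop, or NA if
#'   none).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) < 3L) stop("CDS must be at least one codon (3 nt)")
  check_dna(cds, "CDS")
  n_codons <- nchar(cds) %/% 3L
  if (nchar(cds) %% 3L != 0L) {
    warning("CDS length not a multiple of 3; trailing ", nchar(cds) %% 3L,
            " nt ignored")
    cds <- substr(cds, 1L, n_codons * 3L)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at == -1L) {
    list(protein = aa, terminated_early = FALSE, stop_codon_number = NA_integer_)
  } else {
    list(protein = substr(aa, 1L, stop_at - 1L),
         terminated_early = stop_at < n_codons,
         stop_codon_number = as.integer(stop_at))
  }
}

#' Gene model constructor
#'
#' An exon/CDS model on a reference sequence. `cds_start_offset` and
#' `cds_end_offset` delimit the coding region within the concatenated exonic
#' sequence (1-based inclusive).
#'
#' @param sequence reference DNA (character), e.g. the genomic span of the
#'   gene.
#' @param exons data.frame with `start_bp`, `end_bp` (1-based inclusive on
#'   `sequence`), ordered, non-overlapping.
#' @param cds_start_offset,cds_end_offset coding-region limits in exonic
#'   coordinates; the coding length must be divisible by 3.
#' @return A `gene_model` object.
#' @export
gene_model <- function(sequence, exons, cds_start_offset = 1L,
                       cds_end_offset = NULL) {
  sequence <- toupper(as.character(sequence))
  check_dna(sequence, "gene sequence")
  exons <- as.data.frame(exons)
  stopifnot(all(c("start_bp", "end_bp") %in% names(exons)),
            all(exons$start_bp <= exons$end_bp),
            all(exons$end_bp <= nchar(sequence)))
  if (nrow(exons) > 1L && any(exons$start_bp[-1L] <= exons$end_bp[-nrow(exons)])) {
    stop("exons must be ordered and non-overlapping")
  }
  exonic_len <- sum(exons$end_bp - exons$start_bp + 1L)
  if (is.null(cds_end_offset)) cds_end_offset <- exonic_len
  cds_len <- cds_end_offset - cds_start_offset + 1L
  if (cds_len %% 3L != 0L) {
    stop("coding length (", cds_len, " nt) is not divisible by 3")
  }
  structure(list(sequence = sequence, exons = exons,
                 cds_start_offset = as.integer(cds_start_offset),
                 cds_end_offset = as.integer(cds_end_offset)),
            class = "gene_model")
}

## concatenated exonic sequence of a model
exonic_seq <- function(model) {
  paste(substring(model$sequence, model$exons$start_bp, model$exons$end_bp),
        collapse = "")
}

#' Coding sequence of a gene model
#'
#' @param model a [gene_model()].
#' @return The CDS as a character string.
#' @export
model_cds <- function(model) {
  substr(exonic_seq(model), model$cds_start_offset, model$cds_end_offset)
}

#' Write / read a gene model (FASTA + JSON sidecar)
#'
#' The sequence goes to FASTA (via Biostrings) and the exon structure and CDS
#' offsets to a small JSON sidecar next to it.
#'
#' @param model a [gene_model()].
#' @param fasta_path FASTA output path; the sidecar is `<fasta_path>.json`.
#' @return the FASTA path, invisibly.
#' @export
write_gene_model <- function(model, fasta_path) {
  seqs <- Biostrings::DNAStringSet(model$sequence)
  names(seqs) <- "gene_model"
  Biostrings::writeXStringSet(seqs, fasta_path)
  jsonlite::write_json(
    list(exons = model$exons, cds_start_offset = model$cds_start_offset,
         cds_end_offset = model$cds_end_offset),
    paste0(fasta_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(fasta_path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- jsonlite::read_json(paste0(fasta_path, ".json"), simplifyVector = TRUE)
  gene_model(as.character(seqs[[1L]]), meta$exons,
             meta$cds_start_offset, meta$cds_end_offset)
}

#' Classify a single-base substitution under a gene model
#'
#' Maps an exon-relative offset to a CDS coordinate and codon, then classifies
#' the substitution as synonymous, missense or nonsense (alt codon is a stop
#' while the reference codon is not). The label is the one-letter reference
#' amino acid, the codon number, and the alternate amino acid ("X" for a stop,
#' "=" for synonymous), e.g. "R145X".
#'
#' @param model a [gene_model()].
#' @param exon_number 1-based exon index.
#' @param offset_in_exon 1-based offset within that exon (the "+250 bp of exon
#'   6" convention).
#' @param ref,alt reference and alternate bases; `ref` must match the model
#'   sequence.
#' @return A `variant_effect` list: `cds_position`, `exon_number`,
#'   `offset_in_exon`, `ref_base`, `alt_base`, `codon_number`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `effect_class`, `label`.
#' @export
classify_variant <- function(model, exon_number, offset_in_exon, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(ref %in% c("A", "C", "G", "T"), alt %in% c("A", "C", "G", "T"))
  if (ref == alt) stop("ref and alt are identical (", ref, "): not a variant")
  if (exon_number < 1L || exon_number > nrow(model$exons)) {
    stop("exon_number out of range")
  }
  ex <- model$exons[exon_number, ]
  exon_len <- ex$end_bp - ex$start_bp + 1L
  if (offset_in_exon < 1L || offset_in_exon > exon_len) {
    stop("offset_in_exon outside exon ", exon_number, " (length ", exon_len, ")")
  }
  prev_len <- if (exon_number > 1L) {
    sum(model$exons$end_bp[1:(exon_number - 1L)] -
          model$exons$start_bp[1:(exon_number - 1L)] + 1L)
  } else 0L
  exonic_pos <- prev_len + offset_in_exon
  if (exonic_pos < model$cds_start_offset || exonic_pos > model$cds_end_offset) {
    stop("position is outside the coding region")
  }
  genomic_pos <- ex$start_bp + offset_in_exon - 1L
  found <- substr(model$sequence, genomic_pos, genomic_pos)
  if (found != ref) {
    stop("reference mismatch at exon ", exon_number, " offset ", offset_in_exon,
         ": model has '", found, "', got '", ref, "'")
  }
  cds_position <- exonic_pos - model$cds_start_offset + 1L
  codon_number <- (cds_position - 1L) %/% 3L + 1L
  pos_in_codon <- (cds_position - 1L) %% 3L + 1L
  cds <- model_cds(model)
  ref_codon <- substr(cds, (codon_number - 1L) * 3L + 1L, codon_number * 3L)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt
  ref_aa <- codon_aa(ref_codon)
  alt_aa <- codon_aa(alt_codon)
  effect_class <- if (alt_aa == ref_aa) "synonymous"
  else if (alt_aa == "*" && ref_aa != "*") "nonsense"
  else "missense"
  label <- paste0(ref_aa, codon_number,
                  switch(effect_class, synonymous = "=", nonsense = "X",
                         missense = alt_aa))
  structure(list(cds_position = cds_position, exon_number = exon_number,
                 offset_in_exon = offset_in_exon, ref_base = ref,
                 alt_base = alt, codon_number = codon_number,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 effect_class = effect_class, label = label),
            class = "variant_effect")
}

#' @export
print.variant_effect <- function(x, ...) {
  cat(x$label, ": ", x$effect_class, ", exon ", x$exon_number, " offset +",
      x$offset_in_exon, ", CDS ", x$cds_position, " (", x$ref_codon, "->",
      x$alt_codon, ", codon ", x$codon_number, ")\n", sep = "")
  invisible(x)
}

#' In-silico restriction digest
#'
#' Finds all (possibly overlapping) occurrences of the recognition motif on
#' the given strand and cuts after `cut_offset` bases of each occurrence. The
#' default models NlaIII: motif CATG, cut 3' of the G. Fragment lengths are
#' strand-independent at this level for a palindromic-site enzyme, so a single
#' strand is scanned.
#'
#' @param seq DNA string (character).
#' @param motif recognition sequence, non-empty.
#' @param cut_offset cut after this many bases of the motif, in
#'   `[0, nchar(motif)]`.
#' @return Ordered integer vector of fragment lengths; always sums to
#'   `nchar(seq)`.
#' @export
digest_dna <- function(seq, motif = "CATG", cut_offset = 4L) {
  seq <- toupper(as.character(seq))
  motif <- toupper(as.character(motif))
  if (nchar(motif) < 1L) stop("motif must be non-empty")
  if (cut_offset < 0L || cut_offset > nchar(motif)) {
    stop("cut_offset must be in [0, nchar(motif)]")
  }
  n <- nchar(seq)
  if (n == 0L) return(integer())
  check_dna(seq, "sequence")
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  cuts <- Biostrings::start(hits) - 1L + cut_offset
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  as.integer(diff(c(0L, cuts, n)))
}

#' Predicted gel band pattern of a genotype
#'
#' Digests the one or two allele sequences implied by a biallelic genotype at
#' a known variant position in an amplicon, and pools the distinct fragment
#' lengths: a band is a distinct length (equal lengths co-migrate).
#'
#' @param amplicon_ref reference amplicon sequence (carrying `ref` at
#'   `variant_pos`).
#' @param variant_pos 1-based position of the variant in the amplicon.
#' @param ref,alt the two alleles.
#' @param genotype two-allele string drawn from `ref`/`alt` letters, e.g.
#'   "CC", "CT" or "TT" for a C/T variant (order-insensitive).
#' @param motif,cut_offset recognition site, as in [digest_dna()].
#' @return A `digest_pattern` list: `allele_fragments` (per-allele ordered
#'   fragment lengths), `band_lengths` (sorted distinct pooled lengths),
#'   `n_bands`.
#' @export
band_pattern <- function(amplicon_ref, variant_pos, ref, alt, genotype,
                         motif = "CATG", cut_offset = 4L) {
  amplicon_ref <- toupper(as.character(amplicon_ref))
  ref <- toupper(ref); alt <- toupper(alt)
  found <- substr(amplicon_ref, variant_pos, variant_pos)
  if (found != ref) {
    stop("amplicon has '", found, "' at position ", variant_pos,
         ", expected ref '", ref, "'")
  }
  alleles <- strsplit(toupper(genotype), "")[[1L]]
  if (length(alleles) != 2L || !all(alleles %in% c(ref, alt))) {
    stop("genotype must be two alleles drawn from ", ref, "/", alt)
  }
  amplicon_alt <- amplicon_ref
  substr(amplicon_alt, variant_pos, variant_pos) <- alt
  allele_seqs <- ifelse(alleles == ref, amplicon_ref, amplicon_alt)
  frags <- lapply(unique(allele_seqs), digest_dna, motif = motif,
                  cut_offset = cut_offset)
  names(frags) <- ifelse(unique(allele_seqs) == amplicon_ref, ref, alt)
  bands <- sort(unique(unlist(frags)))
  structure(list(allele_fragments = frags, band_lengths = bands,
                 n_bands = length(bands)),
            class = "digest_pattern")
}

#' @export
print.digest_pattern <- function(x, ...) {
  cat("digest_pattern: ", x$n_bands, " band(s): ",
      paste(x$band_lengths, collapse = ", "), " bp\n", sep = "")
  for (a in names(x$allele_fragments)) {
    cat("  allele ", a, ": ",
        paste(x$allele_fragments[[a]], collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}

#' Concordance table constructor
#'
#' @param group character vector over `affected`/`carrier`/`normal_related`/
#'   `control`.
#' @param genotype biallelic genotype strings (e.g. "CC", "CT", "TT";
#'   order-insensitive).
#' @param count non-negative integer counts.
#' @return A `concordance_table` data.frame.
#' @export
concordance_table <- function(group, genotype, count) {
  groups <- c("affected", "carrier", "normal_related", "control")
  stopifnot(all(group %in% groups), all(count >= 0))
  genotype <- vapply(strsplit(toupper(genotype), ""),
                     function(a) paste(sort(a), collapse = ""), character(1))
  t <- data.frame(group = group, genotype = genotype, count = as.integer(count),
                  stringsAsFactors = FALSE)
  class(t) <- c("concordance_table", "data.frame")
  t
}

#' Genotype-phenotype concordance under a recessive model
#'
#' An individual is concordant with the autosomal-recessive model when:
#' affected implies homozygous risk; carrier implies heterozygous; normal
#' (related or control) implies not homozygous risk. Per-group rates are
#' reported along with a pooled rate over every individual in the table.
#'
#' @param table a [concordance_table()].
#' @param risk_allele the recessive risk allele letter (default "T").
#' @param ref_allele the wild-type allele letter (default "C").
#' @return list with `per_group` (named fraction vector, NA for empty groups)
#'   and `overall` (pooled fraction).
#' @export
concordance <- function(table, risk_allele = "T", ref_allele = "C") {
  if (nrow(table) == 0L || sum(table$count) == 0L) {
    stop("empty concordance table: at least one individual required")
  }
  hom_risk <- paste(sort(c(risk_allele, risk_allele)), collapse = "")
  het <- paste(sort(c(ref_allele, risk_allele)), collapse = "")
  ok <- ifelse(table$group == "affected", table$genotype == hom_risk,
        ifelse(table$group == "carrier", table$genotype == het,
               table$genotype != hom_risk))
  groups <- c("affected", "carrier", "normal_related", "control")
  per_group <- vapply(groups, function(g) {
    tot <- sum(table$count[table$group == g])
    if (tot == 0L) NA_real_ else sum(table$count[table$group == g & ok]) / tot
  }, numeric(1))
  list(per_group = per_group,
       overall = sum(table$count[ok]) / sum(table$count))
}
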