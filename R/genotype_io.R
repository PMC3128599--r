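#' @importFrom data.table fread fwrite data.table as.data.table
#' @importFrom stats rbinom runif rpois setNames rmultinom
#' @importFrom utils head tail
NULL

GENO_LEVELS <- c("homA", "het", "homB", "nocall")
STATUS_LEVELS <- c("affected", "carrier", "normal", "unknown")

## numeric-aware ordering of chromosome names: "2" < "10" < "X"
chrom_order <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  order(is.na(num), num, chr)
}

chrom_rank <- function(chr) {
  lev <- unique(chr)
  lev <- lev[chrom_order(lev)]
  match(chr, lev)
}

#' SNP map constructor
#'
#' Builds an ordered SNP map: entries are sorted by (chromosome, position) and
#' assigned a contiguous 0-based index in that order, the coordinate system in
#' which "consecutive SNPs" is defined for run finding.
#'
#' @param snp_name character vector of unique SNP names.
#' @param chromosome character vector of chromosome names (numeric-aware
#'   ordering: "2" sorts before "10").
#' @param position_bp integer vector of 1-based bp positions, strictly
#'   increasing within a chromosome after sorting.
#' @return A `snp_map` data.frame with columns `snp_name`, `chromosome`,
#'   `position_bp`, `contiguous_index`.
#' @export
snp_map <- function(snp_name, chromosome, position_bp) {
  snp_name <- as.character(snp_name)
  chromosome <- as.character(chromosome)
  if (length(snp_name) == 0L) {
    m <- data.frame(snp_name = character(), chromosome = character(),
                    position_bp = integer(), contiguous_index = integer(),
                    stringsAsFactors = FALSE)
    class(m) <- c("snp_map", "data.frame")
    return(m)
  }
  if (anyDuplicated(snp_name)) {
    dup <- unique(snp_name[duplicated(snp_name)])
    stop("duplicate SNP name(s) in map: ", paste(head(dup, 5L), collapse = ", "))
  }
  if (any(!is.finite(position_bp)) || any(position_bp < 1)) {
    stop("positions must be positive integers")
  }
  position_bp <- as.integer(position_bp)
  o <- order(chrom_rank(chromosome), position_bp)
  m <- data.frame(snp_name = snp_name[o], chromosome = chromosome[o],
                  position_bp = position_bp[o],
                  contiguous_index = seq_along(snp_name) - 1L,
                  stringsAsFactors = FALSE)
  same_chr <- m$chromosome[-1L] == m$chromosome[-nrow(m)]
  if (nrow(m) > 1L && any(same_chr & diff(m$position_bp) == 0L)) {
    i <- which(same_chr & diff(m$position_bp) == 0L)[1L]
    stop("tied positions within chromosome ", m$chromosome[i], " at ",
         m$position_bp[i], " (", m$snp_name[i], ", ", m$snp_name[i + 1L], ")")
  }
  rownames(m) <- NULL
  class(m) <- c("snp_map", "data.frame")
  m
}

#' Read a SNP map file
#'
#' Reads a delimited (tab or comma) map file with SNP name, chromosome and bp
#' position columns, sorts by chromosome and position and assigns contiguous
#' indices. Input row order is irrelevant.
#'
#' @param path path to the map file.
#' @param col_names length-3 character vector naming the (snp, chromosome,
#'   position) columns when the file has a header; ignored for headerless
#'   files, where the first three columns are used.
#' @return A [snp_map()] object.
#' @export
read_snp_map <- function(path, col_names = c("snp_name", "chromosome", "position")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(snp_map(character(), character(), integer()))
  dt <- data.table::fread(path, header = "auto", colClasses = "character",
                          data.table = TRUE, showProgress = FALSE)
  if (nrow(dt) == 0L) return(snp_map(character(), character(), integer()))
  if (all(col_names %in% names(dt))) {
    dt <- dt[, col_names, with = FALSE]
  } else {
    if (ncol(dt) < 3L) stop("map file needs at least 3 columns (name, chromosome, position)")
    dt <- dt[, 1:3]
  }
  names(dt) <- c("snp_name", "chromosome", "position")
  pos <- suppressWarnings(as.numeric(dt$position))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop("non-numeric position '", dt$position[bad], "' at data line ", bad,
         " of ", path)
  }
  snp_map(dt$snp_name, dt$chromosome, pos)
}

#' Write a SNP map file
#'
#' @param map a [snp_map()] object.
#' @param path output path; tab-delimited with header.
#' @export
write_snp_map <- function(map, path) {
  data.table::fwrite(
    data.table::data.table(snp_name = map$snp_name, chromosome = map$chromosome,
                           position = map$position_bp),
    path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id` and `status`
#'   (affected/carrier/normal/unknown).
#' @return data.frame with columns `sample_id`, `status`.
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  if (!all(c("sample_id", "status") %in% names(dt))) {
    stop("sample sheet must have columns sample_id, status")
  }
  ss <- as.data.frame(dt[, c("sample_id", "status")])
  bad <- setdiff(unique(ss$status), STATUS_LEVELS)
  if (length(bad)) {
    stop("unknown status value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(STATUS_LEVELS, collapse = ", "), ")")
  }
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  ss
}

## normalize an allele-pair string to the four-symbol alphabet; order-insensitive
decode_ab <- function(a1, a2) {
  g <- paste0(a1, a2)
  out <- rep(NA_character_, length(g))
  out[g %in% c("AA")] <- "homA"
  out[g %in% c("AB", "BA")] <- "het"
  out[g %in% c("BB")] <- "homB"
  out[g %in% c("--", "", "NCNC", "NANA") | a1 %in% c("-", "N", "") |
        a2 %in% c("-", "N", "")] <- "nocall"
  if (anyNA(out)) {
    stop("unrecognized genotype code(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "))
  }
  out
}

decode_cell <- function(x) {
  x[x %in% c("--", "NC", "", NA)] <- "nocall"
  known <- x %in% GENO_LEVELS
  x[!known & x %in% c("AA")] <- "homA"
  x[!known & x %in% c("AB", "BA")] <- "het"
  x[!known & x %in% c("BB")] <- "homB"
  if (!all(x %in% GENO_LEVELS)) {
    stop("unrecognized genotype code(s): ",
         paste(unique(x[!x %in% GENO_LEVELS]), collapse = ", "))
  }
  x
}

#' Genotype matrix constructor
#'
#' @param calls character matrix (samples x SNPs) over
#'   `homA`/`het`/`homB`/`nocall`; rows named by sample, columns by SNP in map
#'   order.
#' @param samples data.frame with `sample_id` and `status`.
#' @param map a [snp_map()] aligned to the columns of `calls`.
#' @param qc optional data.frame with `snp_name`, `call_rate`, `gentrain`.
#' @return A `genotype_matrix` object (list with elements `calls`, `samples`,
#'   `map`, `qc`).
#' @export
genotype_matrix <- function(calls, samples, map, qc = NULL) {
  stopifnot(is.matrix(calls), is.data.frame(samples))
  if (nrow(calls) != nrow(samples)) stop("calls rows must match samples")
  if (ncol(calls) != nrow(map)) stop("calls columns must match map entries")
  if (!all(calls %in% GENO_LEVELS)) {
    stop("calls must be one of ", paste(GENO_LEVELS, collapse = "/"))
  }
  bad <- setdiff(unique(samples$status), STATUS_LEVELS)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  rownames(calls) <- samples$sample_id
  colnames(calls) <- map$snp_name
  if (!is.null(qc)) {
    qc <- as.data.frame(qc)
    if (!all(c("snp_name", "call_rate", "gentrain") %in% names(qc))) {
      stop("qc needs columns snp_name, call_rate, gentrain")
    }
    qc <- qc[match(map$snp_name, qc$snp_name), , drop = FALSE]
    if (anyNA(qc$snp_name)) stop("qc missing entries for some map SNPs")
    rownames(qc) <- NULL
  }
  structure(list(calls = calls, samples = samples, map = map, qc = qc),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  st <- table(factor(x$samples$status, levels = STATUS_LEVELS))
  cat("genotype_matrix: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " SNPs on ", length(unique(x$map$chromosome)), " chromosome(s)\n", sep = "")
  cat("  status: ", paste(names(st), st, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  QC metadata: ", if (is.null(x$qc)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Read a genotype report
#'
#' Reads either a GenomeStudio-like long-format "Final Report" (one row per
#' sample x SNP with A/B allele columns) or a simple matrix CSV (one row per
#' sample, one column per SNP). Cells absent from the report become `nocall`;
#' column order follows the map's contiguous index.
#'
#' @param path report file.
#' @param map a [snp_map()]; every SNP in the report must be present in it.
#' @param samples data.frame (`sample_id`, `status`) or path to a sample-sheet
#'   CSV. Report rows for samples not in the sheet are an error; sheet samples
#'   absent from the report get all-`nocall` rows.
#' @param dialect `"long"` (default) or `"matrix"`.
#' @param long_cols named character vector giving the long-format column names
#'   for `sample`, `snp`, `a1`, `a2` and optionally `gc` (GenTrain score).
#' @return A [genotype_matrix()].
#' @export
read_genotype_report <- function(path, map, samples,
                                 dialect = c("long", "matrix"),
                                 long_cols = c(sample = "Sample ID",
                                               snp = "SNP Name",
                                               a1 = "Allele1 - AB",
                                               a2 = "Allele2 - AB")) {
  dialect <- match.arg(dialect)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  dt <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  calls <- matrix("nocall", nrow = nrow(samples), ncol = nrow(map),
                  dimnames = list(samples$sample_id, map$snp_name))
  if (dialect == "long") {
    need <- long_cols[c("sample", "snp", "a1", "a2")]
    if (!all(need %in% names(dt))) {
      stop("long report must have columns: ", paste(need, collapse = ", "))
    }
    sid <- dt[[need[["sample"]]]]
    snp <- dt[[need[["snp"]]]]
    unknown <- setdiff(unique(snp), map$snp_name)
    if (length(unknown)) {
      stop("SNP(s) in report not in map: ", paste(head(unknown, 5L), collapse = ", "))
    }
    unknown_s <- setdiff(unique(sid), samples$sample_id)
    if (length(unknown_s)) {
      stop("sample(s) in report not in sample sheet: ",
           paste(head(unknown_s, 5L), collapse = ", "))
    }
    key <- paste(sid, snp, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stop("duplicate (sample, SNP) row in report: ",
           gsub("\r", " / ", d, fixed = TRUE))
    }
    g <- decode_ab(dt[[need[["a1"]]]], dt[[need[["a2"]]]])
    calls[cbind(match(sid, samples$sample_id), match(snp, map$snp_name))] <- g
  } else {
    if (ncol(dt) < 1L) stop("empty matrix report")
    sid <- dt[[1L]]
    unknown_s <- setdiff(unique(sid), samples$sample_id)
    if (length(unknown_s)) {
      stop("sample(s) in report not in sample sheet: ",
           paste(head(unknown_s, 5L), collapse = ", "))
    }
    if (anyDuplicated(sid)) stop("duplicate sample row in matrix report")
    snps <- names(dt)[-1L]
    unknown <- setdiff(snps, map$snp_name)
    if (length(unknown)) {
      stop("SNP(s) in report not in map: ", paste(head(unknown, 5L), collapse = ", "))
    }
    g <- apply(as.matrix(dt[, -1L, drop = FALSE]), 2L, decode_cell)
    if (is.null(dim(g))) g <- matrix(g, nrow = length(sid))
    calls[match(sid, samples$sample_id), match(snps, map$snp_name)] <- g
  }
  genotype_matrix(calls, samples, map)
}

#' Write a genotype report (long GenomeStudio-like dialect)
#'
#' No-call cells are written as `-`/`-` allele pairs; the output round-trips
#' through [read_genotype_report()].
#'
#' @param m a [genotype_matrix()].
#' @param path output path (tab-delimited).
#' @export
write_genotype_report <- function(m, path) {
  a1 <- c(homA = "A", het = "A", homB = "B", nocall = "-")
  a2 <- c(homA = "A", het = "B", homB = "B", nocall = "-")
  g <- as.vector(m$calls)  # column-major: SNP blocks
  dt <- data.table::data.table(
    `Sample ID` = rep(m$samples$sample_id, times = ncol(m$calls)),
    `SNP Name` = rep(m$map$snp_name, each = nrow(m$calls)),
    `Allele1 - AB` = a1[g],
    `Allele2 - AB` = a2[g])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

## subset a genotype matrix by SNP positions (logical or integer), reindexing
## the map contiguously
subset_snps <- function(m, keep) {
  map <- m$map[keep, , drop = FALSE]
  map$contiguous_index <- seq_len(nrow(map)) - 1L
  rownames(map) <- NULL
  class(map) <- c("snp_map", "data.frame")
  genotype_matrix(m$calls[, keep, drop = FALSE], m$samples, map,
                  qc = if (is.null(m$qc)) NULL else m$qc[keep, , drop = FALSE])
}

subset_samples <- function(m, keep) {
  genotype_matrix(m$calls[keep, , drop = FALSE],
                  m$samples[keep, , drop = FALSE], m$map, qc = m$qc)
}

#' Apply per-SNP quality-control filters
#'
#' Removes SNPs failing the chip QC rule: retained SNPs must have call rate
#' strictly greater than `min_call_rate` and GenTrain score at least
#' `min_gentrain`. No sample is removed and no allele-frequency filter is
#' applied. Surviving SNPs are re-indexed contiguously, which defines the
#' adjacency used downstream by run finding.
#'
#' @param m a [genotype_matrix()] with QC metadata.
#' @param min_call_rate call-rate threshold (strict `>`), default 0.80.
#' @param min_gentrain GenTrain threshold (inclusive `>=`), default 0.25.
#' @param quiet suppress the removal-count message.
#' @return A filtered [genotype_matrix()].
#' @export
apply_qc <- function(m, min_call_rate = 0.80, min_gentrain = 0.25, quiet = FALSE) {
  if (is.null(m$qc)) {
    stop("no QC metadata on this genotype_matrix; attach qc or skip apply_qc explicitly")
  }
  if (anyNA(m$qc$call_rate) || anyNA(m$qc$gentrain)) {
    stop("QC metadata incomplete: call_rate/gentrain required for every SNP")
  }
  ok_cr <- m$qc$call_rate > min_call_rate
  ok_gt <- m$qc$gentrain >= min_gentrain
  if (!quiet) {
    message(sum(!ok_cr), " SNP(s) fail call rate <= ", min_call_rate, "; ",
            sum(!ok_gt), " SNP(s) fail GenTrain < ", min_gentrain, "; ",
            sum(!(ok_cr & ok_gt)), " removed of ", nrow(m$map))
  }
  subset_snps(m, ok_cr & ok_gt)
}

#' Partition samples by disease status
#'
#' @param m a [genotype_matrix()] with at least one affected sample.
#' @return A list with elements `affected`, `carrier`, `normal`, each a
#'   [genotype_matrix()] over the same SNP axis (possibly with zero samples).
#' @export
split_by_status <- function(m) {
  st <- m$samples$status
  if (!any(st == "affected")) {
    stop("no affected samples: the consensus scan is undefined")
  }
  list(affected = subset_samples(m, st == "affected"),
       carrier = subset_samples(m, st == "carrier"),
       normal = subset_samples(m, st == "normal"))
}
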