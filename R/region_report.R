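## Candidate-region reporting: bp spans in Mb, distances between runs, and
## gene-content annotation from BED intervals. All coordinates are 1-based
## inclusive internally; BED input (0-based half-open) is converted on read.

## round half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  trunc(x * p + 0.5 + 1e-9) / p
}

#' Region span in megabases
#'
#' Span is `(end_bp - start_bp + 1) / 1e6`, rounded half-up to 2 decimals to
#' match conventional Mb formatting.
#'
#' @param start_bp,end_bp 1-based inclusive boundary positions, `end_bp >=
#'   start_bp`.
#' @return Span in Mb, 2 decimals.
#' @export
span_mb <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) stop("reversed coordinates: end_bp < start_bp")
  round_half_up((end_bp - start_bp + 1) / 1e6, 2L)
}

#' Separation between two disjoint runs on one chromosome
#'
#' @param earlier,later single rows of a `roh_runs` data.frame (or any objects
#'   with `start_bp`/`end_bp`/`chromosome`), `later` starting after `earlier`
#'   ends.
#' @return Gap in bp (start of later minus end of earlier); >= 0 for disjoint
#'   sorted runs.
#' @export
region_separation <- function(earlier, later) {
  if (earlier$chromosome != later$chromosome) {
    stop("runs are on different chromosomes")
  }
  later$start_bp - earlier$end_bp
}

#' Read gene intervals from a BED file
#'
#' Uses the standard BED convention (0-based half-open); intervals are
#' converted to 1-based inclusive coordinates on read.
#'
#' @param path BED file with at least chrom/start/end/name columns.
#' @return A `gene_set` data.frame: `chromosome`, `start_bp`, `end_bp`,
#'   `gene_name` (1-based inclusive). Names need not be unique.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  g <- data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
                  start_bp = GenomicRanges::start(gr),
                  end_bp = GenomicRanges::end(gr),
                  gene_name = if (!is.null(gr$name)) as.character(gr$name)
                  else paste0("interval_", seq_along(gr)),
                  stringsAsFactors = FALSE)
  message("read ", nrow(g), " BED interval(s); coordinates converted to 1-based inclusive")
  class(g) <- c("gene_set", "data.frame")
  g
}

#' Genes overlapping a region
#'
#' Overlap means at least one shared bp under closed-interval intersection; no
#' minimum-fraction rule is applied.
#'
#' @param chromosome chromosome name (same convention as the SNP map).
#' @param start_bp,end_bp 1-based inclusive region boundaries.
#' @param genes a `gene_set` from [read_gene_bed()] (or equivalent data.frame).
#' @return The overlapping gene rows, sorted by `start_bp`.
#' @export
genes_in_region <- function(chromosome, start_bp, end_bp, genes) {
  if (end_bp < start_bp) stop("reversed coordinates: end_bp < start_bp")
  q <- GenomicRanges::GRanges(chromosome, IRanges::IRanges(start_bp, end_bp))
  s <- GenomicRanges::GRanges(genes$chromosome,
                              IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  g <- genes[sort(S4Vectors::subjectHits(hits)), , drop = FALSE]
  g <- g[order(g$start_bp), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Annotate scan runs into region reports
#'
#' @param runs a `roh_runs` data.frame from [scan_roh()] / [find_runs()].
#' @param genes optional `gene_set`; when given, each region gets its
#'   overlapping genes and a gene count.
#' @return A `region_report` data.frame: run columns plus `span_mb`, `n_genes`
#'   and a `genes` list-column.
#' @export
region_report <- function(runs, genes = NULL) {
  rep <- as.data.frame(runs)
  rep$span_mb <- if (nrow(rep)) span_mb(rep$start_bp, rep$end_bp) else numeric()
  if (!is.null(genes)) {
    gl <- lapply(seq_len(nrow(rep)), function(i) {
      genes_in_region(rep$chromosome[i], rep$start_bp[i], rep$end_bp[i], genes)
    })
    rep$n_genes <- vapply(gl, nrow, integer(1))
    rep$genes <- gl
  }
  class(rep) <- c("region_report", "data.frame")
  rep
}

#' Write a region report as TSV
#'
#' @param rep a `region_report` (the `genes` list-column is flattened to a
#'   comma-separated name list).
#' @param path output path.
#' @export
write_region_report <- function(rep, path) {
  out <- as.data.frame(rep)
  if (!is.null(out$genes)) {
    out$genes <- vapply(out$genes, function(g) paste(g$gene_name, collapse = ","),
                        character(1))
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
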