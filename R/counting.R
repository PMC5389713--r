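#' Read a BED6 annotation whose name field encodes class and region id
#'
#' Annotation intervals carry a feature class (exon, intron or intergenic)
#' and a region identifier, encoded in the BED name field as `class:id`
#' (e.g. `exon:GENE1`). Coordinates in the file are BED-style 0-based
#' half-open; the returned `GRanges` uses the usual 1-based representation.
#'
#' @param file Path to a BED6 file.
#' @return A `GRanges` with metadata columns `feature_class` and `region_id`.
#' @export
read_annotation_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  nm <- gr$name
  if (any(is.na(nm)) || !all(grepl(":", nm, fixed = TRUE)))
    stop("annotation BED name field must be 'class:id'")
  parts <- strsplit(nm, ":", fixed = TRUE)
  gr$feature_class <- vapply(parts, `[`, character(1), 1L)
  gr$region_id <- vapply(parts, function(x) paste(x[-1], collapse = ":"),
                         character(1))
  gr
}

#' Read aligned-read intervals from BED6
#'
#' @param file Path to a BED6 file of read alignment spans (0-based
#'   half-open; strand in column 6).
#' @return A `GRanges` of reads.
#' @export
read_reads_bed <- function(file) {
  rtracklayer::import(file, format = "BED")
}

# Build a GRanges from a 0-based half-open data.frame
# (chrom, start, end, strand, + extra columns). Handy for tests and callers
# holding BED-like tables in memory.
#' Convert a BED-like 0-based half-open table to GRanges
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, and optionally `feature_class` / `region_id` /
#'   `name`.
#' @return A `GRanges` carrying any extra columns as metadata.
#' @export
granges_from_bed_df <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(df$strand)) "*" else df$strand
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- df[[col]]
  gr
}

# First collision among annotation intervals, or NULL.
.first_annotation_collision <- function(annotation) {
  hits <- GenomicRanges::findOverlaps(annotation, annotation,
                                      ignore.strand = TRUE)
  hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
  if (!length(hits)) return(NULL)
  c(S4Vectors::queryHits(hits)[1], S4Vectors::subjectHits(hits)[1])
}

#' Assign reads to annotation features by their 5' position
#'
#' Each read is reduced to the position of its first transcribed base — the
#' alignment start on the plus strand, the last aligned base on the minus
#' strand — and assigned to the single annotation interval covering that
#' position. The annotation must be non-overlapping, so every read
#' contributes exactly once; reads whose 5' position is covered by no
#' interval are counted as unassigned. Assignment ignores annotation strand
#' (counting is unstranded); the read strand is used only to locate the 5'
#' end, and unstranded reads are treated as plus-strand.
#'
#' @param reads `GRanges` of read alignment spans (strand-aware).
#' @param annotation `GRanges` with metadata columns `feature_class` and
#'   `region_id`; intervals must not overlap one another.
#' @return A list: `feature_counts` (data frame `region_id`,
#'   `feature_class`, `count`, one row per annotation interval),
#'   `class_totals` (named vector over classes), `unassigned`, `total`.
#'   `sum(class_totals) + unassigned == total` always.
#' @examples
#' ann <- granges_from_bed_df(data.frame(
#'   chrom = "chr1", start = c(100, 200), end = c(200, 300), strand = "+",
#'   feature_class = c("exon", "intron"), region_id = c("g1", "g1")))
#' rd <- granges_from_bed_df(data.frame(
#'   chrom = "chr1", start = 150, end = 250, strand = "+"))
#' assign_reads_5prime(rd, ann)$class_totals
#' @export
assign_reads_5prime <- function(reads, annotation) {
  if (!methods::is(annotation, "GRanges") || !methods::is(reads, "GRanges"))
    stop("'reads' and 'annotation' must be GRanges")
  mc <- S4Vectors::mcols(annotation)
  if (!all(c("feature_class", "region_id") %in% names(mc)))
    stop("annotation needs 'feature_class' and 'region_id' metadata columns")
  coll <- .first_annotation_collision(annotation)
  if (!is.null(coll))
    stop("overlapping annotation intervals: ",
         mc$region_id[coll[1]], " (", mc$feature_class[coll[1]], ") and ",
         mc$region_id[coll[2]], " (", mc$feature_class[coll[2]], ")")

  # 5' base: resize to width 1 anchored at the transcription start; GRanges
  # honours strand, so minus-strand reads anchor at their rightmost base.
  fivep <- GenomicRanges::resize(reads, width = 1L, fix = "start")
  hits <- GenomicRanges::findOverlaps(fivep, annotation, ignore.strand = TRUE)
  counts <- S4Vectors::countSubjectHits(hits)
  assigned <- S4Vectors::countQueryHits(hits) > 0

  feature_counts <- data.frame(
    region_id = mc$region_id,
    feature_class = mc$feature_class,
    count = counts,
    stringsAsFactors = FALSE
  )
  class_totals <- vapply(split(counts, mc$feature_class), sum, numeric(1))
  list(
    feature_counts = feature_counts,
    class_totals = class_totals,
    unassigned = sum(!assigned),
    total = length(reads)
  )
}

#' Conservative gene-level intron counts
#'
#' A read that overlaps both an intron and an exon is credited to the exon;
#' the conservative intron count is therefore the difference between the
#' full gene-body count and the gene-level exon count.
#'
#' @param gene_body_counts,exon_counts Named per-gene count vectors over the
#'   same gene universe; exon counts may not exceed body counts.
#' @return Named per-gene intron counts.
#' @export
conservative_intron_counts <- function(gene_body_counts, exon_counts) {
  if (is.null(names(gene_body_counts)) || is.null(names(exon_counts)))
    stop("count vectors must be named by gene id")
  if (!setequal(names(gene_body_counts), names(exon_counts)))
    stop("gene universes differ")
  exon_counts <- exon_counts[names(gene_body_counts)]
  bad <- which(exon_counts > gene_body_counts)
  if (length(bad))
    stop("exon count exceeds gene-body count for gene ",
         names(gene_body_counts)[bad[1]], "; inputs are inconsistent")
  gene_body_counts - exon_counts
}

#' Conservative intergenic counts
#'
#' Each intergenic region is amalgamated with the gene body it precedes
#' along the genomic coordinates; reads overlapping both are credited to the
#' gene, so the conservative intergenic count is the amalgamated count minus
#' the gene-body count of the mapped gene.
#'
#' @param amalgamated_counts Named per-region counts of the combined
#'   gene-plus-preceding-intergenic regions.
#' @param gene_body_counts Named per-gene counts.
#' @param region_to_gene Named character vector mapping each region id to
#'   exactly one gene id.
#' @return Named per-region intergenic counts.
#' @export
conservative_intergenic_counts <- function(amalgamated_counts,
                                           gene_body_counts,
                                           region_to_gene) {
  regions <- names(amalgamated_counts)
  if (is.null(regions)) stop("'amalgamated_counts' must be named by region")
  unmapped <- setdiff(regions, names(region_to_gene))
  if (length(unmapped))
    stop("region(s) with no gene mapping: ", paste(unmapped, collapse = ", "))
  genes <- region_to_gene[regions]
  missing <- setdiff(genes, names(gene_body_counts))
  if (length(missing))
    stop("mapped gene(s) with no body count: ", paste(missing, collapse = ", "))
  out <- amalgamated_counts - gene_body_counts[genes]
  names(out) <- regions
  neg <- which(out < 0)
  if (length(neg))
    stop("negative intergenic count for region ", regions[neg[1]],
         "; inputs are inconsistent")
  out
}

#' Write per-feature counts as TSV
#'
#' @param assignment Result of [assign_reads_5prime()].
#' @param path File path.
#' @export
write_feature_counts_tsv <- function(assignment, path) {
  utils::write.table(assignment$feature_counts, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(assignment)
}
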