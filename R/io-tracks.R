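#' Write intervals to BED
#'
#' Internal intervals are 0-based half-open, which is exactly the BED
#' convention; `rtracklayer` handles the 1-based GRanges conversion.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `name`,
#'   and optionally `strand`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  gr <- intervals_to_gr(intervals)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file into a 0-based half-open interval data.frame
#'
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr)),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Sort and merge overlapping intervals
#'
#' @param intervals data.frame as in [write_intervals()].
#' @return merged, sorted intervals (strand ignored for merging).
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(intervals_to_gr(intervals, stranded = FALSE))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

intervals_to_gr <- function(intervals, stranded = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(intervals$start < intervals$end))
  strand <- if (stranded && "strand" %in% names(intervals))
    ifelse(intervals$strand %in% c("+", "-"), intervals$strand, "*")
  else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = strand)
  if ("name" %in% names(intervals)) gr$name <- intervals$name
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write variant records as a minimal VCF
#'
#' A minimal v4.2-style VCF (no genotype columns; one sample-pair comparison
#' per file).  Internal 0-based positions become 1-based; InDels are written
#' left-anchored on the preceding reference base.
#'
#' @param records variant records from [call_variants()].
#' @param reference reference genome ([org_genome()] or string) the records
#'   were called on, used for the InDel anchor base.
#' @param path output file.
#' @param chrom CHROM field value.
#' @return `path`, invisibly.
#' @export
write_variants <- function(records, reference, path, chrom = NULL) {
  refseq <- genome_seq(reference)
  if (is.null(chrom))
    chrom <- if (inherits(reference, "org_genome")) reference$id else "ref"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant class: SNV, MNV or InDel\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Counted depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(records) > 0) {
    for (i in seq_len(nrow(records))) {
      pos0 <- records$position[i]
      ref <- records$ref_allele[i]
      alt <- records$alt_allele[i]
      if (records$class[i] == "InDel") {
        anchor_pos <- max(pos0 - 1L, 0L)
        anchor <- substr(refseq, anchor_pos + 1L, anchor_pos + 1L)
        ref <- paste0(anchor, ref)
        alt <- paste0(anchor, alt)
        pos1 <- anchor_pos + 1L
      } else {
        pos1 <- pos0 + 1L
      }
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.0f\tPASS\tTYPE=%s;DP=%d;AF=%.4f",
                         chrom, pos1, ref, alt, records$mean_quality[i],
                         records$class[i], records$depth[i], records$frequency[i]),
                 con)
    }
  }
  invisible(path)
}

#' Read/write phylogenetic trees in newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; branch
#' lengths and internal node (support) labels are preserved.
#'
#' @param path newick file.
#' @return `read_tree`: an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  tr
}

#' @rdname read_tree
#' @param tree `phylo` object.
#' @return `write_tree`: `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a YAML configuration file with per-stage parameter blocks
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Timestamped stage logging
#'
#' @param fmt [sprintf()] format string.
#' @param ... values for `fmt`.
#' @return the message, invisibly.
#' @export
org_log <- function(fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  invisible(msg)
}
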