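#' Read sequence records from FASTA or FASTQ
#'
#' Sequences are upper-cased and validated against the \{A,C,G,T,N,-\}
#' alphabet.  Circularity is carried in the FASTA description as the token
#' `circular=true` (no standard exists for this flag, so it is documented
#' here and written back by [write_seqs()]).
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @return data.frame with columns `id`, `desc`, `seq`, `qual` (`NA` for
#'   FASTA) and `circular`.
#' @export
read_seqs <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = format,
                                 with.qualities = (format == "fastq")),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("record with characters outside the nucleotide alphabet in ", path)
      invokeRestart("muffleWarning")
    })
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seqs <- toupper(as.character(x))
  names(seqs) <- NULL
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("record(s) with characters outside {A,C,G,T,N,-}: ",
                     paste(head(id[bad], 3), collapse = ", "))
  qual <- if (format == "fastq") {
    q <- as.character(S4Vectors::mcols(x)$qualities)
    names(q) <- NULL
    q
  } else NA_character_
  circ <- grepl("\\bcircular=true\\b", desc)
  desc <- trimws(sub("\\s*\\bcircular=true\\b\\s*", " ", desc))
  data.frame(id = id, desc = desc, seq = seqs, qual = qual, circular = circ)
}

#' Write sequence records to FASTA or FASTQ
#'
#' FASTA output is wrapped at 70 columns; FASTQ is Sanger/Phred+33.  A
#' `circular=true` token is appended to the description of circular records.
#'
#' @param records data.frame as returned by [read_seqs()], or an
#'   [org_genome()] (written as one FASTA record).
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (inherits(records, "org_genome")) {
    records <- data.frame(id = records$id, desc = "", seq = records$seq,
                          qual = NA_character_, circular = records$circular)
  }
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else ""
  circ <- if ("circular" %in% names(records)) records$circular else FALSE
  desc <- ifelse(circ, trimws(paste(desc, "circular=true")), desc)
  hdr <- trimws(paste(records$id, desc))
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- hdr
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
  } else {
    if (!"qual" %in% names(records) || anyNA(records$qual))
      stop("FASTQ output requires a quality string for every record")
    if (any(nchar(records$qual) != nchar(records$seq)))
      stop("quality string length differs from sequence length")
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(records$qual))
  }
  invisible(path)
}

#' Read an aligned multi-FASTA into a character matrix
#'
#' @param path aligned FASTA; all rows must have equal length.
#' @return character matrix (rows = genomes, columns = alignment positions,
#'   gap character `-`), rownames = record ids.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty alignment file")
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1) stop("ragged alignment: row lengths differ")
  as_alignment(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write an alignment matrix as aligned FASTA
#'
#' @param aln character matrix with rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  recs <- data.frame(id = rownames(aln),
                     seq = apply(aln, 1, paste, collapse = ""))
  write_seqs(recs, path, "fasta")
}

# rows: named character vector of equal-length (gapped) sequences
as_alignment <- function(rows, ids = names(rows)) {
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(m) <- ids
  m
}
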