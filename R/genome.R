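#' Annotated genome container
#'
#' A light container for a (usually circular) genome sequence together with
#' named region intervals and simulator truth metadata.  Intervals are
#' 0-based half-open on the genome's own coordinates; an interval whose end
#' exceeds the sequence length wraps past the origin of a circular genome.
#'
#' @param seq nucleotide string (upper-cased on construction).
#' @param id genome identifier.
#' @param circular logical, is the molecule a circle.
#' @param regions data.frame with columns `name`, `start`, `end`, `strand`
#'   (0-based half-open), or `NULL`.
#' @param truth free-form list of ground-truth metadata from a simulator.
#' @return an object of class `org_genome`.
#' @export
org_genome <- function(seq, id = "genome", circular = TRUE,
                       regions = NULL, truth = list()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN-]", seq)) stop("sequence contains characters outside {A,C,G,T,N,-}")
  if (is.null(regions)) {
    regions <- data.frame(name = character(), start = integer(),
                          end = integer(), strand = character())
  }
  structure(list(seq = seq, id = id, circular = circular,
                 regions = regions, truth = truth),
            class = "org_genome")
}

#' @export
print.org_genome <- function(x, ...) {
  cat(sprintf("<org_genome> %s: %s bp, %s\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  if (nrow(x$regions) > 0) {
    cat("regions:\n")
    print(x$regions, row.names = FALSE)
  }
  invisible(x)
}

#' @export
length.org_genome <- function(x) nchar(x$seq)

genome_seq <- function(g) if (inherits(g, "org_genome")) g$seq else toupper(g)

# named region interval as c(start, end), or NULL
region_of <- function(g, name) {
  i <- match(name, g$regions$name)
  if (is.na(i)) return(NULL)
  c(g$regions$start[i], g$regions$end[i])
}

# sequence of a named region (wrapping on circles)
region_seq <- function(g, name) {
  iv <- region_of(g, name)
  if (is.null(iv)) stop("no region named '", name, "'")
  subseq_circ(g$seq, iv[1], iv[2], g$circular)
}
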