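#' Gene model for splice-site and codon-level guide design
#'
#' A \code{GeneModel} holds a genomic locus sequence together with its exon
#' structure and (optionally) CDS. Models are always stored coding-strand-
#' wise: a minus-strand gene is reverse-complemented and its intervals
#' mirrored at construction, so downstream code (splice-site detection,
#' codon enumeration) always reads left to right in the direction of
#' transcription. The original strand is kept as metadata.
#'
#' Coordinates are 1-based inclusive \linkS4class{IRanges}, the Bioconductor
#' convention, matching GFF3 on input.
#'
#' @slot id gene/transcript identifier.
#' @slot sequence locus DNA (\code{DNAString}), coding strand.
#' @slot source_strand \code{"+"} or \code{"-"}: strand of the gene on the
#'   sequence originally supplied.
#' @slot exons exon intervals (IRanges, sorted, non-overlapping).
#' @slot cds CDS intervals (IRanges; length 0 when absent).
#' @exportClass GeneModel
setClass("GeneModel",
  representation(id = "character", sequence = "DNAString",
                 source_strand = "character", exons = "IRanges",
                 cds = "IRanges"))

setValidity("GeneModel", function(object) {
  msg <- character()
  L <- length(object@sequence)
  alph <- Biostrings::uniqueLetters(object@sequence)
  if (!all(alph %in% c(BASES, "N")))
    msg <- c(msg, "sequence alphabet must be {A,C,G,T,N}")
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "at least one exon required")
  if (length(ex) && (min(IRanges::start(ex)) < 1L || max(IRanges::end(ex)) > L))
    msg <- c(msg, "exons outside sequence")
  if (length(ex) > 1L) {
    if (is.unsorted(IRanges::start(ex)))
      msg <- c(msg, "exons must be sorted")
    if (any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (length(object@cds)) {
    uncovered <- IRanges::setdiff(object@cds, ex)
    if (length(uncovered) > 0L)
      msg <- c(msg, "cds must be contained in exons")
  }
  if (!object@source_strand %in% c("+", "-"))
    msg <- c(msg, "source_strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' @param id,sequence,exons,cds see slots; \code{sequence} may be a string.
#'   \code{exons}/\code{cds} are IRanges (or 2-column start/end matrices) in
#'   the coordinates of the supplied sequence.
#' @param strand strand of the gene on the supplied sequence; \code{"-"}
#'   input is flipped to the coding strand.
#' @rdname GeneModel-class
#' @export
GeneModel <- function(id, sequence, exons, cds = NULL, strand = "+") {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  as_ir <- function(x) {
    if (is.null(x)) return(IRanges::IRanges())
    if (is.matrix(x)) x <- IRanges::IRanges(start = x[, 1], end = x[, 2])
    x
  }
  exons <- as_ir(exons); cds <- as_ir(cds)
  if (strand == "-") {
    L <- length(sequence)
    flip <- function(ir) {
      if (length(ir) == 0L) return(ir)
      out <- IRanges::IRanges(start = L - IRanges::end(ir) + 1L,
                              end = L - IRanges::start(ir) + 1L)
      out[order(IRanges::start(out))]
    }
    sequence <- Biostrings::reverseComplement(sequence)
    exons <- flip(exons); cds <- flip(cds)
  } else {
    exons <- exons[order(IRanges::start(exons))]
    if (length(cds)) cds <- cds[order(IRanges::start(cds))]
  }
  new("GeneModel", id = id, sequence = sequence, source_strand = strand,
      exons = exons, cds = cds)
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s: %d bp locus (%s strand source), %d exon(s)%s\n",
              object@id, length(object@sequence), object@source_strand,
              length(object@exons),
              if (length(object@cds)) sprintf(", CDS over %d interval(s)",
                                              length(object@cds)) else ""))
})

#' Accessors for GeneModel
#' @param x a \linkS4class{GeneModel}.
#' @return \code{geneSequence}: the coding-strand \code{DNAString};
#'   \code{geneExons}, \code{geneCds}: IRanges; \code{geneId}: character.
#' @export
geneSequence <- function(x) x@sequence

#' @rdname geneSequence
#' @export
geneExons <- function(x) x@exons

#' @rdname geneSequence
#' @export
geneCds <- function(x) x@cds

#' @rdname geneSequence
#' @export
geneId <- function(x) x@id

## locus coordinates of CDS bases, 5'->3', as an integer vector
cdsPositions <- function(gene) {
  if (length(gene@cds) == 0L) stop("gene ", gene@id, " has no CDS")
  unlist(lapply(seq_along(gene@cds), function(i)
    IRanges::start(gene@cds)[i]:IRanges::end(gene@cds)[i]))
}

#' Find splice sites of a gene model
#'
#' Reports the intronic dinucleotides that define each splice site on the
#' transcribed strand: the splice donor (SD) is the first two intron bases
#' (canonically GT) after each non-terminal exon, the splice acceptor (SA)
#' the last two intron bases (canonically AG) before each non-initial exon.
#' Disrupting either dinucleotide abolishes recognition of the adjacent
#' exon and causes exon skipping.
#'
#' @param gene a \linkS4class{GeneModel} with at least 2 exons (a
#'   single-exon gene yields an empty table).
#' @param include_noncanonical keep sites whose dinucleotide is not GT/AG
#'   (flagged \code{canonical = FALSE})? Default drops them.
#' @return data.frame with columns \code{kind} ("donor"/"acceptor"),
#'   \code{exon_index} (flanking exon), \code{pos1}, \code{pos2} (locus
#'   coordinates of the dinucleotide), \code{dinucleotide},
#'   \code{canonical}.
#' @export
findSpliceSites <- function(gene, include_noncanonical = FALSE) {
  stopifnot(is(gene, "GeneModel"))
  ex <- gene@exons
  n <- length(ex)
  if (n < 2L)
    return(data.frame(kind = character(), exon_index = integer(),
                      pos1 = integer(), pos2 = integer(),
                      dinucleotide = character(), canonical = logical()))
  seqc <- as.character(gene@sequence)
  rows <- list()
  for (i in seq_len(n - 1L)) {  # donor after exon i
    p <- IRanges::end(ex)[i] + 1L
    d <- substr(seqc, p, p + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "donor", exon_index = i, pos1 = p, pos2 = p + 1L,
      dinucleotide = d, canonical = identical(d, "GT"))
  }
  for (i in 2:n) {              # acceptor before exon i
    p <- IRanges::start(ex)[i] - 2L
    d <- substr(seqc, p, p + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "acceptor", exon_index = i, pos1 = p, pos2 = p + 1L,
      dinucleotide = d, canonical = identical(d, "AG"))
  }
  out <- do.call(rbind, rows)
  if (!include_noncanonical) out <- out[out$canonical, , drop = FALSE]
  rownames(out) <- NULL
  out
}
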