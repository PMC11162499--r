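#' Read / write FASTA
#'
#' Thin wrappers over \code{Biostrings} that preserve record order and
#' names and reject duplicate identifiers.
#'
#' @param path file path.
#' @param seqs a named \code{DNAStringSet} (or named character vector).
#' @param width line-wrap width for output (default 70).
#' @return \code{readFasta}: a \code{DNAStringSet} (empty, with a warning,
#'   for an empty file). \code{writeFasta}: \code{path}, invisibly.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0L) warning("FASTA file ", path, " contains no records")
  ## Biostrings keeps full header lines; use the first token as id
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- names(x)[duplicated(names(x))]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  x
}

#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = width)
  invisible(path)
}

#' Read / write FASTQ
#'
#' FASTQ wrappers over \code{Biostrings}; written records carry a constant
#' quality (the simulator does not model base qualities and the quantifier
#' ignores them).
#'
#' @param path file path.
#' @param reads a \code{DNAStringSet} (or character vector).
#' @param quality_char constant PHRED character for output (default "I").
#' @return \code{readFastq}: a \code{DNAStringSet}. \code{writeFastq}:
#'   \code{path}, invisibly.
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path, quality_char = "I") {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  quals <- Biostrings::BStringSet(vapply(
    Biostrings::width(reads),
    function(w) paste(rep(quality_char, w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read gene models from GFF3 + FASTA
#'
#' Parses gene/mRNA/exon/CDS features (one transcript per gene) into
#' \linkS4class{GeneModel} objects, looking up each gene's locus sequence
#' by seqid in the FASTA. GFF3 coordinates are 1-based inclusive, matching
#' the package's internal convention; minus-strand genes are flipped to
#' the coding strand at construction. Exon/CDS containment is validated by
#' the GeneModel validity method.
#'
#' @param gff_path GFF3 file with exon and (optionally) CDS features whose
#'   Parent/ID attributes group them by transcript or gene.
#' @param fasta a \code{DNAStringSet} (e.g. from \code{\link{readFasta}})
#'   or FASTA path.
#' @return named list of \linkS4class{GeneModel}.
#' @export
readGff3Genes <- function(gff_path, fasta) {
  if (is.character(fasta)) fasta <- readFasta(fasta)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr)
  feat <- df[tolower(df$type) %in% c("exon", "cds"), , drop = FALSE]
  if (nrow(feat) == 0L) stop("no exon/CDS features in ", gff_path)
  parent <- vapply(seq_len(nrow(feat)), function(i) {
    p <- feat$Parent[[i]]
    if (length(p) == 0L) as.character(feat$ID[i]) else as.character(p[1])
  }, character(1))
  ## collapse mRNA-level parents to their gene seqid grouping
  out <- list()
  for (grp in unique(parent)) {
    rows <- feat[parent == grp, , drop = FALSE]
    seqid <- as.character(rows$seqnames[1])
    if (!seqid %in% names(fasta))
      stop("seqid ", seqid, " not found in FASTA")
    L <- length(fasta[[seqid]])
    if (max(rows$end) > L)
      stop("feature beyond sequence length for ", seqid)
    strand <- as.character(rows$strand[1])
    if (!strand %in% c("+", "-")) strand <- "+"
    ex <- rows[tolower(rows$type) == "exon", , drop = FALSE]
    cd <- rows[tolower(rows$type) == "cds", , drop = FALSE]
    out[[grp]] <- GeneModel(
      id = grp, sequence = fasta[[seqid]],
      exons = IRanges::IRanges(start = ex$start, end = ex$end),
      cds = if (nrow(cd)) IRanges::IRanges(start = cd$start, end = cd$end)
            else NULL,
      strand = strand)
  }
  out
}

#' Write a gene model as GFF3
#'
#' Writes gene/exon/CDS rows (1-based inclusive, plus strand: models are
#' stored coding-strand-wise) for round-tripping simulated gene models.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param path output file.
#' @param seqid sequence identifier (default the gene id).
#' @return \code{path}, invisibly.
#' @export
writeGff3Gene <- function(gene, path, seqid = geneId(gene)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  L <- length(gene@sequence)
  lines <- sprintf("%s\tgbekit\tgene\t1\t%d\t.\t+\t.\tID=%s", seqid, L,
                   gene@id)
  ex <- gene@exons
  lines <- c(lines, sprintf("%s\tgbekit\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                            seqid, IRanges::start(ex), IRanges::end(ex),
                            gene@id))
  if (length(gene@cds))
    lines <- c(lines, sprintf("%s\tgbekit\tCDS\t%d\t%d\t.\t+\t0\tParent=%s",
                              seqid, IRanges::start(gene@cds),
                              IRanges::end(gene@cds), gene@id))
  writeLines(lines, con)
  invisible(path)
}

#' Write a guide-candidate table as TSV
#'
#' Tab-separated candidate table (header row, "." for missing values),
#' mirroring the supplementary-table idiom of guide-design reports.
#'
#' @param candidates GuideCandidate data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCandidateTsv <- function(candidates, path) {
  out <- candidates
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidateTsv
#' @param path TSV written by \code{writeCandidateTsv}.
#' @return \code{readCandidateTsv}: the candidate data.frame with "."
#'   restored to NA and column types matching the designer output.
#' @export
readCandidateTsv <- function(path) {
  out <- read.delim(path, na.strings = ".", colClasses = "character")
  for (col in c("start", "end", "targeted_base_position",
                "targeted_locus_pos", "codon_index"))
    out[[col]] <- as.integer(out[[col]])
  out
}
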