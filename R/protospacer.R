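#' Enumerate protospacer+PAM frames on both strands
#'
#' Slides a 23-nt frame (20-nt protospacer, 3-nt PAM at positions 21--23)
#' over both strands of a sequence and keeps frames whose PAM positions
#' match the IUPAC pattern. Frames containing N are excluded.
#'
#' For a plus-strand frame, \code{start..end} cover the 23-mer left to
#' right with the PAM at \code{end-2..end}. For a minus-strand frame the
#' 23-mer is the reverse complement of \code{start..end}, so the PAM maps
#' to locus positions \code{start..start+2} and protospacer position p maps
#' to locus coordinate \code{end - p + 1}.
#'
#' @param sequence DNA string or \code{DNAString} (length >= 23).
#' @param pam 3-letter IUPAC pattern (default \code{"NGG"}).
#' @return data.frame with columns \code{protospacer}, \code{pam} (both in
#'   protospacer-strand sense), \code{start}, \code{end} (1-based inclusive
#'   locus coordinates of the 23-nt frame), \code{strand}; ordered by locus
#'   coordinate then strand (+ before -).
#' @examples
#' scanProtospacers(paste(c(rep("A", 20), "AGG"), collapse = ""))
#' @export
scanProtospacers <- function(sequence, pam = "NGG") {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  if (nchar(pam) != 3L) stop("pam must be a 3-character IUPAC pattern")
  .check_iupac(pam)
  L <- nchar(sequence)
  empty <- data.frame(protospacer = character(), pam = character(),
                      start = integer(), end = integer(),
                      strand = character())
  if (L < 23L) return(empty)

  subj <- Biostrings::DNAString(sequence)
  hits_for <- function(strand) {
    ## PAM matches on the protospacer strand; for '-' search the revcomp
    ## pattern on the plus strand so coordinates stay in locus space
    pampat <- if (strand == "+") pam else revcompChar(pam)
    m <- Biostrings::matchPattern(pampat, subj, fixed = FALSE)
    pamstart <- IRanges::start(m)
    if (strand == "+") {
      keep <- pamstart >= 21L
      fs <- pamstart[keep] - 20L
    } else {
      keep <- pamstart + 22L <= L
      fs <- pamstart[keep]
    }
    if (length(fs) == 0L) return(empty)
    frames <- substring(sequence, fs, fs + 22L)
    ok <- !grepl("N", frames, fixed = TRUE)
    fs <- fs[ok]; frames <- frames[ok]
    if (length(fs) == 0L) return(empty)
    if (strand == "-") frames <- revcompChar(frames)
    data.frame(protospacer = substr(frames, 1L, 20L),
               pam = substr(frames, 21L, 23L),
               start = fs, end = fs + 22L,
               strand = strand)
  }
  out <- rbind(hits_for("+"), hits_for("-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## locus coordinate of protospacer position p for a frame row
protoPosToLocus <- function(start, end, strand, p) {
  ifelse(strand == "+", start + p - 1L, end - p + 1L)
}

## protospacer position (1..23) of a locus coordinate within a frame
locusToProtoPos <- function(start, end, strand, pos) {
  ifelse(strand == "+", pos - start + 1L, end - pos + 1L)
}

#' Naive guide-dependent off-target scan
#'
#' Scans a genome sequence for PAM-valid frames whose 20-nt protospacer is
#' within a Hamming-distance budget of a query protospacer (mismatches
#' only, no bulges; the PAM is not counted in the distance). This mirrors
#' the common in-silico off-target prediction setting of at most 3
#' mismatches and no gapped matches.
#'
#' @param genome_seq DNA string or \code{DNAString}.
#' @param protospacer 20-nt query (protospacer-strand sense).
#' @param pam IUPAC PAM pattern (default \code{"NGG"}).
#' @param max_mismatches maximum Hamming distance (default 3).
#' @return data.frame with \code{start}, \code{end} (23-nt frame, locus
#'   coordinates), \code{strand}, \code{protospacer} (site sequence,
#'   protospacer-strand sense), \code{mismatches}.
#' @export
findOffTargets <- function(genome_seq, protospacer, pam = "NGG",
                           max_mismatches = 3L) {
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt")
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  frames <- scanProtospacers(genome_seq, pam)
  if (nrow(frames) == 0L) {
    frames$mismatches <- integer()
    return(frames[c("start", "end", "strand", "protospacer", "mismatches")])
  }
  q <- strsplit(toupper(protospacer), "")[[1]]
  mm <- vapply(strsplit(frames$protospacer, ""),
               function(s) sum(s != q), integer(1))
  out <- frames[mm <= max_mismatches,
                c("start", "end", "strand", "protospacer"), drop = FALSE]
  out$mismatches <- mm[mm <= max_mismatches]
  rownames(out) <- NULL
  out
}
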