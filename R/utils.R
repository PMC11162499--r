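#' @import methods
#' @importFrom stats median quantile sd setNames runif
#' @importFrom utils write.table read.delim packageVersion combn
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom IRanges IRanges
#' @importFrom S4Vectors isConstant
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.check_iupac <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0L)
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(bad, collapse = ", "))
  invisible(chars)
}

## TRUE where `seq` (plain ACGT string, same length) matches the IUPAC pattern
iupacMatches <- function(seq, pattern) {
  pc <- .check_iupac(pattern)
  sc <- strsplit(seq, "")[[1]]
  if (length(sc) != length(pc)) return(FALSE)
  all(mapply(function(s, p) s %in% IUPAC_SETS[[p]], sc, pc))
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complementChar <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("not a valid codon: ", codon)
  aa
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## evaluate `expr` under a temporary RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## fan a top-level seed out into per-stage seeds, deterministically and
## within 32-bit integer range
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}
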