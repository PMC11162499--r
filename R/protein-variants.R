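#' UNG1 / UNG2 residue-numbering equivalence
#'
#' Human uracil DNA glycosylase has two isoforms differing only in their
#' N-termini: mitochondrial UNG1 (304 aa) and nuclear UNG2 (313 aa). Within
#' the shared catalytic domain, UNG2 numbering equals UNG1 numbering plus a
#' constant offset of 9 (e.g. UNG1 Y147 is UNG2 Y156, UNG1 N204 is UNG2
#' N213). \code{mapUng1ToUng2} adds the offset; \code{mapUng2ToUng1}
#' subtracts it.
#'
#' @param position 1-based residue index (vectorized).
#' @return integer vector of mapped residue indices.
#' @examples
#' mapUng1ToUng2(147)  # 156
#' mapUng2ToUng1(213)  # 204
#' @export
mapUng1ToUng2 <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L))
    stop("position must be a positive residue index")
  position + 9L
}

#' @rdname mapUng1ToUng2
#' @export
mapUng2ToUng1 <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L))
    stop("position must be a positive residue index")
  out <- position - 9L
  if (any(out < 1L))
    stop("UNG2 positions 1..9 have no UNG1 equivalent")
  out
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.scheme_target <- c("alanine" = "A", "arginine" = "R",
                    "aspartate" = "D", "valine" = "V")

#' Plan a scanning- or site-saturation mutagenesis library
#'
#' Plans the substitution libraries used for glycosylase engineering:
#' residue-by-residue replacement over a region with a single amino acid
#' (X>A, X>R, X>D or X>V), or site saturation (all 19 non-native residues)
#' at one position. Under the alanine scan, native alanines are mutated to
#' valine (A>V) so every residue in the region is covered; under the other
#' scanning schemes a native residue equal to the scheme target is skipped
#' (no no-op variants are ever proposed). The region is also partitioned
#' into left-aligned 8-residue segments (the last may be shorter), the unit
#' in which library oligos are assembled.
#'
#' @param protein_seq amino-acid sequence (single string, one-letter codes).
#' @param region_start,region_end 1-based inclusive residue range. For
#'   \code{scheme = "saturation"} the region must be a single residue.
#' @param scheme one of \code{"alanine"}, \code{"arginine"},
#'   \code{"aspartate"}, \code{"valine"}, \code{"saturation"}.
#' @param isoform label recorded with each variant (default \code{"UNG2"}).
#' @param segment_width segment size for the partition (default 8).
#' @return a list of class \code{MutagenesisPlan} with elements
#'   \code{variants} (data.frame: position, from, to, isoform,
#'   segment_index), \code{segments} (data.frame: index, start, end),
#'   \code{scheme}, \code{region}.
#' @examples
#' seq214 <- paste(rep("G", 220), collapse = "")
#' plan <- planScanningMutagenesis(seq214, 214, 214, "saturation")
#' nrow(plan$variants)  # 19
#' @export
planScanningMutagenesis <- function(protein_seq, region_start, region_end,
                                    scheme = c("alanine", "arginine",
                                               "aspartate", "valine",
                                               "saturation"),
                                    isoform = "UNG2", segment_width = 8L) {
  scheme <- match.arg(scheme)
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  n <- nchar(protein_seq)
  if (region_start < 1L || region_end > n || region_start > region_end)
    stop("region ", region_start, "-", region_end,
         " outside sequence of length ", n)
  aas <- strsplit(toupper(protein_seq), "")[[1]]
  if (!all(aas %in% c(AA1, "*")))
    stop("protein_seq contains invalid amino-acid letters")

  segments <- data.frame(
    index = seq_len(ceiling((region_end - region_start + 1L) / segment_width)))
  segments$start <- region_start + (segments$index - 1L) * segment_width
  segments$end <- pmin(segments$start + segment_width - 1L, region_end)
  seg_of <- function(pos) findInterval(pos, segments$start)

  if (scheme == "saturation") {
    if (region_start != region_end)
      stop("saturation scheme requires a single-residue region")
    native <- aas[region_start]
    to <- setdiff(AA1, native)
    variants <- data.frame(position = region_start, from = native, to = to,
                           isoform = isoform,
                           segment_index = seg_of(region_start))
  } else {
    target <- .scheme_target[[scheme]]
    pos <- region_start:region_end
    from <- aas[pos]
    to <- rep(target, length(pos))
    if (scheme == "alanine") {
      to[from == "A"] <- "V"  # A>V fallback: cover native alanines
      keep <- rep(TRUE, length(pos))
    } else {
      keep <- from != target  # no fallback published; skip no-ops
    }
    variants <- data.frame(position = pos[keep], from = from[keep],
                           to = to[keep], isoform = isoform,
                           segment_index = seg_of(pos[keep]))
  }
  stopifnot(all(variants$from != variants$to))
  structure(list(variants = variants, segments = segments, scheme = scheme,
                 region = c(region_start, region_end)),
            class = "MutagenesisPlan")
}

#' @export
print.MutagenesisPlan <- function(x, ...) {
  cat(sprintf("MutagenesisPlan: scheme %s over residues %d-%d (%d variants, %d segments)\n",
              x$scheme, x$region[1], x$region[2], nrow(x$variants),
              nrow(x$segments)))
  invisible(x)
}

#' Export a mutagenesis plan as TSV
#'
#' Writes the variant table (position, from, to, isoform, segment_index)
#' as a tab-separated file with a header row.
#'
#' @param plan a \code{MutagenesisPlan}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMutagenesisPlan <- function(plan, path) {
  stopifnot(inherits(plan, "MutagenesisPlan"))
  write.table(plan$variants, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
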