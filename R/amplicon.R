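#' Alignment and quantification parameters
#'
#' Global affine-gap alignment scores used to align amplicon reads to the
#' reference, plus the flank (bp) added around the protospacer to form the
#' indel quantification window. Defaults make single-event reads
#' unambiguous: match +2, mismatch -2, gap open -10, gap extend -1,
#' flank 3 bp.
#'
#' @slot match_score,mismatch_penalty,gap_open,gap_extend numeric scores
#'   (penalties negative).
#' @slot quantification_flank non-negative integer.
#' @exportClass AlignmentParams
setClass("AlignmentParams",
  representation(match_score = "numeric", mismatch_penalty = "numeric",
                 gap_open = "numeric", gap_extend = "numeric",
                 quantification_flank = "integer"))

setValidity("AlignmentParams", function(object) {
  if (!(object@gap_open <= object@gap_extend &&
        object@gap_extend <= 0 && 0 <= object@match_score))
    return("need gap_open <= gap_extend <= 0 <= match_score")
  if (object@quantification_flank < 0L)
    return("quantification_flank must be >= 0")
  TRUE
})

#' @param match_score,mismatch_penalty,gap_open,gap_extend,quantification_flank
#'   see slots.
#' @rdname AlignmentParams-class
#' @export
AlignmentParams <- function(match_score = 2, mismatch_penalty = -2,
                            gap_open = -10, gap_extend = -1,
                            quantification_flank = 3L) {
  new("AlignmentParams", match_score = match_score,
      mismatch_penalty = mismatch_penalty, gap_open = gap_open,
      gap_extend = gap_extend,
      quantification_flank = as.integer(quantification_flank))
}

#' Per-position editing outcome counts over aligned amplicon reads
#'
#' Holds, for every reference position, the number of reads calling
#' A/C/G/T/deletion there -- tallied over all reads (\code{counts}) and
#' over the subset without an indel in the quantification window
#' (\code{counts_noindel}) -- plus insertion counts keyed by the reference
#' gap position (an insertion "after position g"), read totals and the
#' protospacer interval.
#'
#' @slot reference amplicon sequence (\code{DNAString}).
#' @slot protospacer_start,protospacer_end protospacer interval (reference
#'   coordinates, protospacer on the plus strand of the reference).
#' @slot counts,counts_noindel 5 x L integer matrices (rows A,C,G,T,del).
#' @slot insertions integer vector of length L+1: insertions anchored after
#'   reference positions 0..L (over all reads).
#' @slot n_reads_total,n_reads_indel,n_reads_discarded integers.
#' @slot flank quantification flank used.
#' @exportClass AmpliconOutcomeTable
setClass("AmpliconOutcomeTable",
  representation(reference = "DNAString", protospacer_start = "integer",
                 protospacer_end = "integer", counts = "matrix",
                 counts_noindel = "matrix", insertions = "integer",
                 n_reads_total = "integer", n_reads_indel = "integer",
                 n_reads_discarded = "integer", flank = "integer"))

setValidity("AmpliconOutcomeTable", function(object) {
  L <- length(object@reference)
  if (!identical(dim(object@counts), c(5L, L)) ||
      !identical(dim(object@counts_noindel), c(5L, L)))
    return("counts matrices must be 5 x reference length")
  if (object@n_reads_indel > object@n_reads_total)
    return("n_reads_indel must be <= n_reads_total")
  if (object@protospacer_start < 1L || object@protospacer_end > L ||
      object@protospacer_start > object@protospacer_end)
    return("protospacer interval outside reference")
  TRUE
})

setMethod("show", "AmpliconOutcomeTable", function(object) {
  cat(sprintf(paste0("AmpliconOutcomeTable: %d bp reference, protospacer ",
                     "%d-%d\n  %d reads (%d with window indel, %d discarded)\n"),
              length(object@reference), object@protospacer_start,
              object@protospacer_end, object@n_reads_total,
              object@n_reads_indel, object@n_reads_discarded))
})

CALL_LEVELS <- c("A", "C", "G", "T", "-")

## resolve a protospacer given as sequence or c(start, end)
.resolve_protospacer <- function(reference, protospacer) {
  refc <- as.character(reference)
  if (is.character(protospacer)) {
    hits <- gregexpr(protospacer, refc, fixed = TRUE)[[1]]
    if (hits[1] == -1L) stop("protospacer not found in reference")
    if (length(hits) > 1L) stop("protospacer matches reference more than once")
    c(hits[1], hits[1] + nchar(protospacer) - 1L)
  } else {
    as.integer(protospacer[1:2])
  }
}

.align_batch <- function(reads, reference, params) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params@match_score, mismatch = params@mismatch_penalty,
    baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    reads, reference, type = "global", substitutionMatrix = mat,
    gapOpening = -params@gap_open, gapExtension = -params@gap_extend)
}

## reference gap positions (insertion after ref position g) for one
## gapped pattern/subject string pair
.insertion_anchors <- function(pat, subj) {
  sc <- strsplit(subj, "")[[1]]
  refpos <- cumsum(sc != "-")
  gaps <- which(sc == "-")
  if (length(gaps) == 0L) return(integer())
  ## one anchor per gap run
  runs <- split(gaps, cumsum(c(1L, diff(gaps) != 1L)))
  vapply(runs, function(r) refpos[r[1]] , integer(1)) - 0L
}

#' Align one read to the amplicon reference
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties, via
#' \code{Biostrings::pairwiseAlignment}; ties are resolved deterministically
#' by the alignment engine. Returns a base call (or deletion) for every
#' reference position plus insertion records.
#'
#' @param read,reference DNA strings (non-empty).
#' @param params an \linkS4class{AlignmentParams}.
#' @return list with \code{calls} (character vector, one of A/C/G/T/- per
#'   reference position), \code{insertions} (integer vector of reference
#'   positions after which an insertion is anchored; position 0 = before
#'   the reference), and \code{score}.
#' @export
alignRead <- function(read, reference, params = AlignmentParams()) {
  if (!nzchar(as.character(read)) || !nzchar(as.character(reference)))
    stop("read and reference must be non-empty")
  pa <- .align_batch(Biostrings::DNAStringSet(as.character(read)),
                     Biostrings::DNAString(as.character(reference)), params)
  calls <- strsplit(as.character(Biostrings::aligned(pa))[1], "")[[1]]
  ins <- integer()
  if (sum(Biostrings::nindel(pa)@insertion[, "Length"]) > 0L)
    ins <- .insertion_anchors(
      as.character(Biostrings::alignedPattern(pa))[1],
      as.character(Biostrings::alignedSubject(pa))[1])
  list(calls = calls, insertions = unname(ins),
       score = Biostrings::score(pa))
}

#' Quantify editing outcomes over amplicon reads
#'
#' Aligns every read to the amplicon reference (global, affine gaps) and
#' tallies per-reference-position A/C/G/T/deletion calls. A read is an
#' indel read iff any gap event (deletion or insertion) overlaps the
#' quantification window, i.e. the protospacer extended by
#' \code{quantification_flank} on both sides. Substitution counts are
#' tallied from non-gap columns for all reads and, separately, for the
#' indel-free subset (the two denominators reported throughout). Reads
#' shorter than the quantification window are discarded and counted.
#'
#' @param reads character vector or \code{DNAStringSet} of reads.
#' @param reference amplicon reference (string or \code{DNAString}).
#' @param protospacer 20-nt protospacer sequence (must match the reference
#'   plus strand uniquely) or integer \code{c(start, end)} interval.
#' @param params an \linkS4class{AlignmentParams}.
#' @return an \linkS4class{AmpliconOutcomeTable}.
#' @export
quantifyAmplicon <- function(reads, reference, protospacer,
                             params = AlignmentParams()) {
  if (is(reference, "DNAString")) reference <- as.character(reference)
  reference <- toupper(reference)
  L <- nchar(reference)
  ps <- .resolve_protospacer(reference, protospacer)
  if (ps[1] < 1L || ps[2] > L) stop("protospacer interval outside reference")
  win <- c(max(1L, ps[1] - params@quantification_flank),
           min(L, ps[2] + params@quantification_flank))
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)

  empty_counts <- matrix(0L, nrow = 5L, ncol = L,
                         dimnames = list(CALL_LEVELS, NULL))
  short <- nchar(reads) < (win[2] - win[1] + 1L)
  n_disc <- sum(short)
  if (n_disc > 0L) {
    message(n_disc, " read(s) shorter than the quantification window discarded")
    reads <- reads[!short]
  }
  n <- length(reads)
  if (n == 0L)
    return(new("AmpliconOutcomeTable",
               reference = Biostrings::DNAString(reference),
               protospacer_start = ps[1], protospacer_end = ps[2],
               counts = empty_counts, counts_noindel = empty_counts,
               insertions = integer(L + 1L), n_reads_total = 0L,
               n_reads_indel = 0L, n_reads_discarded = n_disc,
               flank = params@quantification_flank))

  ## collapse to unique alleles: duplicated reads align identically, so
  ## align each distinct sequence once and weight the tallies
  allele_tab <- table(reads)
  alleles <- names(allele_tab)
  w <- as.integer(allele_tab)
  k <- length(alleles)

  pa <- .align_batch(Biostrings::DNAStringSet(alleles),
                     Biostrings::DNAString(reference), params)
  m <- matrix(unlist(strsplit(as.character(Biostrings::aligned(pa)), ""),
                     use.names = FALSE),
              nrow = k, ncol = L, byrow = TRUE)

  ## deletions in window, per allele
  del_in_win <- rowSums(m[, win[1]:win[2], drop = FALSE] == "-") > 0L

  ## insertion anchors, only for alleles that have insertions at all
  ins_counts <- integer(L + 1L)  # index g+1 = insertion after position g
  ins_in_win <- rep(FALSE, k)
  has_ins <- Biostrings::nindel(pa)@insertion[, "Length"] > 0L
  if (any(has_ins)) {
    pats <- as.character(Biostrings::alignedPattern(pa))[has_ins]
    subjs <- as.character(Biostrings::alignedSubject(pa))[has_ins]
    anchors <- mapply(.insertion_anchors, pats, subjs, SIMPLIFY = FALSE)
    wi <- w[has_ins]
    for (j in seq_along(anchors))
      for (a in anchors[[j]])
        ins_counts[a + 1L] <- ins_counts[a + 1L] + wi[j]
    ins_in_win[has_ins] <- vapply(
      anchors, function(a) any(a >= win[1] - 1L & a <= win[2]), logical(1))
  }
  is_indel <- del_in_win | ins_in_win

  tally <- function(keep) {
    out <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(CALL_LEVELS, NULL))
    if (!any(keep)) return(out)
    mk <- m[keep, , drop = FALSE]
    wk <- w[keep]
    for (b in CALL_LEVELS)
      out[b, ] <- as.integer(colSums((mk == b) * wk))
    out
  }
  new("AmpliconOutcomeTable",
      reference = Biostrings::DNAString(reference),
      protospacer_start = ps[1], protospacer_end = ps[2],
      counts = tally(rep(TRUE, k)), counts_noindel = tally(!is_indel),
      insertions = ins_counts, n_reads_total = n,
      n_reads_indel = sum(w[is_indel]), n_reads_discarded = n_disc,
      flank = params@quantification_flank)
}

## counts matrix for the requested denominator
.denom_counts <- function(table, denominator) {
  switch(match.arg(denominator, c("without_indels", "with_indels")),
         with_indels = table@counts,
         without_indels = table@counts_noindel)
}

## reference coordinate of a 1-based protospacer position
.proto_ref_pos <- function(table, position) {
  position <- as.integer(position)
  refpos <- table@protospacer_start + position - 1L
  if (position < 1L || refpos > table@protospacer_end)
    stop("position must lie within the protospacer")
  refpos
}

#' Conversion purity at a protospacer position
#'
#' Purity of the desired product among all conversions of the source base:
#' e.g. T-to-G purity = T-to-G yield / (T-to-A + T-to-C + T-to-G yield).
#'
#' @param table an \linkS4class{AmpliconOutcomeTable}.
#' @param position 1-based protospacer position.
#' @param source_base reference base at the position (checked; default "T").
#' @param product desired product base (default "G").
#' @param denominator read set: \code{"without_indels"} (default) or
#'   \code{"with_indels"}.
#' @return purity in [0,1], or \code{NA} when no conversions were observed.
#' @export
conversionPurity <- function(table, position, source_base = "T",
                             product = "G",
                             denominator = "without_indels") {
  refpos <- .proto_ref_pos(table, position)
  refbase <- substr(as.character(table@reference), refpos, refpos)
  if (refbase != source_base)
    stop("reference base at protospacer position ", position, " is ",
         refbase, ", not ", source_base)
  cnt <- .denom_counts(table, denominator)[, refpos]
  converted <- sum(cnt[setdiff(BASES, source_base)])
  if (converted == 0L) return(NA_real_)
  unname(cnt[product] / converted)
}

#' T-to-S conversion ratio at a protospacer position
#'
#' Ratio of strong-base products among all conversions of the source base:
#' T-to-S ratio = (T-to-C + T-to-G yield) / (T-to-A + T-to-C + T-to-G
#' yield). Greater than or equal to the single-product purity by
#' construction.
#'
#' @inheritParams conversionPurity
#' @param products the "desired" product set (default C and G).
#' @return ratio in [0,1], or \code{NA} when no conversions were observed.
#' @export
conversionRatioTS <- function(table, position, source_base = "T",
                              products = c("C", "G"),
                              denominator = "without_indels") {
  refpos <- .proto_ref_pos(table, position)
  refbase <- substr(as.character(table@reference), refpos, refpos)
  if (refbase != source_base)
    stop("reference base at protospacer position ", position, " is ",
         refbase, ", not ", source_base)
  cnt <- .denom_counts(table, denominator)[, refpos]
  converted <- sum(cnt[setdiff(BASES, source_base)])
  if (converted == 0L) return(NA_real_)
  unname(sum(cnt[setdiff(products, source_base)]) / converted)
}

#' Indel frequency of an outcome table
#'
#' Fraction of reads carrying a gap event (insertion or deletion)
#' overlapping the quantification window.
#'
#' @param table an \linkS4class{AmpliconOutcomeTable}.
#' @return \code{n_reads_indel / n_reads_total}; \code{NA} when the table
#'   holds no reads.
#' @export
indelFrequency <- function(table) {
  stopifnot(is(table, "AmpliconOutcomeTable"))
  if (table@n_reads_total == 0L) return(NA_real_)
  table@n_reads_indel / table@n_reads_total
}

#' Per-position conversion frequency
#'
#' Frequency of reads calling \code{product} at a protospacer position,
#' under either denominator: \code{with_indels} divides by all reads
#' aligned across the position (deletion calls included in the
#' denominator), \code{without_indels} by indel-free reads only.
#'
#' @inheritParams conversionPurity
#' @param product product base.
#' @return frequency in [0,1]; \code{NA} if no reads cover the position.
#' @export
conversionFrequency <- function(table, position, product,
                                denominator = "without_indels") {
  refpos <- .proto_ref_pos(table, position)
  cnt <- .denom_counts(table, denominator)[, refpos]
  tot <- sum(cnt)
  if (tot == 0L) return(NA_real_)
  unname(cnt[product] / tot)
}

#' Summarize editing outcomes at a site
#'
#' Collapses an \linkS4class{AmpliconOutcomeTable} into the per-site
#' summary used for window and motif profiling: per-protospacer-position
#' conversion frequency of the source base (both denominators), the peak
#' position, indel frequency, and purity / T-to-S-style ratio at the peak.
#'
#' @param table an \linkS4class{AmpliconOutcomeTable}.
#' @param source_base the edited base (default "T").
#' @param products the editor's intended products (default C and G).
#' @return list of class \code{EditingSummary}: \code{conv_without},
#'   \code{conv_with} (length-20 numeric, NA where the reference base at
#'   that protospacer position is not \code{source_base}),
#'   \code{peak_position}, \code{indel_frequency}, \code{purity},
#'   \code{ts_ratio}, \code{reference}, \code{protospacer_start},
#'   \code{source_base}.
#' @export
summarizeEditing <- function(table, source_base = "T",
                             products = c("C", "G")) {
  stopifnot(is(table, "AmpliconOutcomeTable"))
  refc <- as.character(table@reference)
  plen <- min(20L, table@protospacer_end - table@protospacer_start + 1L)
  conv <- function(denom) {
    out <- rep(NA_real_, 20L)
    cnts <- .denom_counts(table, denom)
    for (p in seq_len(plen)) {
      refpos <- table@protospacer_start + p - 1L
      if (substr(refc, refpos, refpos) != source_base) next
      cnt <- cnts[, refpos]
      tot <- sum(cnt)
      if (tot == 0L) next
      out[p] <- sum(cnt[setdiff(BASES, source_base)]) / tot
    }
    out
  }
  cw <- conv("without_indels"); ca <- conv("with_indels")
  peak <- if (all(is.na(cw))) NA_integer_ else which.max(cw)  # ties: lower
  purity <- ts <- NA_real_
  if (!is.na(peak)) {
    purity <- conversionPurity(table, peak, source_base, products[length(products)])
    ts <- conversionRatioTS(table, peak, source_base, products)
  }
  structure(list(conv_without = cw, conv_with = ca, peak_position = peak,
                 indel_frequency = indelFrequency(table), purity = purity,
                 ts_ratio = ts, reference = refc,
                 protospacer_start = table@protospacer_start,
                 source_base = source_base),
            class = "EditingSummary")
}

#' @export
print.EditingSummary <- function(x, ...) {
  cat(sprintf("EditingSummary (%s editing): peak position %s, indel freq %s\n",
              x$source_base,
              ifelse(is.na(x$peak_position), "NA", x$peak_position),
              format(x$indel_frequency, digits = 3)))
  invisible(x)
}

#' Aggregate editing-window profile across sites
#'
#' Collects site-level per-position conversion frequencies (protospacer
#' positions 1--20) and reports median and quartiles per position, the peak
#' position (highest median; ties break toward the PAM-distal, lower
#' position) and the inferred optimal window: the contiguous run of
#' positions around the peak whose median frequency exceeds
#' \code{threshold} times the peak median.
#'
#' @param summaries list of \code{EditingSummary} objects (or bare numeric
#'   length-20 vectors of per-position frequencies).
#' @param threshold fraction of the peak median required for window
#'   membership (default 0.5).
#' @param denominator which site-level frequencies to use (default
#'   \code{"without_indels"}).
#' @return list of class \code{WindowProfile}: \code{median}, \code{q25},
#'   \code{q75}, \code{n_sites} (per position), \code{peak},
#'   \code{window} (c(start, end)), \code{threshold}.
#' @export
windowProfile <- function(summaries, threshold = 0.5,
                          denominator = "without_indels") {
  stopifnot(length(summaries) >= 1L)
  freqs <- lapply(summaries, function(s) {
    if (inherits(s, "EditingSummary"))
      if (denominator == "without_indels") s$conv_without else s$conv_with
    else as.numeric(s)
  })
  fm <- do.call(rbind, freqs)
  stopifnot(ncol(fm) == 20L)
  med <- apply(fm, 2L, median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  q25 <- apply(fm, 2L, quantile, probs = 0.25, na.rm = TRUE, names = FALSE)
  q75 <- apply(fm, 2L, quantile, probs = 0.75, na.rm = TRUE, names = FALSE)
  n_sites <- colSums(!is.na(fm))
  usable <- !is.na(med)
  if (!any(usable)) stop("no position has an observed frequency")
  peak <- which(usable)[which.max(med[usable])]  # which.max: first (lower) tie
  keep <- usable & med >= threshold * med[peak]
  lo <- peak; hi <- peak
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  while (hi < 20L && keep[hi + 1L]) hi <- hi + 1L
  structure(list(median = med, q25 = q25, q75 = q75, n_sites = n_sites,
                 peak = peak, window = c(lo, hi), threshold = threshold),
            class = "WindowProfile")
}

#' @export
print.WindowProfile <- function(x, ...) {
  cat(sprintf("WindowProfile: inferred optimal window %d-%d, peak %d (threshold %.2f of peak)\n",
              x$window[1], x$window[2], x$peak, x$threshold))
  invisible(x)
}

#' 5'-motif preference of editing
#'
#' Groups each site by the 5' neighbor of its maximally edited target base
#' (AN/CN/GN/TN motifs, N = the source base) and reports the mean,
#' standard deviation and count of the site-level maximal conversion
#' frequency per group. Sites whose peak base sits at reference position 1
#' (no 5' neighbor) are excluded with a warning.
#'
#' @param summaries list of \code{EditingSummary} objects (as produced by
#'   \code{\link{summarizeEditing}}; each carries its reference sequence).
#' @param denominator which frequencies to use (default
#'   \code{"without_indels"}).
#' @return data.frame with \code{motif} (e.g. "AC"), \code{mean_freq},
#'   \code{sd_freq}, \code{n_sites}.
#' @export
motifPreference <- function(summaries, denominator = "without_indels") {
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "EditingSummary"))
    freqs <- if (denominator == "without_indels") s$conv_without else s$conv_with
    if (all(is.na(freqs))) return(NULL)
    peak <- which.max(freqs)
    refpos <- s$protospacer_start + peak - 1L
    if (refpos <= 1L) {
      warning("site peak at reference position 1 has no 5' neighbor; excluded")
      return(NULL)
    }
    motif <- paste0(substr(s$reference, refpos - 1L, refpos - 1L),
                    s$source_base)
    data.frame(motif = motif, freq = freqs[peak])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    return(data.frame(motif = character(), mean_freq = numeric(),
                      sd_freq = numeric(), n_sites = integer()))
  agg <- split(rows$freq, rows$motif)
  out <- data.frame(motif = names(agg),
                    mean_freq = vapply(agg, mean, numeric(1)),
                    sd_freq = vapply(agg, function(v)
                      if (length(v) > 1L) sd(v) else NA_real_, numeric(1)),
                    n_sites = vapply(agg, length, integer(1)))
  rownames(out) <- NULL
  out
}

#' Fold change between two efficiencies
#'
#' Ratio of two (percentage) values rounded to 2 significant figures, the
#' convention used when reporting editing-efficiency enhancements.
#'
#' @param value_a,value_b numeric values on the same scale;
#'   \code{value_b > 0}.
#' @return \code{signif(value_a / value_b, 2)}; \code{NA} when
#'   \code{value_b} is 0.
#' @examples
#' foldChange(10.2, 1.0)   # 10
#' foldChange(51.4, 13.3)  # 3.9
#' @export
foldChange <- function(value_a, value_b) {
  if (any(value_b < 0)) stop("value_b must be non-negative")
  out <- ifelse(value_b == 0, NA_real_, signif(value_a / value_b, 2))
  out
}
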