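## Columns shared by all GuideCandidate tables
.empty_candidates <- function() {
  data.frame(gene = character(), application = character(),
             site_kind = character(), protospacer = character(),
             pam = character(), start = integer(), end = integer(),
             strand = character(), targeted_base_position = integer(),
             targeted_locus_pos = integer(), targeted_base = character(),
             intended_products = character(), editor = character(),
             codon_index = integer(), codon = character(),
             edited_codon = character(), edited_aa = character())
}

.candidate_row <- function(gene_id, application, site_kind, frame, p,
                           locus_pos, base_on_proto, products, editor_name,
                           codon_index = NA_integer_, codon = NA_character_,
                           edited_codon = NA_character_,
                           edited_aa = NA_character_) {
  data.frame(gene = gene_id, application = application,
             site_kind = site_kind, protospacer = frame$protospacer,
             pam = frame$pam, start = frame$start, end = frame$end,
             strand = frame$strand, targeted_base_position = p,
             targeted_locus_pos = locus_pos, targeted_base = base_on_proto,
             intended_products = paste(products, collapse = ","),
             editor = editor_name, codon_index = codon_index,
             codon = codon, edited_codon = edited_codon,
             edited_aa = edited_aa)
}

## base as read on the protospacer strand at a locus coordinate
.base_on_strand <- function(seqc, pos, strand) {
  b <- substr(seqc, pos, pos)
  if (strand == "+") b else complementChar(b)
}

#' Design sgRNAs that disrupt splice donor/acceptor sites
#'
#' For every canonical splice site of a gene and every PAM-valid protospacer
#' frame on either strand, emits a guide candidate whenever at least one base
#' of the SD (GT) or SA (AG) dinucleotide, as read on the protospacer strand,
#' is the editor's source base and falls inside the requested editing window.
#' Any conversion of either dinucleotide base is treated as disrupting the
#' site (and hence inducing skipping of the flanked exon).
#'
#' @param gene a \linkS4class{GeneModel} (coding-strand-wise).
#' @param editor an \linkS4class{EditorSpec}.
#' @param mode \code{"optimal"} (default; the window used for candidate
#'   counting) or \code{"editable"}.
#' @return GuideCandidate data.frame, one row per (frame, targeted
#'   dinucleotide base); applications are \code{SD_disruption} /
#'   \code{SA_disruption}.
#' @export
findSpliceSiteGuides <- function(gene, editor,
                                 mode = c("optimal", "editable")) {
  stopifnot(is(gene, "GeneModel"), is(editor, "EditorSpec"))
  mode <- match.arg(mode)
  sites <- findSpliceSites(gene)
  if (nrow(sites) == 0L) return(.empty_candidates())
  frames <- scanProtospacers(gene@sequence, editor@pam)
  if (nrow(frames) == 0L) return(.empty_candidates())
  seqc <- as.character(gene@sequence)
  products <- intendedProducts(editor)
  rows <- list()
  for (s in seq_len(nrow(sites))) {
    site <- sites[s, ]
    app <- if (site$kind == "donor") "SD_disruption" else "SA_disruption"
    for (pos in c(site$pos1, site$pos2)) {
      for (f in seq_len(nrow(frames))) {
        fr <- frames[f, ]
        p <- locusToProtoPos(fr$start, fr$end, fr$strand, pos)
        if (p < 1L || p > 20L) next
        b <- .base_on_strand(seqc, pos, fr$strand)
        if (!b %in% BASES) next
        if (canEdit(editor, b, p, mode))
          rows[[length(rows) + 1L]] <- .candidate_row(
            gene@id, app, site$kind, fr, p, pos, b, products, editor@name)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate single-base codon edits reachable by an editor
#'
#' Applies the editor's chemistry to every codon position on both strands:
#' a sense-strand edit replaces the codon base directly; an antisense edit
#' converts the paired base, so the sense codon acquires the complement of
#' the product. Each outcome is annotated with its translation.
#'
#' @param codon 3-letter codon over A/C/G/T.
#' @param editor an \linkS4class{EditorSpec}.
#' @param products \code{"predominant"} (default: design-time intended
#'   edits exclude minor products) or \code{"all"}.
#' @return data.frame with \code{codon_pos} (1..3), \code{strand}
#'   (\code{sense}/\code{antisense}: the protospacer strand carrying the
#'   source base), \code{product} (base written on the protospacer strand),
#'   \code{edited_codon}, \code{aa}, \code{is_stop}.
#' @examples
#' reg <- builtinEditors()
#' codonEditOutcomes("TAC", reg[["gGBE"]])  # TAA / TAG, both stops
#' @export
codonEditOutcomes <- function(codon, editor,
                              products = c("predominant", "all")) {
  products <- match.arg(products)
  codon <- toupper(codon)
  if (nchar(codon) != 3L || !all(strsplit(codon, "")[[1]] %in% BASES))
    stop("codon must be 3 letters over A/C/G/T")
  stopifnot(is(editor, "EditorSpec"))
  src <- editor@conversion@source_base
  prods <- if (products == "predominant") intendedProducts(editor)
           else editor@conversion@product_bases
  cb <- strsplit(codon, "")[[1]]
  rows <- list()
  for (i in 1:3) {
    if (cb[i] == src) {                      # edit on the sense strand
      for (P in prods) {
        nc <- cb; nc[i] <- P
        ec <- paste(nc, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          codon_pos = i, strand = "sense", product = P, edited_codon = ec,
          aa = translateCodon(ec), is_stop = ec %in% STOP_CODONS)
      }
    }
    if (complementChar(cb[i]) == src) {      # edit on the antisense strand
      for (P in prods) {
        nc <- cb; nc[i] <- complementChar(P)
        ec <- paste(nc, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          codon_pos = i, strand = "antisense", product = P,
          edited_codon = ec, aa = translateCodon(ec),
          is_stop = ec %in% STOP_CODONS)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(codon_pos = integer(), strand = character(),
                      product = character(), edited_codon = character(),
                      aa = character(), is_stop = logical()))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

## shared candidate emitter for codon-level designs
.codon_guides <- function(gene, editor, mode, codon_indices, keep_outcome,
                          application) {
  seqc <- as.character(gene@sequence)
  cdsp <- cdsPositions(gene)
  if (length(cdsp) %% 3L != 0L)
    warning("CDS length of ", gene@id, " is not a multiple of 3; ",
            "trailing bases ignored")
  frames <- scanProtospacers(gene@sequence, editor@pam)
  rows <- list()
  for (ci in codon_indices) {
    idx <- (ci - 1L) * 3L + 1:3
    codon <- paste(substring(seqc, cdsp[idx], cdsp[idx]), collapse = "")
    if (grepl("N", codon, fixed = TRUE)) next
    outs <- codonEditOutcomes(codon, editor)
    outs <- outs[keep_outcome(outs, codon), , drop = FALSE]
    if (nrow(outs) == 0L || nrow(frames) == 0L) next
    for (o in seq_len(nrow(outs))) {
      oc <- outs[o, ]
      locus_pos <- cdsp[idx[oc$codon_pos]]
      want_strand <- if (oc$strand == "sense") "+" else "-"
      for (f in which(frames$strand == want_strand)) {
        fr <- frames[f, ]
        p <- locusToProtoPos(fr$start, fr$end, fr$strand, locus_pos)
        if (p < 1L || p > 20L) next
        b <- .base_on_strand(seqc, locus_pos, fr$strand)
        if (canEdit(editor, b, p, mode))
          rows[[length(rows) + 1L]] <- .candidate_row(
            gene@id, application, NA_character_, fr, p, locus_pos, b,
            oc$product, editor@name, codon_index = ci, codon = codon,
            edited_codon = oc$edited_codon, edited_aa = oc$aa)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design sgRNAs that introduce a premature termination codon
#'
#' Scans every in-frame sense codon of the CDS for single-base edits,
#' reachable by the editor's chemistry on either strand, that create a stop
#' codon (TAA/TAG/TGA) and for which the edited base lies inside the
#' editor's window of a PAM-valid protospacer. Candidates editing the
#' initiator codon or the natural stop codon are excluded.
#'
#' @inheritParams findSpliceSiteGuides
#' @return GuideCandidate data.frame (application \code{PTC_introduction})
#'   with the targeted codon, its index and the resulting stop codon.
#' @export
findPtcIntroductionGuides <- function(gene, editor,
                                      mode = c("optimal", "editable")) {
  stopifnot(is(gene, "GeneModel"), is(editor, "EditorSpec"))
  mode <- match.arg(mode)
  if (length(gene@cds) == 0L) stop("gene ", gene@id, " has no CDS")
  n_codons <- length(cdsPositions(gene)) %/% 3L
  if (n_codons < 3L) return(.empty_candidates())
  idx <- 2:(n_codons - 1L)  # exclude initiator and natural stop
  .codon_guides(gene, editor, mode, idx,
                function(outs, codon) outs$is_stop & !codon %in% STOP_CODONS,
                "PTC_introduction")
}

#' Design sgRNAs that bypass an annotated premature termination codon
#'
#' For a CDS codon annotated as a PTC (TAA/TAG/TGA), emits candidates whose
#' edit converts the stop into a sense codon; each candidate records the
#' reachable sense codon and its amino acid. Outcomes that remain stop
#' codons are dropped.
#'
#' @inheritParams findSpliceSiteGuides
#' @param ptc_codon_index 1-based index of the PTC codon within the CDS.
#' @return GuideCandidate data.frame (application \code{PTC_bypass}).
#' @export
findPtcBypassGuides <- function(gene, ptc_codon_index, editor,
                                mode = c("optimal", "editable")) {
  stopifnot(is(gene, "GeneModel"), is(editor, "EditorSpec"))
  mode <- match.arg(mode)
  if (length(gene@cds) == 0L) stop("gene ", gene@id, " has no CDS")
  cdsp <- cdsPositions(gene)
  idx <- (ptc_codon_index - 1L) * 3L + 1:3
  if (any(idx > length(cdsp))) stop("ptc_codon_index outside the CDS")
  seqc <- as.character(gene@sequence)
  codon <- paste(substring(seqc, cdsp[idx], cdsp[idx]), collapse = "")
  if (!codon %in% STOP_CODONS)
    stop("codon at index ", ptc_codon_index, " is ", codon,
         ", not a stop codon")
  .codon_guides(gene, editor, mode, ptc_codon_index,
                function(outs, codon) !outs$is_stop, "PTC_bypass")
}

#' Partition guide candidates across editors (Venn regions)
#'
#' Candidate identity is (protospacer sequence, locus interval, guide
#' strand); an sgRNA belongs to an editor's set if it is valid for at least
#' one targeted base. Returns the disjoint region counts over all editor
#' subsets plus per-editor exclusive counts.
#'
#' @param candidate_sets named list: editor name -> GuideCandidate
#'   data.frame (or character vector of precomputed identities).
#' @return a \code{VennPartition} list: \code{sets} (unique identities per
#'   editor), \code{region_counts} (named by editor subsets joined with
#'   \code{&}), \code{exclusive} (per-editor exclusive counts),
#'   \code{union_size}.
#' @export
classifyAcrossEditors <- function(candidate_sets) {
  stopifnot(is.list(candidate_sets), !is.null(names(candidate_sets)))
  ids <- lapply(candidate_sets, function(x) {
    if (is.character(x)) return(unique(x))
    if (nrow(x) == 0L) return(character())
    unique(paste(x$protospacer, x$start, x$end, x$strand, sep = "|"))
  })
  editors <- names(ids)
  univ <- unique(unlist(ids))
  memb <- vapply(ids, function(s) univ %in% s,
                 logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1L,
                                         dimnames = list(NULL, editors))
  if (length(univ) == 0L)
    memb <- matrix(logical(), nrow = 0L, ncol = length(editors),
                   dimnames = list(NULL, editors))
  key <- apply(memb, 1L, function(r) paste(editors[r], collapse = "&"))
  region_counts <- integer()
  subsets <- unlist(lapply(seq_along(editors), function(k)
    combn(editors, k, function(s) paste(s, collapse = "&"),
          simplify = TRUE)))
  region_counts <- setNames(integer(length(subsets)), subsets)
  tab <- table(key)
  region_counts[names(tab)] <- as.integer(tab)
  exclusive <- setNames(region_counts[editors], editors)
  structure(list(sets = ids, region_counts = region_counts,
                 exclusive = exclusive, union_size = length(univ)),
            class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition over", length(x$sets), "editors; union size",
      x$union_size, "\n")
  nz <- x$region_counts[x$region_counts > 0L]
  for (nm in names(nz)) cat(sprintf("  %-30s %d\n", nm, nz[[nm]]))
  invisible(x)
}

#' Will an editor restore an inactivated splice acceptor?
#'
#' Intron-split fluorescent reporters inactivate the AG splice acceptor by
#' mutating its G (AG-to-AT or AG-to-AC); only a T-to-G or C-to-G
#' conversion at the mutated base restores AG and hence correct splicing.
#' The mutated base is placed at a known protospacer position on the
#' targeted strand (position 6 in the reporter design emulated here).
#'
#' @param acceptor 2-letter mutated acceptor dinucleotide (e.g. "AT", "AC").
#' @param editor an \linkS4class{EditorSpec}.
#' @param position protospacer position of the mutated base (default 6).
#' @param mode window mode (default \code{"editable"}).
#' @return \code{TRUE} iff some predominant product of the editor's
#'   chemistry at the mutated base restores the AG dinucleotide.
#' @examples
#' reg <- builtinEditors()
#' predictReporterRestoration("AT", reg[["gTBEv3"]])  # TRUE: T-to-G
#' predictReporterRestoration("AT", reg[["gCBEv2"]])  # FALSE: no T chemistry
#' @export
predictReporterRestoration <- function(acceptor, editor, position = 6L,
                                       mode = c("editable", "optimal")) {
  mode <- match.arg(mode)
  acceptor <- toupper(acceptor)
  if (nchar(acceptor) != 2L || substr(acceptor, 1L, 1L) != "A")
    stop("acceptor must be a 2-letter dinucleotide starting with A")
  position <- as.integer(position)
  if (position < 1L || position > 20L)
    stop("guide does not cover the mutated base (position outside 1..20)")
  mutated <- substr(acceptor, 2L, 2L)
  if (mutated == "G") return(FALSE)  # nothing to restore
  canEdit(editor, mutated, position, mode) &&
    "G" %in% intendedProducts(editor)
}
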