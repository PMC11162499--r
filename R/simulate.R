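#' Ground-truth outcome model for amplicon read simulation
#'
#' Describes the editing-outcome mixture a site produces: per-protospacer-
#' position substitution probabilities (position -> product base ->
#' probability), a per-read indel probability with a signed length
#' distribution (negative = deletion, positive = insertion), and a uniform
#' per-base sequencing error rate. Indels and substitutions are mutually
#' exclusive per read, mirroring how conversion and indel outcome classes
#' are reported as separate fractions.
#'
#' @slot reference amplicon sequence (\code{DNAString}).
#' @slot protospacer_start,protospacer_end protospacer interval on the
#'   reference plus strand.
#' @slot sub_probs named list: protospacer position (as character) -> named
#'   numeric of product-base probabilities (summing to <= 1).
#' @slot indel_probability per-read probability of one indel event, placed
#'   uniformly in the quantification window.
#' @slot indel_lengths,indel_length_probs signed indel lengths and their
#'   probabilities.
#' @slot error_rate per-base uniform miscall probability.
#' @slot seed RNG seed making simulation deterministic.
#' @exportClass OutcomeModel
setClass("OutcomeModel",
  representation(reference = "DNAString", protospacer_start = "integer",
                 protospacer_end = "integer", sub_probs = "list",
                 indel_probability = "numeric", indel_lengths = "integer",
                 indel_length_probs = "numeric", error_rate = "numeric",
                 seed = "integer"))

setValidity("OutcomeModel", function(object) {
  msg <- character()
  for (nm in names(object@sub_probs)) {
    p <- object@sub_probs[[nm]]
    if (any(p < 0) || sum(p) > 1 + 1e-12)
      msg <- c(msg, paste0("substitution probabilities at position ", nm,
                           " must be >= 0 and sum to <= 1"))
    if (!all(names(p) %in% BASES))
      msg <- c(msg, "product bases must be nucleotides")
  }
  if (object@indel_probability < 0 || object@indel_probability > 1)
    msg <- c(msg, "indel_probability must be in [0,1]")
  if (any(object@indel_lengths == 0L))
    msg <- c(msg, "indel lengths must be nonzero")
  if (length(object@indel_lengths) != length(object@indel_length_probs))
    msg <- c(msg, "indel length distribution malformed")
  if (object@error_rate < 0 || object@error_rate > 0.75)
    msg <- c(msg, "error_rate must be in [0, 0.75]")
  if (length(msg)) msg else TRUE
})

#' @param reference amplicon sequence (string or DNAString).
#' @param protospacer 20-nt sequence present on the reference plus strand,
#'   or integer \code{c(start, end)}.
#' @param sub_probs named list mapping protospacer positions (names,
#'   e.g. \code{"5"}) to named product-probability vectors
#'   (e.g. \code{c(G = 0.4, C = 0.2)}).
#' @param indel_probability,indel_lengths,indel_length_probs,error_rate,seed
#'   see slots; defaults: no indels beyond \code{indel_probability}, length
#'   mix of 1--3 bp deletions and 1 bp insertions, no sequencing error,
#'   seed 1.
#' @rdname OutcomeModel-class
#' @export
OutcomeModel <- function(reference, protospacer, sub_probs = list(),
                         indel_probability = 0,
                         indel_lengths = c(-3L, -2L, -1L, 1L),
                         indel_length_probs = c(0.2, 0.3, 0.3, 0.2),
                         error_rate = 0, seed = 1L) {
  if (is.character(reference)) reference <- Biostrings::DNAString(toupper(reference))
  ps <- .resolve_protospacer(reference, protospacer)
  new("OutcomeModel", reference = reference,
      protospacer_start = ps[1], protospacer_end = ps[2],
      sub_probs = sub_probs, indel_probability = indel_probability,
      indel_lengths = as.integer(indel_lengths),
      indel_length_probs = indel_length_probs / sum(indel_length_probs),
      error_rate = error_rate, seed = as.integer(seed))
}

setMethod("show", "OutcomeModel", function(object) {
  cat(sprintf(paste0("OutcomeModel: %d bp reference, protospacer %d-%d, ",
                     "%d edited position(s),\n  indel prob %.3g, error rate %.3g, seed %d\n"),
              length(object@reference), object@protospacer_start,
              object@protospacer_end, length(object@sub_probs),
              object@indel_probability, object@error_rate, object@seed))
})

#' Simulate amplicon reads with a ground-truth ledger
#'
#' Draws \code{n} reads independently from an \linkS4class{OutcomeModel}:
#' each read first draws whether it carries one indel (placed uniformly in
#' the protospacer +/- \code{flank} window); otherwise per-position
#' substitutions are drawn from the model's probability map; uniform
#' sequencing error is overlaid last. Deterministic given the model's seed.
#'
#' @param model an \linkS4class{OutcomeModel}.
#' @param n number of reads (>= 1).
#' @param flank window flank for indel placement (default 3, matching the
#'   default quantification flank).
#' @return list with \code{reads} (a \code{DNAStringSet}) and
#'   \code{ledger}, a data.frame recording per read the true event class
#'   (\code{none}/\code{deletion}/\code{insertion}), indel position and
#'   length, and the true substitutions (e.g. \code{"5T>G"},
#'   comma-separated).
#' @export
simulateAmpliconReads <- function(model, n, flank = 3L) {
  stopifnot(is(model, "OutcomeModel"), n >= 1L)
  refc <- as.character(model@reference)
  L <- nchar(refc)
  win <- c(max(1L, model@protospacer_start - flank),
           min(L, model@protospacer_end + flank))
  pos_map <- lapply(names(model@sub_probs), function(nm) {
    p <- as.integer(nm)
    refpos <- model@protospacer_start + p - 1L
    list(proto = p, refpos = refpos, probs = model@sub_probs[[nm]])
  })
  for (pm in pos_map) {
    if (pm$refpos < 1L || pm$refpos > L)
      stop("substitution position ", pm$proto, " outside the reference")
  }

  withSeed(model@seed, {
    refv <- strsplit(refc, "")[[1]]
    reads <- character(n)
    ev_class <- character(n); ev_pos <- rep(NA_integer_, n)
    ev_len <- rep(NA_integer_, n); ev_subs <- character(n)
    is_indel <- stats::runif(n) < model@indel_probability
    for (i in seq_len(n)) {
      rv <- refv
      subs <- character()
      if (is_indel[i]) {
        len <- sample(model@indel_lengths, 1L,
                      prob = model@indel_length_probs)
        if (len < 0L) {  # deletion starting uniformly in window
          maxstart <- min(win[2], L + len + 1L)
          start <- sample(win[1]:maxstart, 1L)
          rv <- rv[-(start:(start - len - 1L))]
          ev_class[i] <- "deletion"
        } else {         # insertion after a uniform window position
          after <- sample((win[1] - 1L):win[2], 1L)
          insbases <- sample(BASES, len, replace = TRUE)
          rv <- append(rv, insbases, after = after)
          start <- after
          ev_class[i] <- "insertion"
        }
        ev_pos[i] <- start; ev_len[i] <- len
      } else {
        ev_class[i] <- "none"
        for (pm in pos_map) {
          pr <- pm$probs
          u <- stats::runif(1)
          cum <- cumsum(pr)
          k <- which(u < cum)
          if (length(k)) {
            prod <- names(pr)[k[1]]
            rv[pm$refpos] <- prod
            subs <- c(subs, paste0(pm$proto, refv[pm$refpos], ">", prod))
          }
        }
      }
      if (model@error_rate > 0) {
        err <- stats::runif(length(rv)) < model@error_rate
        if (any(err)) {
          for (j in which(err))
            rv[j] <- sample(setdiff(BASES, rv[j]), 1L)
        }
      }
      reads[i] <- paste(rv, collapse = "")
      ev_subs[i] <- paste(subs, collapse = ",")
    }
    list(reads = Biostrings::DNAStringSet(reads),
         ledger = data.frame(read = seq_len(n), event = ev_class,
                             indel_pos = ev_pos, indel_len = ev_len,
                             substitutions = ev_subs))
  })
}

#' Simulate a toy gene model with planted, recoverable features
#'
#' Generates a multi-exon gene locus with canonical GT/AG introns, a CDS
#' starting with ATG and ending with a stop codon, and -- optionally -- a
#' planted in-frame PTC and a planted NGG PAM that places a chosen
#' splice-site base at a chosen protospacer position. Everything planted is
#' recorded in the returned ledger. Deterministic given \code{seed}.
#'
#' @param n_exons number of exons (>= 2).
#' @param exon_length,intron_length lengths (single values or ranges to
#'   sample from uniformly).
#' @param plant_ptc plant a TAA/TAG/TGA codon in-frame mid-CDS?
#' @param plant_pam list or NULL: plant an NGG PAM so that a splice-site
#'   base sits at a chosen protospacer position; fields \code{site} (index
#'   into the splice-site table), \code{dinuc_base} (1 or 2),
#'   \code{position} (protospacer position), \code{strand} ("+"/"-").
#' @param gc GC fraction of the background (default 0.5, uniform ACGT).
#' @param seed RNG seed.
#' @param id gene identifier.
#' @return list with \code{gene} (a \linkS4class{GeneModel}) and
#'   \code{ledger} (list: splice-site table with planted coordinates, CDS
#'   codon table, planted PTC codon index, planted PAM description).
#' @export
simulateGeneModel <- function(n_exons = 3L, exon_length = c(60L, 120L),
                              intron_length = c(40L, 90L),
                              plant_ptc = FALSE, plant_pam = NULL,
                              gc = 0.5, seed = 1L, id = "synthgene") {
  stopifnot(n_exons >= 2L)
  withSeed(seed, {
    rlen <- function(r) if (length(r) == 2L) sample(r[1]:r[2], 1L) else r[1]
    rbg <- function(k) paste(sample(BASES, k, replace = TRUE,
                                    prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                             (1 - gc) / 2)), collapse = "")
    exlens <- vapply(seq_len(n_exons), function(i) rlen(exon_length),
                     integer(1))
    ## keep total CDS length a multiple of 3 with room for start/stop
    inlens <- vapply(seq_len(n_exons - 1L), function(i) rlen(intron_length),
                     integer(1))
    total_exonic <- sum(exlens)
    excess <- (total_exonic - 6L) %% 3L
    exlens[n_exons] <- exlens[n_exons] - excess

    pieces <- character(0)
    exon_starts <- integer(n_exons); exon_ends <- integer(n_exons)
    cursor <- 0L
    for (i in seq_len(n_exons)) {
      ex <- rbg(exlens[i])
      exon_starts[i] <- cursor + 1L
      exon_ends[i] <- cursor + exlens[i]
      pieces <- c(pieces, ex)
      cursor <- cursor + exlens[i]
      if (i < n_exons) {
        intron <- paste0("GT", rbg(inlens[i] - 4L), "AG")
        pieces <- c(pieces, intron)
        cursor <- cursor + inlens[i]
      }
    }
    seqc <- paste(pieces, collapse = "")
    ## CDS = all exonic bases; force ATG ... stop
    substr(seqc, 1L, 3L) <- "ATG"
    cds <- IRanges::IRanges(start = exon_starts, end = exon_ends)
    gene0 <- GeneModel(id, seqc, cds, cds = cds, strand = "+")
    cdsp <- cdsPositions(gene0)
    n_codons <- length(cdsp) %/% 3L
    last_idx <- cdsp[((n_codons - 1L) * 3L + 1L):(n_codons * 3L)]
    for (k in 1:3) substr(seqc, last_idx[k], last_idx[k]) <-
      substr("TAA", k, k)
    ## scrub accidental internal stops so the planted PTC is unique
    seqc_v <- strsplit(seqc, "")[[1]]
    for (ci in 2:(n_codons - 1L)) {
      idx <- cdsp[((ci - 1L) * 3L + 1L):(ci * 3L)]
      while (paste(seqc_v[idx], collapse = "") %in% STOP_CODONS)
        seqc_v[idx[1]] <- sample(c("C", "G"), 1L)
    }
    seqc <- paste(seqc_v, collapse = "")

    ptc_index <- NA_integer_
    if (plant_ptc) {
      ptc_index <- sample(3:(n_codons - 2L), 1L)
      idx <- cdsp[((ptc_index - 1L) * 3L + 1L):(ptc_index * 3L)]
      ptc <- sample(STOP_CODONS, 1L)
      for (k in 1:3) substr(seqc, idx[k], idx[k]) <- substr(ptc, k, k)
    }

    gene <- GeneModel(id, seqc, cds, cds = cds, strand = "+")
    sites <- findSpliceSites(gene)

    pam_plant <- NULL
    if (!is.null(plant_pam)) {
      st <- sites[plant_pam$site, ]
      base_pos <- if ((plant_pam$dinuc_base %||% 1L) == 1L) st$pos1 else st$pos2
      p <- plant_pam$position
      strand <- plant_pam$strand %||% "+"
      L <- nchar(seqc)
      if (strand == "+") {
        fstart <- base_pos - p + 1L
        pam_at <- fstart + 20L
        if (fstart < 1L || pam_at + 2L > L)
          stop("infeasible PAM placement for planted site")
        substr(seqc, pam_at + 1L, pam_at + 2L) <- "GG"
      } else {
        fend <- base_pos + p - 1L
        fstart <- fend - 22L
        if (fstart < 1L || fend > L)
          stop("infeasible PAM placement for planted site")
        substr(seqc, fstart, fstart + 1L) <- "CC"  # revcomp NGG
      }
      ## re-check introns untouched at their dinucleotides
      gene <- GeneModel(id, seqc, cds, cds = cds, strand = "+")
      sites2 <- findSpliceSites(gene)
      if (nrow(sites2) != nrow(sites))
        stop("infeasible PAM placement: splice dinucleotide overwritten")
      sites <- sites2
      pam_plant <- list(site = plant_pam$site, base_locus_pos = base_pos,
                        protospacer_position = p, strand = strand,
                        frame_start = fstart)
    }

    codon_tab <- {
      cdsp2 <- cdsPositions(gene)
      nc <- length(cdsp2) %/% 3L
      data.frame(
        index = seq_len(nc),
        codon = vapply(seq_len(nc), function(ci) {
          idx <- cdsp2[((ci - 1L) * 3L + 1L):(ci * 3L)]
          paste(substring(seqc, idx, idx), collapse = "")
        }, character(1)))
    }

    list(gene = gene,
         ledger = list(splice_sites = sites, codons = codon_tab,
                       ptc_codon_index = ptc_index, planted_pam = pam_plant,
                       seed = seed))
  })
}
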