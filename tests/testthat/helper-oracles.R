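## Independent brute-force oracles. These deliberately share no code with
## the package internals: plain character loops, explicit IUPAC table.

.ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_rc <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_iupac_ok <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  all(mapply(function(s, p) s %in% .ORACLE_IUPAC[[p]], sc, pc))
}

## exhaustive protospacer+PAM frame scan, both strands
oracle_scan <- function(seqc, pam = "NGG") {
  L <- nchar(seqc)
  rows <- list()
  if (L >= 23L) {
    for (i in 1:(L - 22L)) {
      frame <- substr(seqc, i, i + 22L)
      if (grepl("N", frame, fixed = TRUE)) next
      if (oracle_iupac_ok(substr(frame, 21L, 23L), pam))
        rows[[length(rows) + 1L]] <- data.frame(
          protospacer = substr(frame, 1L, 20L),
          pam = substr(frame, 21L, 23L),
          start = i, end = i + 22L, strand = "+")
      fr <- oracle_rc(frame)
      if (oracle_iupac_ok(substr(fr, 21L, 23L), pam))
        rows[[length(rows) + 1L]] <- data.frame(
          protospacer = substr(fr, 1L, 20L),
          pam = substr(fr, 21L, 23L),
          start = i, end = i + 22L, strand = "-")
    }
  }
  if (length(rows) == 0L)
    return(data.frame(protospacer = character(), pam = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

## exhaustive off-target scan (Hamming, PAM excluded from distance)
oracle_offtargets <- function(seqc, proto, pam = "NGG", maxmm = 3L) {
  frames <- oracle_scan(seqc, pam)
  if (nrow(frames) == 0L) return(frames)
  q <- strsplit(proto, "")[[1]]
  mm <- vapply(strsplit(frames$protospacer, ""),
               function(s) sum(s != q), integer(1))
  out <- frames[mm <= maxmm, , drop = FALSE]
  out$mismatches <- mm[mm <= maxmm]
  out
}

## exhaustive codon-edit enumeration over strands x positions x products
oracle_codon_outcomes <- function(codon, source, products) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cb <- strsplit(codon, "")[[1]]
  rows <- list()
  for (i in 1:3) for (P in products) {
    if (cb[i] == source) {
      nc <- cb; nc[i] <- P
      rows[[length(rows) + 1L]] <- data.frame(
        codon_pos = i, strand = "sense", product = P,
        edited_codon = paste(nc, collapse = ""))
    }
    if (comp[[cb[i]]] == source) {
      nc <- cb; nc[i] <- comp[[P]]
      rows[[length(rows) + 1L]] <- data.frame(
        codon_pos = i, strand = "antisense", product = P,
        edited_codon = paste(nc, collapse = ""))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(codon_pos = integer(), strand = character(),
                      product = character(), edited_codon = character()))
  unique(do.call(rbind, rows))
}

## splice sites straight from the exon definition
oracle_splice_sites <- function(seqc, exon_starts, exon_ends) {
  n <- length(exon_starts)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    p <- exon_ends[i] + 1L
    if (substr(seqc, p, p + 1L) == "GT")
      rows[[length(rows) + 1L]] <- data.frame(kind = "donor",
                                              pos = c(p, p + 1L))
  }
  for (i in seq_len(n)[-1L]) {
    p <- exon_starts[i] - 2L
    if (substr(seqc, p, p + 1L) == "AG")
      rows[[length(rows) + 1L]] <- data.frame(kind = "acceptor",
                                              pos = c(p, p + 1L))
  }
  if (length(rows) == 0L) return(data.frame(kind = character(),
                                            pos = integer()))
  do.call(rbind, rows)
}

## exhaustive splice-disruption guide enumeration for one editor
oracle_splice_guides <- function(seqc, exon_starts, exon_ends,
                                 source, window_lo, window_hi, pam = "NGG") {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sites <- oracle_splice_sites(seqc, exon_starts, exon_ends)
  frames <- oracle_scan(seqc, pam)
  rows <- list()
  if (nrow(sites) == 0L || nrow(frames) == 0L) {
    return(data.frame(protospacer = character(), start = integer(),
                      end = integer(), strand = character(),
                      position = integer(), locus_pos = integer()))
  }
  for (s in seq_len(nrow(sites))) {
    pos <- sites$pos[s]
    for (f in seq_len(nrow(frames))) {
      fr <- frames[f, ]
      p <- if (fr$strand == "+") pos - fr$start + 1L else fr$end - pos + 1L
      if (p < 1L || p > 20L) next
      b <- substr(seqc, pos, pos)
      if (fr$strand == "-") b <- comp[[b]]
      if (b == source && p >= window_lo && p <= window_hi)
        rows[[length(rows) + 1L]] <- data.frame(
          protospacer = fr$protospacer, start = fr$start, end = fr$end,
          strand = fr$strand, position = p, locus_pos = pos)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(protospacer = character(), start = integer(),
                      end = integer(), strand = character(),
                      position = integer(), locus_pos = integer()))
  unique(do.call(rbind, rows))
}

## direct per-column counting, valid for gapless equal-length reads
oracle_column_counts <- function(reads, refc) {
  L <- nchar(refc)
  m <- do.call(rbind, strsplit(reads, ""))
  out <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(c("A","C","G","T"),
                                                         NULL))
  for (b in rownames(out)) out[b, ] <- colSums(m == b)
  out
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

## sort candidate/frame tables into a canonical order for comparison
canon <- function(df, cols) {
  df <- unique(df[, cols, drop = FALSE])
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## exhaustive PTC-introduction guide enumeration for one editor
oracle_ptc_guides <- function(seqc, cds_starts, cds_ends, source, products,
                              window_lo, window_hi, pam = "NGG") {
  stops <- c("TAA", "TAG", "TGA")
  cdsp <- unlist(mapply(function(s, e) s:e, cds_starts, cds_ends,
                        SIMPLIFY = FALSE))
  n_codons <- length(cdsp) %/% 3L
  frames <- oracle_scan(seqc, pam)
  rows <- list()
  for (ci in seq_len(n_codons)) {
    if (ci == 1L || ci == n_codons) next
    idx <- cdsp[((ci - 1L) * 3L + 1L):(ci * 3L)]
    codon <- paste(substring(seqc, idx, idx), collapse = "")
    if (codon %in% stops) next
    outs <- oracle_codon_outcomes(codon, source, products)
    if (nrow(outs) == 0L || nrow(frames) == 0L) next
    outs <- outs[outs$edited_codon %in% stops, , drop = FALSE]
    for (o in seq_len(nrow(outs))) {
      oc <- outs[o, ]
      locus_pos <- idx[oc$codon_pos]
      want_strand <- if (oc$strand == "sense") "+" else "-"
      fsub <- frames[frames$strand == want_strand, , drop = FALSE]
      for (f in seq_len(nrow(fsub))) {
        fr <- fsub[f, ]
        p <- if (fr$strand == "+") locus_pos - fr$start + 1L
             else fr$end - locus_pos + 1L
        if (p < 1L || p > 20L) next
        if (p >= window_lo && p <= window_hi)
          rows[[length(rows) + 1L]] <- data.frame(
            protospacer = fr$protospacer, start = fr$start, end = fr$end,
            strand = fr$strand, position = p, locus_pos = locus_pos,
            edited_codon = oc$edited_codon)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(protospacer = character(), start = integer(),
                      end = integer(), strand = character(),
                      position = integer(), locus_pos = integer(),
                      edited_codon = character()))
  unique(do.call(rbind, rows))
}
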