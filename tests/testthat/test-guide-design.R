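reg <- builtinEditors()

test_that("protospacer scan matches the exhaustive oracle and handles edge cases", {
  ## single frame, + strand only
  s <- paste0(paste(rep("A", 20), collapse = ""), "AGG")
  hits <- scanProtospacers(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$pam, "AGG")
  ## no G anywhere: NGG cannot match either strand
  expect_equal(nrow(scanProtospacers(paste(rep("A", 30), collapse = ""))), 0L)
  ## too short
  expect_equal(nrow(scanProtospacers("ACGTACGT")), 0L)
  ## frames containing N are excluded
  sN <- paste0(paste(rep("A", 10), collapse = ""), "N",
               paste(rep("A", 9), collapse = ""), "AGG")
  expect_equal(nrow(scanProtospacers(sN)), 0L)
  expect_error(scanProtospacers(s, pam = "NQZ"), "IUPAC")

  ## random sequences vs brute force, NGG and NGN
  for (seed in 1:5) {
    set.seed(seed)
    seqc <- random_dna(200)
    for (pam in c("NGG", "NGN")) {
      got <- canon(scanProtospacers(seqc, pam),
                   c("protospacer", "pam", "start", "end", "strand"))
      want <- canon(oracle_scan(seqc, pam),
                    c("protospacer", "pam", "start", "end", "strand"))
      expect_equal(got, want, label = sprintf("seed %d pam %s", seed, pam))
    }
  }
})

test_that("splice sites are located at exon boundaries with canonical filtering", {
  ## 3-exon toy gene: exons 1-10, 21-30, 41-50; introns GT..AG
  seqc <- paste0("ATGCCCGGGC", "GT", "CCCCCC", "AG",
                 "CCCGGGCCCT", "GT", "CCCCCC", "AG", "CCCGGGTTAA")
  ex <- IRanges::IRanges(start = c(1, 21, 41), end = c(10, 30, 50))
  g <- GeneModel("toy", seqc, ex)
  sites <- findSpliceSites(g)
  expect_equal(nrow(sites), 4L)
  expect_equal(sites$kind[order(sites$pos1)], c("donor", "acceptor",
                                                "donor", "acceptor"))
  expect_equal(sort(sites$pos1), c(11L, 19L, 31L, 39L))
  expect_true(all(sites$canonical))

  ## GC donor in intron 1: flagged and excluded by default
  seqc2 <- seqc
  substr(seqc2, 12, 12) <- "C"
  g2 <- GeneModel("toy2", seqc2, ex)
  expect_equal(nrow(findSpliceSites(g2)), 3L)
  withnc <- findSpliceSites(g2, include_noncanonical = TRUE)
  expect_equal(nrow(withnc), 4L)
  expect_equal(withnc$dinucleotide[withnc$pos1 == 11], "GC")
  expect_false(withnc$canonical[withnc$pos1 == 11])

  ## single-exon gene: no splice sites
  g1 <- GeneModel("mono", "ATGCCCGGGTTTAAACCCGGG",
                  IRanges::IRanges(1, 21))
  expect_equal(nrow(findSpliceSites(g1)), 0L)
})

test_that("planted donor-T at position 5 is designable by gTBEv3 but a PAM-free locus is not", {
  ## place the donor T (locus 26) at protospacer position 5 of the + frame
  ## starting at 22: protospacer 22-41, PAM AGG at locus 42-44
  bg <- function(n) paste(rep("C", n), collapse = "")
  seqc <- paste0(bg(20), "ATCG", "GT", bg(15), "AGG", bg(3), "AG", bg(10))
  ## exon1: 1-24 (donor at 25-26); acceptor AG at 48-49, exon2 50-59
  ex <- IRanges::IRanges(start = c(1, 50), end = c(24, 59))
  g <- GeneModel("planted", seqc, ex)
  sites <- findSpliceSites(g)
  expect_equal(sites$pos1[sites$kind == "donor"], 25L)
  expect_equal(sites$pos1[sites$kind == "acceptor"], 48L)
  cand <- findSpliceSiteGuides(g, reg[["gTBEv3"]], "optimal")
  hit <- cand[cand$strand == "+" & cand$targeted_locus_pos == 26, ]
  expect_gte(nrow(hit), 1L)
  expect_equal(unique(hit$targeted_base), "T")
  expect_true(5 %in% hit$targeted_base_position)
  expect_equal(unique(hit$application), "SD_disruption")

  ## all-C background has no A on either protospacer strand near the sites
  ## at ABE window positions: the antisense of GT reads AC, but the A sits
  ## at position 6 on the minus-strand frame anchored by the same PAM --
  ## outside no frame here: verify against the oracle instead
  abe <- reg[["ABE"]]
  got <- findSpliceSiteGuides(g, abe, "optimal")
  want <- oracle_splice_guides(seqc, IRanges::start(ex), IRanges::end(ex),
                               "A", abe@window@optimal_start,
                               abe@window@optimal_end)
  expect_equal(nrow(got), nrow(want))

  ## PAM-free locus (A/T background cannot form NGG on either strand)
  seqc3 <- paste0(paste(rep("AT", 15), collapse = ""), "GT",
                  paste(rep("TA", 10), collapse = ""), "AG",
                  paste(rep("AT", 15), collapse = ""))
  ex3 <- IRanges::IRanges(start = c(1, 55), end = c(30, 84))
  g3 <- GeneModel("pamfree", seqc3, ex3)
  expect_equal(nrow(findSpliceSiteGuides(g3, reg[["gTBEv3"]], "editable")), 0L)
})

test_that("splice guide designer agrees exactly with the brute-force oracle on random loci", {
  editors <- list(reg[["gTBEv3"]], reg[["gCBEv2"]], reg[["ABE"]],
                  reg[["gGBE"]])
  for (seed in 1:8) {
    gm <- simulateGeneModel(n_exons = 3L, seed = 1000 + seed)
    g <- gm$gene
    seqc <- as.character(geneSequence(g))
    ex <- geneExons(g)
    for (e in editors) {
      for (mode in c("optimal", "editable")) {
        w <- e@window
        lo <- if (mode == "optimal") w@optimal_start else w@editable_start
        hi <- if (mode == "optimal") w@optimal_end else w@editable_end
        got <- findSpliceSiteGuides(g, e, mode)
        want <- oracle_splice_guides(seqc, IRanges::start(ex),
                                     IRanges::end(ex),
                                     e@conversion@source_base, lo, hi)
        cols_got <- canon(got, c("protospacer", "start", "end", "strand",
                                 "targeted_base_position",
                                 "targeted_locus_pos"))
        names(cols_got) <- c("protospacer", "start", "end", "strand",
                             "position", "locus_pos")
        expect_equal(cols_got,
                     canon(want, c("protospacer", "start", "end", "strand",
                                   "position", "locus_pos")),
                     label = sprintf("seed %d editor %s mode %s", seed,
                                     e@name, mode))
      }
    }
  }
})

test_that("every emitted candidate satisfies window and PAM predicates post hoc", {
  gm <- simulateGeneModel(n_exons = 4L, seed = 99)
  g <- gm$gene
  for (enm in c("gTBEv3", "gCBEv2", "CBE")) {
    e <- reg[[enm]]
    for (mode in c("optimal", "editable")) {
      cand <- findSpliceSiteGuides(g, e, mode)
      if (nrow(cand) == 0L) next
      for (i in seq_len(nrow(cand))) {
        expect_true(canEdit(e, cand$targeted_base[i],
                            cand$targeted_base_position[i], mode))
        expect_true(oracle_iupac_ok(cand$pam[i], e@pam))
      }
    }
  }
})

test_that("widening the window from optimal to editable never removes candidates", {
  for (seed in 1:5) {
    gm <- simulateGeneModel(n_exons = 3L, seed = 200 + seed)
    for (enm in c("gTBEv3", "gCBEv2")) {
      opt <- findSpliceSiteGuides(gm$gene, reg[[enm]], "optimal")
      edi <- findSpliceSiteGuides(gm$gene, reg[[enm]], "editable")
      key <- function(d) paste(d$protospacer, d$start, d$strand,
                               d$targeted_locus_pos)
      expect_true(all(key(opt) %in% key(edi)),
                  label = sprintf("seed %d %s", seed, enm))
    }
  }
})

test_that("designing on the reverse complement mirrors candidates", {
  gm <- simulateGeneModel(n_exons = 3L, seed = 77)
  g <- gm$gene
  seqc <- as.character(geneSequence(g))
  L <- nchar(seqc)
  ex <- geneExons(g)
  ## the same gene handed over in minus-strand representation
  g_rc <- GeneModel("mirror", oracle_rc(seqc),
                    IRanges::IRanges(start = L - IRanges::end(ex) + 1L,
                                     end = L - IRanges::start(ex) + 1L),
                    strand = "-")
  for (enm in c("gTBEv3", "ABE")) {
    a <- findSpliceSiteGuides(g, reg[[enm]], "editable")
    b <- findSpliceSiteGuides(g_rc, reg[[enm]], "editable")
    ## GeneModel flips minus-strand input back to the coding strand, so
    ## the candidate tables must be identical up to ordering
    expect_equal(canon(a, c("protospacer", "start", "end", "strand",
                            "targeted_locus_pos")),
                 canon(b, c("protospacer", "start", "end", "strand",
                            "targeted_locus_pos")),
                 label = enm)
  }
})

test_that("codon edit outcomes match the brute-force enumerator for all 64 codons x all editors", {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  for (enm in names(reg)) {
    e <- reg[[enm]]
    for (codon in codons) {
      got <- codonEditOutcomes(codon, e)
      want <- oracle_codon_outcomes(codon, e@conversion@source_base,
                                    e@conversion@predominant)
      expect_equal(canon(got, c("codon_pos", "strand", "product",
                                "edited_codon")),
                   canon(want, c("codon_pos", "strand", "product",
                                 "edited_codon")),
                   label = paste(enm, codon))
      ## translations are consistent
      if (nrow(got))
        expect_equal(got$is_stop, got$edited_codon %in% c("TAA","TAG","TGA"))
    }
  }
})

test_that("stop-codon logic reproduces the known gTBE/gGBE codon targets", {
  gtbe <- reg[["gTBEv3"]]; ggbe <- reg[["gGBE"]]
  ## TAG edited by gTBE at sense position 1 gives CAG and GAG
  out <- codonEditOutcomes("TAG", gtbe)
  sense1 <- out[out$strand == "sense" & out$codon_pos == 1L, ]
  expect_setequal(sense1$edited_codon, c("CAG", "GAG"))
  expect_true(all(c("CAG", "GAG") %in% out$edited_codon))
  ## TAC is a stop-producing gGBE target via the antisense G
  out_tac <- codonEditOutcomes("TAC", ggbe)
  expect_setequal(out_tac$edited_codon[out_tac$is_stop], c("TAA", "TAG"))
  ## TCA likewise
  out_tca <- codonEditOutcomes("TCA", ggbe)
  expect_setequal(out_tca$edited_codon[out_tca$is_stop], c("TGA", "TAA"))
  expect_error(codonEditOutcomes("TAX", gtbe), "A/C/G/T")
})

test_that("PTC introduction requires a CDS, a stop-producing edit, window and PAM", {
  gm <- simulateGeneModel(n_exons = 2L, seed = 5)
  g <- gm$gene
  nocds <- GeneModel("nocds", as.character(geneSequence(g)), geneExons(g))
  expect_error(findPtcIntroductionGuides(nocds, reg[["CBE"]]), "no CDS")

  ## oracle comparison over simulated genes and two editors
  for (seed in c(21, 22, 23)) {
    gm <- simulateGeneModel(n_exons = 3L, seed = seed)
    g <- gm$gene
    seqc <- as.character(geneSequence(g))
    for (enm in c("gGBE", "CBE")) {
      e <- reg[[enm]]
      got <- findPtcIntroductionGuides(g, e, "editable")
      if (nrow(got)) {
        expect_true(all(got$edited_codon %in% c("TAA", "TAG", "TGA")))
        expect_false(any(got$codon %in% c("TAA", "TAG", "TGA")))
        ## recheck each emitted row independently
        for (i in seq_len(nrow(got))) {
          b <- substr(seqc, got$targeted_locus_pos[i],
                      got$targeted_locus_pos[i])
          if (got$strand[i] == "-") b <- oracle_rc(b)
          expect_equal(b, e@conversion@source_base)
          expect_true(canEdit(e, b, got$targeted_base_position[i],
                              "editable"))
        }
      }
    }
  }
})

test_that("PTC introduction finds planted TGG targeted by CBE through the antisense CCA", {
  ## TGG codon: antisense reads CCA; CBE C->T on antisense gives TAG/TGA.
  ## Build CDS  ATG | TGG | ... with a CCN PAM (revcomp NGG) placed so the
  ## edited C sits in CBE's editable window on the minus strand.
  ## minus-strand frame: start..end, protospacer position p at locus end-p+1.
  ## put codon TGG at locus 31-33; want antisense C (locus 32, say) at p=5
  ## -> end = 32+5-1 = 36, start = 14; PAM CC at 14-15.
  bg <- function(n) paste(rep("A", n), collapse = "")
  seqc <- paste0(bg(10), "ATG", "CC", bg(15), "T", "TGG", bg(12), "TAA",
                 bg(10))
  ## CDS: 11-13 (ATG), then contiguous through TAA; single exon
  cds_end <- regexpr("TAA", seqc, fixed = TRUE)[1] + 2L
  ex <- IRanges::IRanges(1, nchar(seqc))
  cds <- IRanges::IRanges(11, cds_end)
  g <- GeneModel("tgg", seqc, ex, cds = cds)
  got <- findPtcIntroductionGuides(g, reg[["CBE"]], "editable")
  tgg_rows <- got[got$codon == "TGG", ]
  if (nrow(tgg_rows) > 0L) {
    expect_true(all(tgg_rows$strand == "-"))
    expect_true(all(tgg_rows$edited_codon %in% c("TAG", "TGA")))
  }
  ## regardless of PAM fortuity, the designer must agree with a direct
  ## re-derivation from codonEditOutcomes + scanProtospacers
  frames <- scanProtospacers(seqc, "NGG")
  expect_true(all(got$protospacer %in% frames$protospacer))
})

test_that("PTC bypass lists only sense-codon outcomes and validates its input", {
  ## single-exon gene with PTC TAG at codon 3
  seqc <- paste0("ATG", "AAA", "TAG", "GGG", "CCC", "TAA",
                 paste(rep("G", 24), collapse = ""))
  g <- GeneModel("ptc", seqc, IRanges::IRanges(1, nchar(seqc)),
                 cds = IRanges::IRanges(1, 18))
  expect_error(findPtcBypassGuides(g, 2, reg[["gTBEv3"]]), "not a stop")
  cand <- findPtcBypassGuides(g, 3, reg[["gTBEv3"]], "editable")
  if (nrow(cand)) {
    expect_true(all(!cand$edited_codon %in% c("TAA", "TAG", "TGA")))
    expect_true(all(cand$application == "PTC_bypass"))
    expect_true(all(cand$edited_codon %in% c("CAG", "GAG", "TAC", "TAT",
                                             "TCG", "TGG")))
  }
  ## gTBE on TAG position 1 must reach CAG (Gln) and GAG (Glu) outcomes
  out <- codonEditOutcomes("TAG", reg[["gTBEv3"]])
  keep <- out[!out$is_stop, ]
  expect_true(all(c("CAG", "GAG") %in% keep$edited_codon))
  expect_equal(sort(unique(keep$aa[keep$edited_codon %in% c("CAG", "GAG")])),
               c("E", "Q"))
  ## an editor with no applicable base in any window frame yields nothing:
  ## TGA has no C on either strand for a gCBE... (antisense TCA has C);
  ## use ABE on TAG where no sense codon is reachable within this locus
  cand2 <- findPtcBypassGuides(g, 3, reg[["ABE"]], "optimal")
  expect_true(all(!cand2$edited_codon %in% c("TAA", "TAG", "TGA")))
})

test_that("cross-editor Venn partition matches brute-force set algebra", {
  ## identical sets
  ids <- paste0("c", 1:5)
  v <- classifyAcrossEditors(list(A = ids, B = ids))
  expect_equal(v$union_size, 5L)
  expect_equal(unname(v$region_counts[["A&B"]]), 5L)
  expect_equal(unname(v$exclusive[["A"]]), 0L)
  ## disjoint sets
  v2 <- classifyAcrossEditors(list(A = paste0("x", 1:3),
                                   B = paste0("y", 1:4)))
  expect_equal(v2$union_size, 7L)
  expect_equal(unname(v2$region_counts[["A&B"]]), 0L)
  expect_equal(unname(v2$exclusive[["A"]]), 3L)
  expect_equal(unname(v2$exclusive[["B"]]), 4L)
  ## random sets vs brute force
  for (seed in 1:5) {
    set.seed(seed)
    univ <- paste0("id", 1:40)
    sets <- lapply(1:4, function(i) sample(univ, sample(5:25, 1)))
    names(sets) <- c("ABE", "CBE", "gGBE", "gTBE")
    v3 <- classifyAcrossEditors(sets)
    expect_equal(v3$union_size, length(unique(unlist(sets))))
    expect_equal(sum(v3$region_counts), v3$union_size)
    expect_true(all(v3$region_counts >= 0L))
    ## pairwise overlap check vs direct intersection
    inter_ab <- length(intersect(sets$ABE, sets$gGBE))
    in_both <- sum(v3$region_counts[grepl("ABE", names(v3$region_counts)) &
                                    grepl("gGBE", names(v3$region_counts))])
    expect_equal(in_both, inter_ab)
    ## exclusives vs direct set difference
    only_gtbe <- length(setdiff(sets$gTBE,
                                unlist(sets[c("ABE", "CBE", "gGBE")])))
    expect_equal(unname(v3$exclusive[["gTBE"]]), only_gtbe)
  }
})

test_that("reporter restoration requires matching chemistry with a G product", {
  expect_true(predictReporterRestoration("AT", reg[["gTBEv3"]]))
  expect_true(predictReporterRestoration("AC", reg[["gCBEv2"]]))
  expect_false(predictReporterRestoration("AT", reg[["gCBEv2"]]))
  expect_false(predictReporterRestoration("AC", reg[["gTBEv3"]]))
  expect_false(predictReporterRestoration("AC", reg[["CBE"]]))  # C->T only
  expect_false(predictReporterRestoration("AG", reg[["gTBEv3"]]))
  ## position outside any guide
  expect_error(predictReporterRestoration("AT", reg[["gTBEv3"]],
                                          position = 25), "cover")
  ## position outside the editable window
  expect_false(predictReporterRestoration("AT", reg[["gTBEv3"]],
                                          position = 15))
})

test_that("off-target scan equals the exhaustive oracle", {
  set.seed(31)
  genome <- random_dna(5000)
  ## plant an exact site
  proto <- "ACGTACGTACGTACGTACGT"
  site <- paste0(proto, "TGG")
  substr(genome, 1001, 1023) <- site
  hits <- findOffTargets(genome, proto, max_mismatches = 0L)
  expect_true(any(hits$start == 1001 & hits$strand == "+" &
                  hits$mismatches == 0L))
  ## absent site at 0 mismatches
  expect_equal(nrow(findOffTargets(paste(rep("A", 100), collapse = ""),
                                   proto, max_mismatches = 0L)), 0L)
  ## full equality with the oracle at max 3
  got <- canon(findOffTargets(genome, proto, max_mismatches = 3L),
               c("start", "end", "strand", "protospacer", "mismatches"))
  want <- canon(oracle_offtargets(genome, proto, maxmm = 3L),
                c("start", "end", "strand", "protospacer", "mismatches"))
  expect_equal(got, want)
})
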