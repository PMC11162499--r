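#' Run a simulate / design / quantify pipeline stage chain
#'
#' Executes the configured subcommand chain and writes all artifacts plus a
#' reproducibility manifest (JSON: config, derived seeds, package version)
#' into \code{out_dir}. All randomness derives deterministically from the
#' single top-level \code{seed}, fanned out per stage, so identical config
#' and seed reproduce outputs byte-identically. Results go to files;
#' progress messages go to stderr.
#'
#' Supported stages:
#' \describe{
#'   \item{simulate}{simulate a gene model (FASTA + GFF3 + ledger JSON)
#'     and, if \code{sim$reads} is set, amplicon reads (FASTQ).}
#'   \item{design-splice}{splice-site disruption candidates for the chosen
#'     editors (TSV + Venn JSON).}
#'   \item{design-ptc}{PTC-introduction candidates (TSV).}
#'   \item{offtarget-scan}{off-target table for a query protospacer (TSV).}
#'   \item{quantify}{editing-outcome summary of FASTQ reads against an
#'     amplicon reference (TSV frequency matrix + JSON summary).}
#' }
#'
#' @param config nested list; see the examples and the package vignette.
#'   Common fields: \code{stages} (character vector of stage names),
#'   \code{editors} (names resolved in the registry), \code{mode},
#'   \code{pam}, \code{sim} (gene/read simulation parameters),
#'   \code{quantify} (reads/reference/protospacer), \code{offtarget}
#'   (protospacer/max_mismatches).
#' @param out_dir output directory (created if needed).
#' @param seed top-level seed.
#' @param registry editor registry (default \code{builtinEditors()}).
#' @return named list of written file paths plus the in-memory stage
#'   results, invisibly.
#' @export
runPipeline <- function(config, out_dir, seed = 1L,
                        registry = builtinEditors()) {
  stopifnot(is.list(config), length(config$stages) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (ed in config$editors %||% character())
    registry[[ed]]  # errors early on unknown editor names
  paths <- list(); results <- list()
  gene <- NULL; gene_ledger <- NULL

  for (stage in config$stages) {
    message("[gbekit] stage: ", stage)
    sseed <- deriveSeed(seed, stage)
    if (stage == "simulate") {
      sim <- config$sim %||% list()
      gm <- simulateGeneModel(
        n_exons = sim$n_exons %||% 3L,
        plant_ptc = isTRUE(sim$plant_ptc),
        plant_pam = sim$plant_pam,
        seed = sseed, id = sim$id %||% "synthgene")
      gene <- gm$gene; gene_ledger <- gm$ledger
      fa <- file.path(out_dir, "locus.fasta")
      writeFasta(setNames(Biostrings::DNAStringSet(as.character(
        geneSequence(gene))), geneId(gene)), fa)
      gff <- file.path(out_dir, "locus.gff3")
      writeGff3Gene(gene, gff)
      lj <- file.path(out_dir, "sim_ledger.json")
      jsonlite::write_json(list(
        splice_sites = gene_ledger$splice_sites,
        ptc_codon_index = gene_ledger$ptc_codon_index,
        seed = sseed), lj, auto_unbox = TRUE, digits = NA, na = "null")
      paths[c("locus_fasta", "locus_gff3", "sim_ledger")] <- c(fa, gff, lj)
      if (!is.null(sim$reads)) {
        rs <- sim$reads
        model <- OutcomeModel(rs$reference, rs$protospacer,
                              sub_probs = rs$sub_probs %||% list(),
                              indel_probability = rs$indel_probability %||% 0,
                              error_rate = rs$error_rate %||% 0,
                              seed = deriveSeed(seed, "simulate-reads"))
        simr <- simulateAmpliconReads(model, rs$n %||% 1000L)
        fq <- file.path(out_dir, "reads.fastq")
        writeFastq(simr$reads, fq)
        paths$reads_fastq <- fq
        results$read_model <- model
      }
      results$gene <- gene; results$sim_ledger <- gene_ledger
    } else if (stage == "design-splice") {
      if (is.null(gene)) gene <- .pipeline_load_gene(config)
      eds <- config$editors %||% c("gTBEv3", "gCBEv2", "ABE", "CBE")
      mode <- config$mode %||% "optimal"
      sets <- lapply(eds, function(e)
        findSpliceSiteGuides(gene, registry[[e]], mode))
      names(sets) <- eds
      cand <- do.call(rbind, sets)
      tsv <- file.path(out_dir, "splice_candidates.tsv")
      writeCandidateTsv(cand, tsv)
      venn <- classifyAcrossEditors(sets)
      vj <- file.path(out_dir, "splice_venn.json")
      jsonlite::write_json(list(region_counts = as.list(venn$region_counts),
                                union_size = venn$union_size),
                           vj, auto_unbox = TRUE, digits = NA)
      paths[c("splice_tsv", "venn_json")] <- c(tsv, vj)
      results$splice_candidates <- cand; results$venn <- venn
    } else if (stage == "design-ptc") {
      if (is.null(gene)) gene <- .pipeline_load_gene(config)
      eds <- config$editors %||% c("gGBE", "CBE")
      mode <- config$mode %||% "optimal"
      cand <- do.call(rbind, lapply(eds, function(e)
        findPtcIntroductionGuides(gene, registry[[e]], mode)))
      tsv <- file.path(out_dir, "ptc_candidates.tsv")
      writeCandidateTsv(cand, tsv)
      paths$ptc_tsv <- tsv
      results$ptc_candidates <- cand
    } else if (stage == "offtarget-scan") {
      ot <- config$offtarget
      if (is.null(ot$protospacer)) stop("offtarget-scan needs a protospacer")
      genome <- if (!is.null(ot$genome_fasta))
        as.character(readFasta(ot$genome_fasta)[[1]])
      else as.character(geneSequence(gene))
      hits <- findOffTargets(genome, ot$protospacer,
                             pam = config$pam %||% "NGG",
                             max_mismatches = ot$max_mismatches %||% 3L)
      tsv <- file.path(out_dir, "offtargets.tsv")
      write.table(hits, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      paths$offtarget_tsv <- tsv
      results$offtargets <- hits
    } else if (stage == "quantify") {
      q <- config$quantify %||% list()
      reads <- if (!is.null(q$fastq)) readFastq(q$fastq)
               else if (!is.null(paths$reads_fastq)) readFastq(paths$reads_fastq)
               else stop("quantify stage needs reads")
      reference <- q$reference %||% as.character(results$read_model@reference)
      protospacer <- q$protospacer %||%
        c(results$read_model@protospacer_start,
          results$read_model@protospacer_end)
      tab <- quantifyAmplicon(reads, reference, protospacer)
      summ <- summarizeEditing(tab, source_base = q$source_base %||% "T")
      freq <- data.frame(position = 1:20,
                         conv_without_indels = summ$conv_without,
                         conv_with_indels = summ$conv_with)
      tsv <- file.path(out_dir, "conversion_frequencies.tsv")
      fr <- freq; fr[is.na(fr)] <- "."
      write.table(fr, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      sj <- file.path(out_dir, "editing_summary.json")
      jsonlite::write_json(list(
        peak_position = summ$peak_position,
        indel_frequency = summ$indel_frequency,
        purity = summ$purity, ts_ratio = summ$ts_ratio,
        n_reads = tab@n_reads_total), sj, auto_unbox = TRUE, digits = NA,
        na = "null")
      paths[c("frequencies_tsv", "summary_json")] <- c(tsv, sj)
      results$outcome_table <- tab; results$summary <- summ
    } else {
      stop("unknown pipeline stage: ", stage)
    }
  }

  manifest <- list(config = config, seed = seed,
                   stage_seeds = setNames(
                     lapply(config$stages, function(s) deriveSeed(seed, s)),
                     config$stages),
                   gbekit_version = as.character(packageVersion("gbekit")))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  paths$manifest <- mf
  invisible(c(paths, list(results = results)))
}

.pipeline_load_gene <- function(config) {
  if (is.null(config$gff3) || is.null(config$fasta))
    stop("design stages need either a prior simulate stage or gff3+fasta paths")
  genes <- readGff3Genes(config$gff3, config$fasta)
  genes[[1]]
}
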