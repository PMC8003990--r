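#' Default pipeline thresholds
#'
#' Every threshold of the candidate funnel in one place: minimum transcript
#' length (200 nt), expression cutoff (1 FPKM), minimum ORF length (50 aa),
#' expected-count level of the dynamic ORF cutoff (alpha 0.05), protein
#' homology cutoff (50 bits), sequence-conservation identity/length
#' (80 percent / 100 bp, strict), TSI threshold (0.8, inclusive), synteny
#' anchor distance (100 kb), human expression (1 TPM in 1 sample), and DE
#' significance (q < 0.05).
#'
#' @return Named list of thresholds.
#' @export
pipeline_config <- function() {
  list(min_len = 200, min_fpkm = 1.0, min_aa = 50L, alpha = 0.05,
       min_bits = 50.0, min_identity = 80, min_aln_length = 100,
       tsi_threshold = 0.8, max_anchor_distance = 1e5,
       human_min_tpm = 1.0, human_min_samples = 1L, fdr = 0.05,
       scrna_min_cells = 3L)
}

#' Run the full candidate pipeline on a fixture-style input bundle
#'
#' Executes every stage against the file layout written by
#' [generate_fixture()]: candidate selection, coding-potential
#' classification, known/novel status, tissue specificity, sequence and
#' synteny conservation with human-expression verification, per-locus
#' differential expression in the three disease models, single-cell
#' validation, and the integration funnel at transcript and locus level.
#'
#' @param dir input directory (see [generate_fixture()] for the layout).
#' @param config thresholds from [pipeline_config()].
#' @param verbose print per-stage record counts.
#' @return List with per-stage tables: `candidates`, `verdicts`, `novelty`,
#'   `tsi`, `seq_pairs`, `syn_pairs`, `de` (per model), `coherence`,
#'   `scrna`, `records`, `funnel`, `locus_records`, `locus_funnel`, `loci`.
#' @export
run_pipeline <- function(dir, config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ref <- read_gtf(file.path(dir, "mouse_reference.gtf"))
  asm <- read_gtf(file.path(dir, "mouse_assembled.gtf"))
  expr <- read_expression_table(file.path(dir, "expression_fpkm.tsv"),
                                file.path(dir, "expression_samples.tsv"))
  say("loaded %d assembled / %d reference transcripts",
      nrow(asm$transcripts), nrow(ref$transcripts))

  ## stage 1: length + expression selection
  cand <- select_candidates(asm, expr, min_len = config$min_len,
                            min_fpkm = config$min_fpkm)
  say("candidates after length/expression filter: %d", length(cand))

  ## stage 2: coding potential
  seqs <- read_transcript_fasta(file.path(dir, "mouse_transcripts.fa"))
  prot <- read_blast6(file.path(dir, "protein_hits.tsv"))
  hex <- read_hexamer_model(file.path(dir, "hexamer_model.tsv"))
  pssm <- read_start_pssm(file.path(dir, "start_pssm.tsv"))
  verdicts <- classify_coding(seqs, hits = prot, alpha = config$alpha,
                              min_bits = config$min_bits,
                              min_aa = config$min_aa,
                              hexamer_model = hex, start_pssm = pssm)
  noncoding_ids <- verdicts$transcript_id[verdicts$verdict == "noncoding"]
  say("noncoding verdicts: %d of %d", length(noncoding_ids), nrow(verdicts))

  ## stage 3: known vs novel
  novelty <- classify_transcripts(asm, ref)

  ## stage 4: tissue specificity
  tsi <- compute_tsi(expr, threshold = config$tsi_threshold)
  pod_expr <- apply(expr$values[, expr$compartment == "podocyte",
                                drop = FALSE], 1, max) >= config$min_fpkm
  pod_set <- podocyte_specific_set(tsi, threshold = config$tsi_threshold)
  say("TSI-specific podocyte features: %d", length(pod_set))

  ## stage 5: conservation
  aln <- read_blast6(file.path(dir, "lnc_alignments.tsv"))
  seq_pairs <- sequence_conservation(alignments = aln,
                                     min_identity = config$min_identity,
                                     min_length = config$min_aln_length)
  human <- read_gtf(file.path(dir, "human_annotation.gtf"))
  tx2gene <- stats::setNames(asm$transcripts$gene_id,
                             asm$transcripts$transcript_id)
  cand_nc <- intersect(cand, noncoding_ids)
  mouse_genes <- rbind(
    gene_table(subset_annotation(ref, ref$transcripts$biotype == "coding")),
    gene_table(subset_annotation(asm, asm$transcripts$transcript_id %in% cand_nc)))
  mouse_order <- gene_order(mouse_genes, species = "mouse")
  human_order <- gene_order(gene_table(human), species = "human")
  hom <- read_blast6(file.path(dir, "anchor_homology.tsv"))
  blocks <- align_gene_orders(mouse_order, human_order, hom,
                              match_bits = config$min_bits)
  lnc_genes <- unique(unname(tx2gene[cand_nc]))
  syn_pairs <- predict_synteny_orthologs(
    lnc_genes, blocks, mouse_order, human_order,
    max_anchor_distance = config$max_anchor_distance)
  htpm <- utils::read.delim(file.path(dir, "human_kidney_tpm.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  hmat <- as.matrix(htpm[, -1, drop = FALSE]); rownames(hmat) <- htpm[[1]]
  seq_pairs <- human_expression_check(seq_pairs, hmat,
                                      min_tpm = config$human_min_tpm,
                                      min_samples = config$human_min_samples)
  syn_pairs <- human_expression_check(syn_pairs, hmat,
                                      min_tpm = config$human_min_tpm,
                                      min_samples = config$human_min_samples)
  say("conserved pairs: %d by sequence, %d by synteny",
      nrow(seq_pairs), nrow(syn_pairs))

  ## stage 6: loci + differential expression
  loci <- bundle_loci(subset_annotation(asm, asm$transcripts$transcript_id
                                        %in% cand_nc))
  tx2loc <- locus_map(loci)
  sheet <- utils::read.delim(file.path(dir, "count_samples.tsv"),
                             stringsAsFactors = FALSE)
  de <- list(); coherence_input <- list()
  for (m in c("wt1", "podocin", "adriamycin")) {
    cm <- read_counts(file.path(dir, paste0("counts_", m, ".tsv")),
                      file.path(dir, "count_samples.tsv"))
    ss <- cm$samples
    keep <- rownames(cm$counts) %in% loci$locus_id
    counts <- cm$counts[keep, , drop = FALSE]
    if (m == "adriamycin") {
      res <- list(test_de(counts, ss, design = "one_factor", fdr = config$fdr))
    } else {
      two <- test_de(counts, ss, design = "two_factor", fdr = config$fdr)
      per_age <- lapply(unique(ss$age), function(a) {
        sel <- ss$age == a
        test_de(counts[, sel, drop = FALSE], ss[sel, , drop = FALSE],
                design = "one_factor", fdr = config$fdr)
      })
      res <- c(list(two), per_age)
    }
    de[[m]] <- combine_contrasts(res)
    coherence_input[[m]] <- de[[m]]
    say("DE in %s: %d significant of %d loci", m,
        sum(de[[m]]$significant), nrow(de[[m]]))
  }
  coherence <- cross_model_summary(coherence_input)

  ## stage 7: single-cell validation
  sc <- read_10x_triplet(file.path(dir, "scrna"))
  labels <- label_podocytes(sc)
  lnc_in_sc <- intersect(unique(unname(tx2gene[cand_nc])), rownames(sc))
  scrna <- wilcoxon_specificity(sc, labels, gene_ids = lnc_in_sc,
                                min_cells = config$scrna_min_cells)
  say("scRNA: %d podocytes, %d lnc genes tested, %d detected",
      sum(labels == "podocyte"), nrow(scrna), sum(scrna$detected))

  ## stage 8: integration
  ids <- asm$transcripts$transcript_id
  g <- unname(tx2gene[ids])
  de_flag <- function(m) {
    sig <- de[[m]]$locus_id[de[[m]]$significant]
    unname(tx2loc[ids]) %in% sig
  }
  sc_row <- match(g, scrna$gene)
  records <- candidate_records(
    feature_id = ids, level = "transcript",
    expressed = ids %in% cand,
    novel = novelty[ids] == "novel",
    noncoding = ids %in% noncoding_ids,
    podocyte_expressed = unname(pod_expr[ids]),
    tsi_specific = ids %in% pod_set,
    seq_conserved = ids %in% seq_pairs$lnc_id,
    synteny_conserved = g %in% syn_pairs$lnc_id,
    homology_clean = !ids %in% apply_homology_filter(ids, prot,
                                                     min_bits = config$min_bits),
    human_expressed = ids %in% seq_pairs$lnc_id[seq_pairs$human_expressed] |
      g %in% syn_pairs$lnc_id[syn_pairs$human_expressed],
    de_wt1 = de_flag("wt1"),
    de_podocin = de_flag("podocin"),
    de_adriamycin = de_flag("adriamycin"),
    scrna_detected = !is.na(sc_row) & scrna$detected[ifelse(is.na(sc_row), 1L, sc_row)],
    scrna_podocyte_specific = !is.na(sc_row) &
      !is.na(scrna$q[ifelse(is.na(sc_row), 1L, sc_row)]) &
      scrna$q[ifelse(is.na(sc_row), 1L, sc_row)] < config$fdr)
  funnel <- build_funnel(records)

  in_locus <- records$feature_id %in% names(tx2loc)
  locus_records <- transcript_to_locus_rollup(records[in_locus, , drop = FALSE],
                                              tx2loc)
  locus_funnel <- build_funnel(locus_records)
  say("funnel tiers (transcripts): %s",
      paste(funnel$tiers$n, collapse = " -> "))

  list(candidates = cand, verdicts = verdicts, novelty = novelty, tsi = tsi,
       podocyte_specific = pod_set, seq_pairs = seq_pairs,
       syn_pairs = syn_pairs, blocks = blocks, de = de,
       coherence = coherence, scrna = scrna, labels = labels,
       records = records, funnel = funnel, loci = loci,
       locus_records = locus_records, locus_funnel = locus_funnel)
}

#' Subset an annotation set by transcript
#'
#' @param annot an `annotation_set`.
#' @param keep logical or character selection of transcripts.
#' @return The reduced `annotation_set`.
#' @export
subset_annotation <- function(annot, keep) {
  tx <- annot$transcripts
  if (is.logical(keep)) keep <- tx$transcript_id[keep]
  annotation_set(tx[tx$transcript_id %in% keep, , drop = FALSE],
                 annot$exons[annot$exons$transcript_id %in% keep, , drop = FALSE])
}
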