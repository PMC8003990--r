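## Seeded generator of a complete toy two-species dataset: every input the
## pipeline consumes, with known per-feature ground truth in a manifest.

#' Fixture generator configuration
#'
#' Study conditions of the synthetic dataset. Defaults give a toy genome
#' that runs in seconds: two "bulk" mouse chromosomes carrying most
#' lncRNAs, one chromosome with human-colinear anchors hosting the planted
#' syntenic orthologs, and one with scrambled anchor homology hosting the
#' rearranged decoys.
#'
#' @param n_lnc total assembled lncRNA candidate transcripts (default 400).
#' @param n_syntenic planted synteny-conserved lncRNAs (default 20).
#' @param n_decoy rearranged synteny decoys (default 20).
#' @param n_contaminant coding contaminants with planted ORFs (default 40).
#' @param n_seq_conserved planted sequence-conserved lncRNAs (default 40).
#' @param n_specific planted podocyte-specific lncRNAs (default 40).
#' @param n_unexpressed transcripts below the expression cutoff (default 20).
#' @param frac_known fraction of transcripts present in the reference
#'   annotation (default 0.7).
#' @param target_identity per-base identity of sequence-conserved ortholog
#'   pairs (default 0.85).
#' @param phi negative-binomial dispersion of the count matrices
#'   (default 0.1).
#' @param n_rep replicates per design cell (default 3).
#' @param contaminant_orf_aa range of planted ORF lengths (default 150-250).
#' @param n_pod_cells,n_other_cells single-cell counts (default 60 / 240).
#' @param n_exclusive planted podocyte-exclusive scRNA genes (default 10).
#' @return A named list of settings.
#' @export
fixture_config <- function(n_lnc = 400L, n_syntenic = 20L, n_decoy = 20L,
                           n_contaminant = 40L, n_seq_conserved = 40L,
                           n_specific = 40L, n_unexpressed = 20L,
                           frac_known = 0.7, target_identity = 0.85,
                           phi = 0.1, n_rep = 3L,
                           contaminant_orf_aa = c(150L, 250L),
                           n_pod_cells = 60L, n_other_cells = 240L,
                           n_exclusive = 10L) {
  cfg <- as.list(environment())
  n_bulk <- cfg$n_lnc - cfg$n_syntenic - cfg$n_decoy
  if (n_bulk < cfg$n_contaminant + cfg$n_unexpressed + cfg$n_specific)
    stop("infeasible fixture fractions: planted classes exceed n_lnc")
  if (cfg$n_syntenic > 20L || cfg$n_decoy > 20L)
    stop("at most 20 syntenic lncRNAs and 20 decoys (one per anchor gap)")
  cfg
}

## one pseudo-random stream per file type, all derived from the master seed
with_stream <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 20000003L) * 97L + k)
  expr
}

random_dna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

blast6_frame <- function(q, s, pident, len, mismatch, bitscore) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = mismatch, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = 1e-30, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

## codon table biased toward GC3-rich codons, stops excluded; gives planted
## ORFs a hexamer composition separable from random background
coding_codons <- function() {
  b <- c("A", "C", "G", "T")
  cods <- do.call(paste0, expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1])
  cods <- setdiff(cods, STOP_CODONS)
  w <- ifelse(substr(cods, 3, 3) %in% c("G", "C"), 3, 1)
  list(codons = cods, weights = w / sum(w))
}

#' Generate the synthetic fixture bundle
#'
#' Writes a complete toy dataset to `dir`: mouse reference and assembled
#' GTFs, transcript FASTA, human annotation and ortholog FASTA, anchor
#' (BLASTP-like) and lncRNA-alignment (BLASTN-like) outfmt-6 tables, a
#' protein-homology table, compartment FPKM tables, negative-binomial count
#' matrices for the three disease models, trained hexamer/start-PSSM
#' scoring models, a 10x-style MTX triplet, and `manifest.json` with the
#' full per-feature ground truth. Regeneration with the same seed is
#' byte-identical; each file type draws from its own random stream derived
#' from the master seed.
#'
#' @param dir output directory (created if absent).
#' @param seed master seed.
#' @param config a [fixture_config()] list.
#' @return The manifest, invisibly (list with `transcripts`, `loci`,
#'   `de`, `scrna`, `config`).
#' @export
generate_fixture <- function(dir, seed = 1L, config = fixture_config()) {
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "scrna"), showWarnings = FALSE)

  n_bulk <- cfg$n_lnc - cfg$n_syntenic - cfg$n_decoy

  ## ---- structure stream: genome layout, classes, exon structures -------
  layout <- with_stream(seed, 1L, {
    sp_bulk <- 110000L; alen <- 4000L
    anchors <- do.call(rbind, lapply(list(
      list(chrom = "mm1", n = 11L, sp = sp_bulk),
      list(chrom = "mm2", n = 11L, sp = sp_bulk),
      list(chrom = "mm3", n = 21L, sp = sp_bulk),
      list(chrom = "mm4", n = 21L, sp = sp_bulk)), function(ch) {
        data.frame(gene_id = sprintf("ANC_%s_%02d", ch$chrom, seq_len(ch$n)),
                   chrom = ch$chrom, start = ch$sp * seq_len(ch$n),
                   end = ch$sp * seq_len(ch$n) + alen - 1L,
                   strand = "+", biotype = "coding", stringsAsFactors = FALSE)
      }))

    ## transcript classes
    ids <- sprintf("MLNC_%04d", seq_len(cfg$n_lnc))
    class_chrom <- c(rep(NA_character_, n_bulk),
                     rep("mm3", cfg$n_syntenic), rep("mm4", cfg$n_decoy))
    is_syn <- class_chrom == "mm3" & !is.na(class_chrom)
    is_decoy <- class_chrom == "mm4" & !is.na(class_chrom)
    bulk_idx <- which(is.na(class_chrom))
    pool <- sample(bulk_idx)            # random partition of bulk transcripts
    contaminant <- pool[seq_len(cfg$n_contaminant)]
    pool <- setdiff(pool, contaminant)
    unexpressed <- pool[seq_len(cfg$n_unexpressed)]
    pool <- setdiff(pool, unexpressed)
    ## specific: 30 bulk + 10 syntenic; seq-conserved: 20 of the specific
    ## bulk + 20 other bulk
    spec_bulk <- pool[seq_len(cfg$n_specific - 10L)]
    specific <- c(spec_bulk, which(is_syn)[seq_len(10L)])
    pool2 <- setdiff(pool, spec_bulk)
    seq_cons <- c(spec_bulk[seq_len(min(20L, length(spec_bulk)))],
                  pool2[seq_len(cfg$n_seq_conserved -
                                  min(20L, length(spec_bulk)))])
    ## non-podocyte features: expressed but podocyte-poor
    pool3 <- setdiff(pool2, seq_cons)
    nonpod <- pool3[seq_len(40L)]

    ## genomic placement
    chrom <- character(cfg$n_lnc); slot_start <- integer(cfg$n_lnc)
    gap_w <- sp_bulk - alen
    slots_per_gap <- (gap_w - 1000L) %/% 3600L
    bulk_cap_per_chrom <- 10L * slots_per_gap
    for (k in seq_along(bulk_idx)) {
      j <- bulk_idx[k]
      if (k <= bulk_cap_per_chrom) { chrom[j] <- "mm1"; kk <- k }
      else { chrom[j] <- "mm2"; kk <- k - bulk_cap_per_chrom }
      gap <- (kk - 1L) %/% slots_per_gap + 1L
      slot <- (kk - 1L) %% slots_per_gap + 1L
      slot_start[j] <- sp_bulk * gap + alen + 500L + (slot - 1L) * 3600L
    }
    for (k in seq_len(cfg$n_syntenic)) {
      j <- which(is_syn)[k]
      chrom[j] <- "mm3"; slot_start[j] <- sp_bulk * k + alen + 2000L
    }
    for (k in seq_len(cfg$n_decoy)) {
      j <- which(is_decoy)[k]
      chrom[j] <- "mm4"; slot_start[j] <- sp_bulk * k + alen + 2000L
    }

    strand <- sample(c("+", "-"), cfg$n_lnc, replace = TRUE)
    known <- rep(FALSE, cfg$n_lnc)
    known[sample(cfg$n_lnc, round(cfg$frac_known * cfg$n_lnc))] <- TRUE

    ## exon structures
    orf_aa <- integer(cfg$n_lnc)
    spliced <- integer(cfg$n_lnc)
    exons <- vector("list", cfg$n_lnc)
    for (j in seq_len(cfg$n_lnc)) {
      if (j %in% contaminant) {
        orf_aa[j] <- sample(seq(cfg$contaminant_orf_aa[1],
                                cfg$contaminant_orf_aa[2]), 1L)
        spliced[j] <- 3L * (orf_aa[j] + 1L) + sample(100:200, 1L) +
          sample(100:200, 1L) + 3L
      } else spliced[j] <- sample(300:2800, 1L)
      ne <- sample(1:3, 1L)
      part <- if (ne == 1L) spliced[j] else {
        cuts <- sort(sample(seq(100L, spliced[j] - 100L), ne - 1L))
        diff(c(0L, cuts, spliced[j]))
      }
      st <- slot_start[j]
      ex <- data.frame(start = integer(ne), end = integer(ne))
      for (e in seq_len(ne)) {
        ex$start[e] <- st
        ex$end[e] <- st + part[e] - 1L
        st <- ex$end[e] + 200L          # 200-bp introns
      }
      exons[[j]] <- ex
    }
    list(anchors = anchors, ids = ids, chrom = chrom, strand = strand,
         exons = exons, spliced = spliced, orf_aa = orf_aa,
         known = known, contaminant = contaminant,
         unexpressed = unexpressed, specific = specific,
         seq_cons = seq_cons, nonpod = nonpod,
         syn = which(is_syn), decoy = which(is_decoy),
         syn_gap = match(which(is_syn), which(is_syn)),
         slots_per_gap = slots_per_gap)
  })

  n <- cfg$n_lnc
  truth <- data.frame(
    transcript_id = layout$ids,
    gene_id = sub("MLNC", "GLNC", layout$ids),
    chrom = layout$chrom, strand = layout$strand,
    spliced_length = layout$spliced,
    planted_orf_aa = ifelse(layout$orf_aa > 0, layout$orf_aa, NA_integer_),
    known = layout$known,
    coding = seq_len(n) %in% layout$contaminant,
    expressed = !(seq_len(n) %in% layout$unexpressed),
    podocyte_expressed = NA,
    specific = seq_len(n) %in% layout$specific,
    seq_conserved = seq_len(n) %in% layout$seq_cons,
    synteny_conserved = seq_len(n) %in% layout$syn,
    decoy = seq_len(n) %in% layout$decoy,
    stringsAsFactors = FALSE)
  truth$podocyte_expressed <- truth$expressed &
    !(seq_len(n) %in% layout$nonpod)

  ## ---- annotations -----------------------------------------------------
  anchors <- layout$anchors
  anchor_tx <- data.frame(
    transcript_id = paste0(anchors$gene_id, "_t1"),
    gene_id = anchors$gene_id, chrom = anchors$chrom,
    strand = anchors$strand, biotype = "coding", stringsAsFactors = FALSE)
  anchor_ex <- data.frame(transcript_id = anchor_tx$transcript_id,
                          start = anchors$start, end = anchors$end)
  lnc_tx <- data.frame(transcript_id = truth$transcript_id,
                       gene_id = truth$gene_id, chrom = truth$chrom,
                       strand = truth$strand, biotype = "noncoding",
                       stringsAsFactors = FALSE)
  lnc_ex <- do.call(rbind, lapply(seq_len(n), function(j)
    cbind(transcript_id = truth$transcript_id[j], layout$exons[[j]])))
  assembled <- annotation_set(lnc_tx, lnc_ex)

  ## reference: anchors + copies of known lncRNAs (terminal ends jittered
  ## on multi-exon transcripts; intron chains preserved)
  ref_rows <- which(truth$known)
  ref_tx <- lnc_tx[ref_rows, , drop = FALSE]
  ref_tx$transcript_id <- paste0("REF_", ref_tx$transcript_id)
  ref_tx$gene_id <- paste0("REF_", ref_tx$gene_id)
  ref_ex <- do.call(rbind, lapply(ref_rows, function(j) {
    ex <- layout$exons[[j]]
    if (nrow(ex) > 1L) {
      ex$start[1L] <- ex$start[1L] - 10L
      ex$end[nrow(ex)] <- ex$end[nrow(ex)] + 10L
    }
    cbind(transcript_id = paste0("REF_", truth$transcript_id[j]), ex)
  }))
  reference <- annotation_set(rbind(anchor_tx, ref_tx),
                              rbind(anchor_ex, ref_ex))
  write_gtf(reference, file.path(dir, "mouse_reference.gtf"))
  write_gtf(assembled, file.path(dir, "mouse_assembled.gtf"))

  ## ---- human annotation + anchor homology ------------------------------
  sp_h <- 250000L; alen <- 4000L
  h_anchors <- do.call(rbind, lapply(list(
    list(chrom = "hs3", n = 21L), list(chrom = "hs4", n = 21L)),
    function(ch) data.frame(
      gene_id = sprintf("HANC_%s_%02d", ch$chrom, seq_len(ch$n)),
      chrom = ch$chrom, start = sp_h * seq_len(ch$n),
      end = sp_h * seq_len(ch$n) + alen - 1L, strand = "+",
      biotype = "coding", stringsAsFactors = FALSE)))
  ## syntenic human ncRNAs: one per hs3 gap, 1 kb right of its anchor
  syn_orth <- sprintf("HLNC_SYN_%02d", seq_len(cfg$n_syntenic))
  syn_nc <- data.frame(gene_id = syn_orth, chrom = "hs3",
                       start = sp_h * seq_len(cfg$n_syntenic) + alen + 1000L,
                       end = sp_h * seq_len(cfg$n_syntenic) + alen + 2500L,
                       strand = "+", biotype = "noncoding",
                       stringsAsFactors = FALSE)
  ## decoy human ncRNAs next to hs4 anchors (never reachable via blocks)
  dec_orth <- sprintf("HLNC_DEC_%02d", seq_len(cfg$n_decoy))
  dec_nc <- data.frame(gene_id = dec_orth, chrom = "hs4",
                       start = sp_h * seq_len(cfg$n_decoy) + alen + 1000L,
                       end = sp_h * seq_len(cfg$n_decoy) + alen + 2500L,
                       strand = "+", biotype = "noncoding",
                       stringsAsFactors = FALSE)
  ## sequence-ortholog ncRNAs live on an anchor-free human chromosome
  seq_orth <- sprintf("HLNC_SEQ_%02d", seq_along(layout$seq_cons))
  seq_nc <- data.frame(gene_id = seq_orth, chrom = "hs1",
                       start = 50000L * seq_along(layout$seq_cons),
                       end = 50000L * seq_along(layout$seq_cons) + 1500L,
                       strand = "+", biotype = "noncoding",
                       stringsAsFactors = FALSE)
  h_genes <- rbind(h_anchors, syn_nc, dec_nc, seq_nc)
  h_tx <- data.frame(transcript_id = paste0(h_genes$gene_id, "_t1"),
                     gene_id = h_genes$gene_id, chrom = h_genes$chrom,
                     strand = h_genes$strand, biotype = h_genes$biotype,
                     stringsAsFactors = FALSE)
  h_ex <- data.frame(transcript_id = h_tx$transcript_id,
                     start = h_genes$start, end = h_genes$end)
  write_gtf(annotation_set(h_tx, h_ex), file.path(dir, "human_annotation.gtf"))

  ## anchor homology: mm3 colinear with hs3; mm4 scrambled against hs4
  ## (stride-8 permutation: no near-colinear run in either orientation);
  ## bulk-chromosome anchors have only sub-threshold hits
  perm <- ((seq_len(21L) - 1L) * 8L) %% 21L + 1L
  hom <- rbind(
    blast6_frame(sprintf("ANC_mm3_%02d", 1:21),
                 sprintf("HANC_hs3_%02d", 1:21), 95, 400, 20, 200),
    blast6_frame(sprintf("ANC_mm4_%02d", 1:21),
                 sprintf("HANC_hs4_%02d", perm), 95, 400, 20, 200),
    blast6_frame(sprintf("ANC_mm1_%02d", 1:11),
                 sprintf("HANC_hs3_%02d", 1:11), 30, 80, 50, 28))
  utils::write.table(hom, file.path(dir, "anchor_homology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  ## ---- sequences stream ------------------------------------------------
  seq_data <- with_stream(seed, 2L, {
    cod <- coding_codons()
    seqs <- character(n)
    start_ctx <- character(0)
    orf_seqs <- character(0)
    for (j in seq_len(n)) {
      if (truth$coding[j]) {
        aa <- layout$orf_aa[j]
        orf <- paste0("ATG",
                      paste(sample(cod$codons, aa - 1L, replace = TRUE,
                                   prob = cod$weights), collapse = ""),
                      sample(STOP_CODONS, 1L))
        rest <- layout$spliced[j] - nchar(orf) - 3L
        u5 <- sample(100:min(200, rest - 100), 1L)
        utr5 <- random_dna(u5)
        utr3 <- random_dna(rest - u5)
        ## in-frame stop guard so the planted ORF is not extended upstream
        seqs[j] <- paste0(utr5, "TAA", orf, utr3)
        ctx_start <- nchar(utr5) + 4L
        start_ctx <- c(start_ctx, substr(seqs[j], ctx_start - 6L, ctx_start + 4L))
        orf_seqs <- c(orf_seqs, orf)
      } else {
        seqs[j] <- random_dna(layout$spliced[j])
      }
    }
    names(seqs) <- truth$transcript_id
    ## sequence-conserved orthologs: copy with per-base substitution
    sub_rate <- 1 - cfg$target_identity
    h_seqs <- character(length(layout$seq_cons))
    n_sub <- integer(length(layout$seq_cons))
    for (k in seq_along(layout$seq_cons)) {
      s <- strsplit(seqs[[layout$seq_cons[k]]], "")[[1]]
      hit <- which(stats::runif(length(s)) < sub_rate)
      for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
      h_seqs[k] <- paste(s, collapse = "")
      n_sub[k] <- length(hit)
    }
    names(h_seqs) <- seq_orth
    bg <- vapply(seq_len(50L), function(i) random_dna(900L), character(1))
    list(seqs = seqs, h_seqs = h_seqs, n_sub = n_sub,
         start_ctx = start_ctx, orf_seqs = orf_seqs, bg = bg)
  })
  write_transcript_fasta(seq_data$seqs, file.path(dir, "mouse_transcripts.fa"))
  write_transcript_fasta(seq_data$h_seqs, file.path(dir, "human_transcripts.fa"))

  ## scoring models trained on the planted coding set vs random background
  hex <- train_hexamer_model(seq_data$orf_seqs, seq_data$bg)
  pssm <- train_start_pssm(seq_data$start_ctx)
  write_tsv(data.frame(hexamer = names(hex), log_odds = unname(hex)),
            file.path(dir, "hexamer_model.tsv"))
  pssm_df <- data.frame(base = rownames(pssm), pssm, check.names = FALSE)
  write_tsv(pssm_df, file.path(dir, "start_pssm.tsv"))

  ## lncRNA alignment table: realized identities of conserved pairs plus
  ## sub-threshold decoy alignments for a sample of other transcripts
  len_q <- layout$spliced[layout$seq_cons]
  aln <- blast6_frame(truth$transcript_id[layout$seq_cons], seq_orth,
                      round(100 * (1 - seq_data$n_sub / len_q), 2),
                      len_q, seq_data$n_sub, round(len_q * 1.2))
  other <- setdiff(which(!truth$coding), layout$seq_cons)[1:30]
  aln <- rbind(aln,
               blast6_frame(truth$transcript_id[other[1:15]],
                            rep(seq_orth[1:5], 3), 65, 300, 105, 90),
               blast6_frame(truth$transcript_id[other[16:30]],
                            rep(seq_orth[6:10], 3), 92, 80, 6, 60))
  utils::write.table(aln, file.path(dir, "lnc_alignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  ## protein homology (BLASTX-like): contaminants hit Swiss-Prot-style
  ## subjects above 50 bits; a few noncoding transcripts get weak hits
  weak <- setdiff(which(!truth$coding), layout$seq_cons)[31:50]
  prot <- rbind(
    blast6_frame(truth$transcript_id[layout$contaminant],
                 sprintf("SP_%04d", seq_along(layout$contaminant)),
                 60, 150, 60, 80 + 2 * seq_along(layout$contaminant)),
    blast6_frame(truth$transcript_id[weak],
                 sprintf("SP_W%03d", seq_along(weak)), 40, 60, 36, 38))
  utils::write.table(prot, file.path(dir, "protein_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  ## ---- expression stream (bulk compartments) ---------------------------
  comps <- c(podocyte = "podocyte_rz", podocyte2 = "podocyte_pa",
             glom1 = "glom_1", glom2 = "glom_2", glom3 = "glom_3",
             kid1 = "kidney_1", kid2 = "kidney_2", kid3 = "kidney_3")
  samp_comp <- c(rep("podocyte", 2), rep("glomerulus", 3), rep("kidney", 3))
  expr <- with_stream(seed, 3L, {
    v <- matrix(0, n, length(comps),
                dimnames = list(truth$transcript_id, unname(comps)))
    for (j in seq_len(n)) {
      total <- if (!truth$expressed[j]) stats::runif(1, 0.05, 0.5)
               else exp(stats::rnorm(1, log(25), 0.8))
      prof <- if (truth$specific[j]) {
        p <- rdirichlet1(c(60, 2, 2))            # TSI ~ 0.9 toward podocyte
        c(p[1], p[2], p[3])
      } else if (seq_len(n)[j] %in% layout$nonpod) {
        p <- rdirichlet1(c(0.5, 10, 10))         # podocyte-poor
        c(p[1], p[2], p[3])
      } else rdirichlet1(c(5, 5, 5))
      by_samp <- prof[match(samp_comp, c("podocyte", "glomerulus", "kidney"))]
      noise <- stats::rgamma(length(comps), shape = 25, rate = 25)
      v[j, ] <- 3 * total * by_samp * noise
    }
    ## guarantee the expression cutoff is two-sided: expressed features
    ## reach 1 FPKM somewhere, unexpressed ones nowhere
    mx <- apply(v, 1, max)
    low <- truth$expressed & mx < 1
    v[low, ] <- v[low, ] * (1.5 / mx[low])
    v[!truth$expressed, ] <- pmin(v[!truth$expressed, , drop = FALSE], 0.9)
    round(v, 4)
  })
  write_tsv(data.frame(transcript_id = rownames(expr), expr,
                       check.names = FALSE),
            file.path(dir, "expression_fpkm.tsv"))
  write_tsv(data.frame(sample = unname(comps), compartment = samp_comp),
            file.path(dir, "expression_samples.tsv"))

  ## ---- human kidney expression (GTEX-like, 4 samples) ------------------
  h_features <- c(syn_orth, seq_orth)
  hexpr <- with_stream(seed, 6L, {
    expressed <- stats::runif(length(h_features)) < 0.7
    m <- matrix(0, length(h_features), 4,
                dimnames = list(h_features, paste0("gtex_", 1:4)))
    m[expressed, ] <- stats::rgamma(sum(expressed) * 4, shape = 4, rate = 1)
    m[!expressed, ] <- stats::runif(sum(!expressed) * 4, 0, 0.4)
    list(values = round(m, 3), expressed = expressed)
  })
  write_tsv(data.frame(feature_id = rownames(hexpr$values), hexpr$values,
                       check.names = FALSE),
            file.path(dir, "human_kidney_tpm.tsv"))

  ## ---- count matrices for the three disease models ---------------------
  nc_annot <- annotation_set(lnc_tx[!truth$coding, , drop = FALSE],
                             lnc_ex[lnc_ex$transcript_id %in%
                                      lnc_tx$transcript_id[!truth$coding], ,
                                    drop = FALSE])
  loci <- bundle_loci(nc_annot)
  tx2loc <- locus_map(loci)
  truth$locus_id <- unname(tx2loc[truth$transcript_id])

  nl <- nrow(loci)
  lfc <- matrix(0, nl, 3, dimnames = list(loci$locus_id,
                                          c("wt1", "podocin", "adriamycin")))
  ## shared coherent DE: the specific+conserved transcripts' loci (T5
  ## candidates) plus extra loci, up in all three models
  t5_tx <- truth$transcript_id[truth$specific &
                                 (truth$seq_conserved | truth$synteny_conserved) &
                                 !truth$coding]
  t5_tx <- t5_tx[seq_len(min(20L, length(t5_tx)))]
  shared_loci <- unique(unname(tx2loc[t5_tx]))
  de_truth <- with_stream(seed, 4L, {
    free <- setdiff(loci$locus_id,
                    unname(tx2loc[truth$transcript_id[!truth$expressed &
                                                        !truth$coding]]))
    free <- setdiff(free, shared_loci)
    take <- function(pool, n) pool[seq_len(min(n, length(pool)))]
    n_extra <- max(4L, round(nl * 0.025))
    n_down <- max(5L, round(nl * 0.055))
    n_mild <- max(4L, round(nl * 0.04))
    extra_shared <- take(sample(free), n_extra); free <- setdiff(free, extra_shared)
    shared <- c(shared_loci, extra_shared)
    lfc[shared, ] <- 2
    for (m in 1:3) {
      down <- take(sample(free), n_down); free <- setdiff(free, down)
      mild <- take(sample(free), n_mild); free <- setdiff(free, mild)
      lfc[down, m] <- -2
      lfc[mild, m] <- 1
    }
    base_mu <- exp(stats::rnorm(nl, log(120), 0.8))
    names(base_mu) <- loci$locus_id
    ## unexpressed loci get near-zero baselines
    base_mu[unname(tx2loc[truth$transcript_id[!truth$expressed & !truth$coding]])] <- 0.5
    sim_counts <- function(design) {
      mu <- outer(base_mu, rep(1, nrow(design)))
      for (s in seq_len(nrow(design))) {
        eff <- if (design$condition[s] == "disease")
          2^lfc[, design$model[s]] else rep(1, nl)
        age_eff <- if (!is.na(design$age[s]) && design$age[s] == "12w") 1.4 else 1
        mu[, s] <- mu[, s] * eff * age_eff
      }
      cnt <- matrix(stats::rnbinom(length(mu), size = 1 / cfg$phi, mu = mu),
                    nrow = nl, dimnames = list(loci$locus_id, design$sample))
      cnt
    }
    designs <- list(
      wt1 = expand.grid(age = c("4w", "12w"), condition = c("control", "disease"),
                        rep = seq_len(cfg$n_rep), stringsAsFactors = FALSE),
      podocin = expand.grid(age = c("4w", "12w"), condition = c("control", "disease"),
                            rep = seq_len(cfg$n_rep), stringsAsFactors = FALSE),
      adriamycin = expand.grid(age = NA_character_, condition = c("control", "disease"),
                               rep = seq_len(cfg$n_rep), stringsAsFactors = FALSE))
    sheets <- list(); counts <- list()
    for (m in names(designs)) {
      d <- designs[[m]]
      d$model <- m
      d$sample <- paste0(m, "_", substr(d$condition, 1, 1),
                         ifelse(is.na(d$age), "", paste0("_", d$age)), "_r", d$rep)
      counts[[m]] <- sim_counts(d)
      sheets[[m]] <- d[c("sample", "model", "condition", "age")]
    }
    list(lfc = lfc, counts = counts,
         sheet = do.call(rbind, sheets))
  })
  for (m in names(de_truth$counts))
    write_tsv(data.frame(locus_id = rownames(de_truth$counts[[m]]),
                         de_truth$counts[[m]], check.names = FALSE),
              file.path(dir, paste0("counts_", m, ".tsv")))
  write_tsv(de_truth$sheet, file.path(dir, "count_samples.tsv"))

  ## ---- scRNA-seq triplet -----------------------------------------------
  markers <- c("Wt1", "Nphs1", "Nphs2", "Mafb")
  spec_genes <- truth$gene_id[truth$specific]
  excl_genes <- spec_genes[seq_len(cfg$n_exclusive)]
  silent_genes <- spec_genes[(cfg$n_exclusive + 1):(cfg$n_exclusive + 5)]
  broad_genes <- setdiff(spec_genes, c(excl_genes, silent_genes))
  bg_genes <- sprintf("Bg%03d", 1:56)
  genes <- c(markers, spec_genes, bg_genes)
  scrna <- with_stream(seed, 5L, {
    ncell <- cfg$n_pod_cells + cfg$n_other_cells
    is_pod <- seq_len(ncell) <= cfg$n_pod_cells
    m <- matrix(0L, length(genes), ncell, dimnames = list(genes, NULL))
    m[markers, is_pod] <- 1L + stats::rpois(4 * sum(is_pod), 3)
    m[markers, !is_pod] <- stats::rpois(4 * sum(!is_pod), 0.02)
    m[excl_genes, is_pod] <- stats::rpois(length(excl_genes) * sum(is_pod), 2)
    m[broad_genes, ] <- stats::rpois(length(broad_genes) * ncell, 0.5)
    m[bg_genes, ] <- stats::rpois(length(bg_genes) * ncell, 1)
    barcodes <- sprintf("CELL_%03d-1", seq_len(ncell))
    colnames(m) <- barcodes
    list(m = m, is_pod = is_pod, barcodes = barcodes)
  })
  Matrix::writeMM(methods::as(Matrix::Matrix(scrna$m, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "scrna", "matrix.mtx"))
  utils::write.table(data.frame(genes, genes, "Gene Expression"),
                     file.path(dir, "scrna", "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(scrna$barcodes),
                     file.path(dir, "scrna", "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  ## ---- manifest --------------------------------------------------------
  truth$conserved_by <- ifelse(truth$seq_conserved & truth$synteny_conserved, "both",
                        ifelse(truth$seq_conserved, "sequence",
                        ifelse(truth$synteny_conserved, "synteny", "none")))
  orth_id <- rep(NA_character_, n)
  orth_id[layout$seq_cons] <- seq_orth
  orth_id[layout$syn] <- syn_orth
  truth$human_ortholog <- orth_id
  truth$human_expressed <- FALSE
  truth$human_expressed[match(h_features[hexpr$expressed],
                              truth$human_ortholog, nomatch = 0) ] <- TRUE
  hx <- match(truth$human_ortholog, h_features)
  truth$human_expressed <- !is.na(hx) & hexpr$expressed[ifelse(is.na(hx), 1L, hx)]
  truth$scrna_exclusive <- truth$gene_id %in% excl_genes
  truth$scrna_present <- truth$gene_id %in% setdiff(spec_genes, silent_genes)
  for (m in colnames(de_truth$lfc))
    truth[[paste0("lfc_", m)]] <-
      de_truth$lfc[match(truth$locus_id, rownames(de_truth$lfc)), m]

  manifest <- list(
    seed = as.integer(seed),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    transcripts = truth,
    loci = data.frame(locus_id = loci$locus_id, chrom = loci$chrom,
                      strand = loci$strand, start = loci$start,
                      end = loci$end, n_transcripts = loci$n_transcripts,
                      stringsAsFactors = FALSE),
    de = data.frame(locus_id = rownames(de_truth$lfc), de_truth$lfc,
                    row.names = NULL, check.names = FALSE),
    scrna = list(markers = markers, exclusive_genes = excl_genes,
                 silent_genes = silent_genes,
                 podocyte_barcodes = scrna$barcodes[scrna$is_pod]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(manifest)
}

#' Read a fixture manifest
#'
#' @param dir fixture directory.
#' @return The manifest list with `transcripts`, `loci` and `de` as
#'   data.frames.
#' @export
read_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  m$transcripts <- as.data.frame(m$transcripts, stringsAsFactors = FALSE)
  m$loci <- as.data.frame(m$loci, stringsAsFactors = FALSE)
  m$de <- as.data.frame(m$de, stringsAsFactors = FALSE)
  m
}

#' Read a hexamer model written by the fixture generator
#' @param path TSV with columns `hexamer`, `log_odds`.
#' @return Named numeric vector.
#' @export
read_hexamer_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$log_odds, df$hexamer)
}

#' Read a start-codon PSSM written by the fixture generator
#' @param path TSV with column `base` then one column per offset -6..+4.
#' @return 4 x 11 numeric matrix.
#' @export
read_start_pssm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
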