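one_to_one <- function(a, b, bits = 200) {
  data.frame(qseqid = a, sseqid = b, bitscore = bits)
}

test_that("perfect colinearity yields one block of all anchor pairs", {
  oa <- order_from(paste0("A", 1:5))
  ob <- order_from(paste0("B", 1:5))
  blk <- align_gene_orders(oa, ob, one_to_one(paste0("A", 1:5), paste0("B", 1:5)))
  expect_equal(nrow(blk$blocks), 1L)
  expect_equal(blk$blocks$score, 5)
  expect_equal(blk$pairs$gene_a, paste0("A", 1:5))
  expect_equal(blk$pairs$gene_b, paste0("B", 1:5))
})

test_that("shuffled orders without homology produce no blocks", {
  oa <- order_from(paste0("A", 1:6))
  ob <- order_from(paste0("B", 1:6))
  blk <- align_gene_orders(oa, ob, one_to_one("A1", "B1")[0, ])
  expect_equal(nrow(blk$blocks), 0L)
  expect_equal(nrow(align_gene_orders(oa[0, ], ob, NULL)$blocks), 0L)
})

test_that("an inverted segment is found through the reverse orientation", {
  oa <- order_from(paste0("A", 1:5))
  ob <- order_from(paste0("B", 5:1))
  blk <- align_gene_orders(oa, ob, one_to_one(paste0("A", 1:5), paste0("B", 1:5)))
  expect_equal(nrow(blk$blocks), 1L)
  expect_equal(blk$blocks$orientation, "-")
  expect_equal(blk$blocks$score, 5)
})

test_that("gene-order DP equals brute-force enumeration on small instances", {
  set.seed(303)
  for (k in 1:60) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    sa <- paste0("A", seq_len(na)); sb <- paste0("B", seq_len(nb))
    ## random homology table
    hom <- expand.grid(qseqid = sa, sseqid = sb, stringsAsFactors = FALSE)
    hom$bitscore <- ifelse(stats::runif(nrow(hom)) < 0.35, 200, 10)
    oa <- order_from(sa); ob <- order_from(sb)
    blk <- align_gene_orders(oa, ob, hom, min_score = 0.5)
    got <- if (nrow(blk$blocks)) max(blk$blocks$score) else 0
    keys <- paste(hom$qseqid, hom$sseqid)[hom$bitscore >= 50]
    sf <- function(a, b) if (paste(a, b) %in% keys) 1 else -1
    want <- brute_order_score(sa, sb, sf)
    expect_equal(got, want, info = paste("case", k))
  }
})

test_that("ortholog prediction follows the adjacency rule", {
  ## mouse: anchor A1, lnc L, anchor A2; human: A1' with adjacent ncRNA H
  mo <- gene_order(data.frame(
    gene_id = c("A1", "L", "A2"), chrom = "m1",
    start = c(1e4, 2e4, 3e4), end = c(1e4, 2e4, 3e4) + 2000,
    strand = "+", biotype = c("coding", "noncoding", "coding")))
  ho <- gene_order(data.frame(
    gene_id = c("A1h", "H", "A2h"), chrom = "h1",
    start = c(1e4, 2e4, 3e4), end = c(1e4, 2e4, 3e4) + 2000,
    strand = "+", biotype = c("coding", "noncoding", "coding")))
  blocks <- align_gene_orders(mo, ho, one_to_one(c("A1", "A2"), c("A1h", "A2h")),
                              min_score = 2)
  p <- predict_synteny_orthologs("L", blocks, mo, ho)
  expect_equal(p$ortholog_id, "H")
  expect_equal(p$evidence, "synteny")
  ## out of distance range: no pair
  p2 <- predict_synteny_orthologs("L", blocks, mo, ho,
                                  max_anchor_distance = 1000)
  expect_equal(nrow(p2), 0L)
  ## unaligned flanking anchors: no pair
  empty_blocks <- align_gene_orders(mo, ho, one_to_one("A1", "A1h")[0, ])
  expect_equal(nrow(predict_synteny_orthologs("L", empty_blocks, mo, ho)), 0L)
})

test_that("prediction is invariant under translation and strand flip", {
  fx <- get_fixture()
  human <- read_gtf(file.path(fx$dir, "human_annotation.gtf"))
  hg <- gene_table(human)
  mref <- read_gtf(file.path(fx$dir, "mouse_reference.gtf"))
  masm <- read_gtf(file.path(fx$dir, "mouse_assembled.gtf"))
  truth <- fx$manifest$transcripts
  mg <- rbind(gene_table(subset_annotation(mref, mref$transcripts$biotype == "coding")),
              gene_table(subset_annotation(
                masm, truth$transcript_id[!truth$coding])))
  hom <- read_blast6(file.path(fx$dir, "anchor_homology.tsv"))
  lncs <- truth$gene_id[truth$synteny_conserved]
  base <- predict_synteny_orthologs(
    lncs, align_gene_orders(gene_order(mg), gene_order(hg), hom),
    gene_order(mg), gene_order(hg))
  ## translate and flip the human genome chromosome-wide
  hg2 <- hg
  for (ch in unique(hg2$chrom)) {
    sel <- hg2$chrom == ch
    C <- max(hg2$end[sel]) + 1e6
    s <- C - hg2$end[sel]; e <- C - hg2$start[sel]
    hg2$start[sel] <- s; hg2$end[sel] <- e
    hg2$strand[sel] <- ifelse(hg2$strand[sel] == "+", "-", "+")
  }
  flipped <- predict_synteny_orthologs(
    lncs, align_gene_orders(gene_order(mg), gene_order(hg2), hom),
    gene_order(mg), gene_order(hg2))
  expect_equal(base[c("lnc_id", "ortholog_id")],
               flipped[c("lnc_id", "ortholog_id")])
})

test_that("planted syntenic orthologs are recovered and decoys rejected", {
  fx <- get_fixture()
  pl <- get_pipeline()
  truth <- fx$manifest$transcripts
  ## condition on the synteny stage's input: candidates the coding filter
  ## passed through (upstream misclassification is measured elsewhere)
  nc_genes <- truth$gene_id[truth$transcript_id %in%
                              pl$verdicts$transcript_id[pl$verdicts$verdict ==
                                                          "noncoding"]]
  planted <- intersect(truth$gene_id[truth$synteny_conserved], nc_genes)
  decoys <- truth$gene_id[truth$decoy]
  expect_gte(length(planted), 18)
  expect_setequal(unique(pl$syn_pairs$lnc_id), planted)
  expect_length(intersect(pl$syn_pairs$lnc_id, decoys), 0)
  ## each planted lncRNA's own planted human ortholog is among its pairs
  ## (the adjacency rule may additionally propose the ncRNA next to the
  ## other flanking anchor)
  m <- merge(pl$syn_pairs, truth, by.x = "lnc_id", by.y = "gene_id")
  found <- tapply(m$ortholog_id == m$human_ortholog, m$lnc_id, any)
  expect_true(all(found))
})
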