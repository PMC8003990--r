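test_that("GTF reading keeps 1-based coordinates, sorts exons, and round-trips", {
  gtf <- c(
    'c1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_biotype "lncRNA"',
    'c1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_biotype "lncRNA"',
    'c1\tx\texon\t501\t700\t.\t-\t.\tgene_id "g2"; transcript_id "t2"; gene_biotype "protein_coding"',
    'c1\tx\texon\t900\t950\t.\t+\t.\tgene_id "g3"; transcript_id "t3";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  a <- read_gtf(f)
  ex1 <- a$exons[a$exons$transcript_id == "t1", ]
  expect_equal(ex1$start, c(101, 301))          # file order was reversed
  expect_equal(ex1$end - ex1$start + 1, c(100, 100))
  expect_equal(unname(spliced_length(a)[c("t1", "t2", "t3")]), c(200, 200, 51))
  expect_equal(a$transcripts$biotype[match(c("t1", "t2", "t3"),
                                           a$transcripts$transcript_id)],
               c("noncoding", "coding", "unknown"))
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(a, f2)
  b <- read_gtf(f2)
  expect_equal(b$exons, a$exons)
  expect_equal(b$transcripts[c("transcript_id", "chrom", "strand")],
               a$transcripts[c("transcript_id", "chrom", "strand")])
  ## unknown biotype becomes noncoding on write (lncRNA set semantics differ)
  expect_equal(b$transcripts$biotype[match(c("t1", "t2"),
                                           b$transcripts$transcript_id)],
               c("noncoding", "coding"))
})

test_that("records without transcript_id follow the selected policy", {
  gtf <- c(
    'c1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  expect_error(read_gtf(f), "transcript_id")
  expect_message(a <- read_gtf(f, on_missing_id = "skip"), "skipping")
  expect_equal(nrow(a$transcripts), 1L)
})

test_that("annotation_set enforces its invariants", {
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "c1",
                   strand = "+", biotype = "noncoding")
  expect_error(annotation_set(tx, data.frame(transcript_id = "t1",
                                             start = 10, end = 5)), "end")
  expect_error(annotation_set(tx, data.frame(transcript_id = c("t1", "t1"),
                                             start = c(1, 50),
                                             end = c(60, 90))), "overlapping")
  expect_error(annotation_set(rbind(tx, tx),
                              data.frame(transcript_id = "t1",
                                         start = 1, end = 10)), "duplicate")
})

test_that("known/novel classification keys on the intron chain", {
  asm <- make_annot(list(id = "a1", ex = list(c(100, 199), c(300, 400))))
  ## same intron (200..299) but terminal ends jittered by 10 bp
  ref <- make_annot(list(id = "r1", ex = list(c(90, 199), c(300, 410))))
  expect_equal(unname(classify_transcripts(asm, ref)), "known")
  ## opposite strand: novel despite identical structure
  ref2 <- make_annot(list(id = "r1", strand = "-",
                          ex = list(c(100, 199), c(300, 400))))
  expect_equal(unname(classify_transcripts(asm, ref2)), "novel")
  ## different intron: novel
  ref3 <- make_annot(list(id = "r1", ex = list(c(100, 210), c(300, 400))))
  expect_equal(unname(classify_transcripts(asm, ref3)), "novel")
})

test_that("terminal-exon jitter never flips a multi-exon known label", {
  set.seed(42)
  ref <- make_annot(list(id = "r1", ex = list(c(1000, 1199), c(1500, 1700),
                                              c(2000, 2300))))
  for (k in 1:20) {
    j1 <- sample(-50:50, 1); j2 <- sample(-50:50, 1)
    asm <- make_annot(list(id = "a1", ex = list(c(1000 + j1, 1199),
                                                c(1500, 1700),
                                                c(2000, 2300 + j2))))
    expect_equal(unname(classify_transcripts(asm, ref)), "known")
  }
})

test_that("mono-exonic transcripts need reciprocal 50 percent overlap", {
  ref <- make_annot(list(id = "r1", ex = list(c(1000, 1999))))  # 1 kb
  ## overlap 600/1000 on both: known
  a1 <- make_annot(list(id = "a1", ex = list(c(1400, 2399))))
  expect_equal(unname(classify_transcripts(a1, ref)), "known")
  ## overlap 300: below half of either: novel
  a2 <- make_annot(list(id = "a2", ex = list(c(1700, 2699))))
  expect_equal(unname(classify_transcripts(a2, ref)), "novel")
  ## asymmetric: short transcript inside, covers < 50% of the reference
  a3 <- make_annot(list(id = "a3", ex = list(c(1100, 1400))))
  expect_equal(unname(classify_transcripts(a3, ref)), "novel")
})

test_that("empty reference classifies everything novel with a warning", {
  asm <- make_annot(list(id = "a1", ex = list(c(1, 300))))
  ref <- make_annot(list(id = "r1", ex = list(c(1, 300))))
  ref <- subset_annotation(ref, character(0))
  expect_warning(lab <- classify_transcripts(asm, ref), "empty reference")
  expect_equal(unname(lab), "novel")
})

test_that("planted known/novel labels are recovered on the fixture", {
  fx <- get_fixture()
  pl <- get_pipeline()
  truth <- fx$manifest$transcripts
  lab <- pl$novelty[truth$transcript_id]
  expect_equal(unname(lab == "known"), truth$known)
})

test_that("locus bundling follows same-strand single-linkage exonic overlap", {
  ## one shared exon base links two transcripts
  a <- make_annot(list(id = "t1", ex = list(c(100, 200))),
                  list(id = "t2", ex = list(c(200, 300))))
  expect_equal(nrow(bundle_loci(a)), 1L)
  ## opposite strands stay apart
  b <- make_annot(list(id = "t1", ex = list(c(100, 200))),
                  list(id = "t2", strand = "-", ex = list(c(150, 250))))
  expect_equal(nrow(bundle_loci(b)), 2L)
  ## transitivity: A-B and B-C overlap, A and C do not
  c3 <- make_annot(list(id = "A", ex = list(c(100, 200))),
                   list(id = "B", ex = list(c(180, 320))),
                   list(id = "C", ex = list(c(300, 400))))
  l3 <- bundle_loci(c3)
  expect_equal(nrow(l3), 1L)
  expect_equal(sort(l3$transcript_ids[[1]]), c("A", "B", "C"))
  ## intron-only overlap does not link (exonic overlap required)
  d <- make_annot(list(id = "t1", ex = list(c(100, 150), c(900, 1000))),
                  list(id = "t2", ex = list(c(300, 400))))
  expect_equal(nrow(bundle_loci(d)), 2L)
  ## coding transcripts are rejected
  e <- make_annot(list(id = "t1", biotype = "coding", ex = list(c(1, 100))))
  expect_error(bundle_loci(e), "coding")
})

test_that("bundled loci partition the input and are maximal", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    txs <- lapply(seq_len(n), function(i) {
      s <- sample(1:2000, 1)
      list(id = paste0("t", i), strand = sample(c("+", "-"), 1),
           ex = list(c(s, s + sample(50:400, 1))))
    })
    a <- do.call(make_annot, txs)
    loci <- bundle_loci(a)
    ## partition
    members <- unlist(loci$transcript_ids)
    expect_setequal(members, a$transcripts$transcript_id)
    expect_equal(anyDuplicated(members), 0L)
    ## maximality: no two loci could be merged under the overlap rule
    sp <- do.call(rbind, lapply(txs, function(t)
      data.frame(id = t$id, strand = t$strand,
                 s = t$ex[[1]][1], e = t$ex[[1]][2])))
    lm <- locus_map(loci)
    for (i in seq_len(nrow(sp))) for (j in seq_len(nrow(sp))) {
      if (i >= j) next
      overlap <- sp$strand[i] == sp$strand[j] &&
        sp$s[i] <= sp$e[j] && sp$s[j] <= sp$e[i]
      if (overlap) expect_equal(unname(lm[sp$id[i]]), unname(lm[sp$id[j]]))
    }
  }
})
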