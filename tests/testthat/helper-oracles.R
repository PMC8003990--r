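## Independent oracles used across the suite. These deliberately share no
## code with the implementation paths they check.

## plain triple-frame ORF scanner: walk codons one by one, first ATG after
## each stop opens the maximal ORF of its stop group
brute_force_orfs <- function(seq, min_aa = 50L) {
  seq <- toupper(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- NULL
  for (f in 0:2) {
    if (f + 3L > nchar(seq)) next
    pos <- seq.int(f + 1L, nchar(seq) - 2L, by = 3L)
    cods <- substring(seq, pos, pos + 2L)
    k <- length(cods)
    idx <- 1L
    while (idx <= k) {
      if (cods[idx] == "ATG") {
        j <- idx + 1L
        while (j <= k && !(cods[j] %in% stops)) j <- j + 1L
        complete <- j <= k
        len <- if (complete) j - idx else k - idx + 1L
        if (len >= min_aa)
          out <- rbind(out, data.frame(
            frame = f, start = pos[idx],
            end = pos[min(j, k)] + 2L, length_aa = len,
            complete = complete))
        ## skip to after this ORF's stop (or end): later ATGs before that
        ## stop are nested and suppressed
        idx <- j + 1L
      } else idx <- idx + 1L
    }
  }
  if (is.null(out))
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), length_aa = integer(0),
                      complete = logical(0)))
  out <- out[order(out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

## definitional step-up BH
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## best local gene-order alignment score by explicit enumeration of all
## chains of aligned pairs (monotone in both orders, linear gap per
## skipped element); considers both orientations of sb
brute_order_score <- function(sa, sb, score_fun, gap = -0.5) {
  one_dir <- function(sb) {
    n <- length(sa); m <- length(sb)
    if (n == 0 || m == 0) return(0)
    M <- matrix(-Inf, n, m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      base <- score_fun(sa[i], sb[j])
      ext <- 0
      if (i > 1 && j > 1) {
        for (i2 in seq_len(i - 1)) for (j2 in seq_len(j - 1)) {
          cand <- M[i2, j2] + gap * ((i - i2 - 1) + (j - j2 - 1))
          if (cand > ext) ext <- cand
        }
      }
      M[i, j] <- base + ext
    }
    max(0, max(M))
  }
  max(one_dir(sb), one_dir(rev(sb)))
}

## independent affine-gap local alignment (Gotoh three-state DP)
gotoh_local_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 2, gap_extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) match else mismatch
    M[i + 1, j + 1] <- max(0, s + max(M[i, j], Ix[i, j], Iy[i, j]))
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                            Ix[i, j + 1] - gap_extend)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                            Iy[i + 1, j] - gap_extend)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

## exact two-sided rank-sum p by explicit enumeration (2*min convention)
enum_wilcox_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(N, n1), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
}

## gene order on one chromosome from a vector of ids
order_from <- function(ids, chrom = "c1", biotype = "coding", gap = 1e4) {
  gene_order(data.frame(gene_id = ids, chrom = chrom,
                        start = gap * seq_along(ids),
                        end = gap * seq_along(ids) + 2000,
                        strand = "+", biotype = biotype))
}

## tiny annotation builder: ex = list of (start,end) pairs per transcript
make_annot <- function(...) {
  txs <- list(...)
  tt <- do.call(rbind, lapply(txs, function(t)
    data.frame(transcript_id = t$id, gene_id = t$gene %||% t$id,
               chrom = t$chrom %||% "c1", strand = t$strand %||% "+",
               biotype = t$biotype %||% "noncoding",
               stringsAsFactors = FALSE)))
  ee <- do.call(rbind, lapply(txs, function(t)
    data.frame(transcript_id = t$id,
               start = vapply(t$ex, `[[`, numeric(1), 1),
               end = vapply(t$ex, `[[`, numeric(1), 2))))
  annotation_set(tt, ee)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## the default seeded fixture and its pipeline run, generated once per
## test session
.fixture_env <- new.env(parent = emptyenv())
get_fixture <- function() {
  if (is.null(.fixture_env$dir)) {
    d <- file.path(tempdir(), "podlnc-fixture")
    .fixture_env$manifest <- generate_fixture(d, seed = 1L)
    .fixture_env$dir <- d
  }
  list(dir = .fixture_env$dir, manifest = .fixture_env$manifest)
}
get_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    fx <- get_fixture()
    .fixture_env$pipeline <- suppressMessages(run_pipeline(fx$dir))
  }
  .fixture_env$pipeline
}
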