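STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_of <- function(seq, frame) {
  n <- nchar(seq)
  starts <- seq.int(frame + 1L, by = 3L, length.out = max(0L, (n - frame) %/% 3L))
  if (!length(starts)) return(list(pos = integer(0), codon = character(0)))
  list(pos = starts, codon = substring(seq, starts, starts + 2L))
}

#' Find sense-strand open reading frames
#'
#' Scans the three forward frames for ATG-initiated ORFs of at least
#' `min_aa` codons before the next in-frame stop. ORFs that reach the 3' end
#' without a stop are reported with `complete = FALSE`. When one candidate is
#' contained within another (a downstream in-frame ATG sharing the same
#' stop), only the longest is reported. Codons containing N never match
#' start or stop.
#'
#' Coordinates are 1-based closed on the sense strand; for a complete ORF
#' `end` includes the stop codon and `length_aa = (end - start + 1)/3 - 1`.
#'
#' @param seq nucleotide string over A,C,G,T,N.
#' @param min_aa minimum ORF length in amino acids (default 50).
#' @param transcript_id optional id recorded in the output.
#' @return data.frame with columns `transcript_id`, `frame` (0,1,2),
#'   `start`, `end`, `length_aa`, `complete`, ordered by start position.
#' @export
find_orfs <- function(seq, min_aa = 50L, transcript_id = NA_character_) {
  seq <- toupper(seq)
  out <- list()
  for (f in 0:2) {
    cd <- codons_of(seq, f)
    k <- length(cd$pos)
    if (k == 0L) next
    is_start <- cd$codon == "ATG"
    is_stop <- cd$codon %in% STOP_CODONS
    s_idx <- which(is_start)
    if (!length(s_idx)) next
    stop_idx <- which(is_stop)
    ## next stop at codon index > start index (stop cannot be the ATG itself)
    nxt <- stop_idx[findInterval(s_idx, stop_idx) + 1L]
    grp <- ifelse(is.na(nxt), .Machine$integer.max, nxt)
    keep <- !duplicated(grp)            # earliest ATG per stop group wins
    s_keep <- s_idx[keep]; stop_keep <- nxt[keep]
    complete <- !is.na(stop_keep)
    len_aa <- ifelse(complete, stop_keep - s_keep, k - s_keep + 1L)
    end_codon <- ifelse(complete, stop_keep, k)
    ok <- len_aa >= min_aa
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = transcript_id, frame = f,
      start = cd$pos[s_keep[ok]],
      end = cd$pos[end_codon[ok]] + 2L,
      length_aa = as.integer(len_aa[ok]),
      complete = complete[ok], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      length_aa = integer(0), complete = logical(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Length of the longest ORF in a sequence
#'
#' @param seq nucleotide string.
#' @param complete_only if TRUE, only stop-terminated ORFs count.
#' @return Longest ORF length in amino acids (0 if none).
#' @export
longest_orf_length <- function(seq, complete_only = FALSE) {
  orfs <- find_orfs(seq, min_aa = 1L)
  if (complete_only) orfs <- orfs[orfs$complete, , drop = FALSE]
  if (!nrow(orfs)) 0L else max(orfs$length_aa)
}

codon_prob <- function(codon, freqs) {
  prod(freqs[strsplit(codon, "")[[1]]])
}

#' Dynamic ORF-length cutoff under a random-sequence null
#'
#' Returns the smallest ORF length n (in codons, at least `min_aa`) such
#' that the expected number of sense-strand ORFs of >= n codons in an i.i.d.
#' random sequence of length L falls below `alpha`:
#' \deqn{E(n, L) = \max(0, L - 3n) \cdot p_{start} \cdot (1 - p_{stop})^{n-1}}
#' with p_start and p_stop the codon probabilities of ATG and of the three
#' stop codons under `base_freqs`. The cutoff is monotone non-decreasing in
#' L: longer transcripts harbour longer chance ORFs, so a fixed length
#' threshold would over-call coding potential on short transcripts and
#' under-call it on long ones.
#'
#' @param L transcript length in nucleotides (>= 3).
#' @param alpha expected-count threshold (default 0.05).
#' @param base_freqs named probabilities for A, C, G, T (default uniform).
#' @param min_aa lower bound on the returned cutoff (default 50).
#' @return Integer cutoff in amino acids.
#' @export
dynamic_orf_cutoff <- function(L, alpha = 0.05,
                               base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                               min_aa = 50L) {
  stopifnot(L >= 3)
  if (!all(c("A", "C", "G", "T") %in% names(base_freqs)))
    stop("base_freqs must name A, C, G, T")
  base_freqs <- base_freqs / sum(base_freqs)
  if (any(base_freqs[c("A", "T", "G")] == 0))
    stop("degenerate base_freqs: zero mass on a base required by start/stop codons")
  p_start <- codon_prob("ATG", base_freqs)
  p_stop <- sum(vapply(STOP_CODONS, codon_prob, numeric(1), freqs = base_freqs))
  n <- as.integer(min_aa)
  repeat {
    e_n <- max(0, L - 3 * n) * p_start * (1 - p_stop)^(n - 1)
    if (e_n < alpha) return(n)
    n <- n + 1L
  }
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
}

count_inframe_hexamers <- function(seqs, step = 3L) {
  tab <- integer(4096)
  names(tab) <- all_hexamers()
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 6L) next
    pos <- seq.int(1L, n - 5L, by = step)
    h <- substring(s, pos, pos + 5L)
    h <- h[!grepl("[^ACGT]", h)]
    if (length(h)) {
      t2 <- table(h)
      tab[names(t2)] <- tab[names(t2)] + as.integer(t2)
    }
  }
  tab
}

#' Train a hexamer log-odds model
#'
#' In-frame hexamer frequencies (step 3 from the first position) of coding
#' sequences against hexamer frequencies of background sequences, as
#' log-odds with pseudocounts.
#'
#' @param coding_seqs character vector of coding sequences (in frame).
#' @param background_seqs character vector of background sequences.
#' @param pseudocount added to every hexamer count (default 1).
#' @return Named numeric vector of log-odds over all 4096 hexamers.
#' @export
train_hexamer_model <- function(coding_seqs, background_seqs, pseudocount = 1) {
  cc <- count_inframe_hexamers(coding_seqs, step = 3L) + pseudocount
  bc <- count_inframe_hexamers(background_seqs, step = 1L) + pseudocount
  log((cc / sum(cc)) / (bc / sum(bc)))
}

#' Train a start-codon position-specific scoring matrix
#'
#' Positions cover offsets -6..+4 relative to the A of the ATG (11
#' positions). Input contexts are 11-mers centred accordingly; the PSSM is
#' the positional log-odds against `background`.
#'
#' @param contexts character vector of 11-nt start contexts.
#' @param background named base probabilities (default uniform).
#' @param pseudocount added per base and position (default 1).
#' @return 4 x 11 matrix (rows A,C,G,T; columns offsets -6..+4).
#' @export
train_start_pssm <- function(contexts,
                             background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             pseudocount = 1) {
  stopifnot(all(nchar(contexts) == 11L))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(pseudocount, 4, 11, dimnames = list(bases, as.character(-6:4)))
  for (ctx in toupper(contexts)) {
    ch <- strsplit(ctx, "")[[1]]
    for (j in seq_len(11L)) if (ch[j] %in% bases)
      counts[ch[j], j] <- counts[ch[j], j] + 1
  }
  freq <- sweep(counts, 2, colSums(counts), "/")
  log(freq / background[bases])
}

#' Score an ORF with a hexamer model and a start-codon PSSM
#'
#' The hexamer log-likelihood is the sum of in-frame hexamer log-odds over
#' the ORF; the start score is the summed positional log-odds of the -6..+4
#' context around the ATG. Hexamers or positions containing N (or falling
#' outside the transcript) contribute zero.
#'
#' @param orf one row of [find_orfs()] output.
#' @param seq the transcript sequence the ORF lives on.
#' @param hexamer_model named log-odds vector (see [train_hexamer_model()]);
#'   NULL scores 0.
#' @param start_pssm 4 x 11 log-odds matrix (see [train_start_pssm()]);
#'   NULL scores 0.
#' @return Named numeric vector `c(ll_score=, start_pssm_score=)`.
#' @export
score_orf <- function(orf, seq, hexamer_model = NULL, start_pssm = NULL) {
  seq <- toupper(seq)
  if ((orf$end - orf$start + 1L) < 6L)
    stop("ORF shorter than 2 codons cannot be scored")
  ll <- 0
  if (!is.null(hexamer_model)) {
    pos <- seq.int(orf$start, orf$end - 5L, by = 3L)
    h <- substring(seq, pos, pos + 5L)
    v <- hexamer_model[h]
    ll <- sum(v[!is.na(v)])
  }
  ps <- 0
  if (!is.null(start_pssm)) {
    bases <- rownames(start_pssm)
    offs <- as.integer(colnames(start_pssm))
    pos <- orf$start + offs
    inside <- pos >= 1L & pos <= nchar(seq)
    ch <- substring(seq, pos[inside], pos[inside])
    ok <- ch %in% bases
    if (any(ok))
      ps <- sum(start_pssm[cbind(ch[ok], as.character(offs[inside][ok]))])
  }
  c(ll_score = ll, start_pssm_score = ps)
}
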