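#' Build a gene-order table
#'
#' Orders genes along each chromosome by midpoint position. Only
#' protein-coding genes serve as synteny anchors; noncoding genes are
#' carried for adjacency lookups.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype` (`coding`/`noncoding`).
#' @param species optional label stored on the result.
#' @return A `gene_order` data.frame (`gene_id`, `chrom`, `pos`, `strand`,
#'   `biotype`) sorted by (chrom, pos).
#' @export
gene_order <- function(genes, species = NA_character_) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  stopifnot(all(need %in% names(genes)))
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    pos = (genes$start + genes$end) / 2,
                    strand = genes$strand, biotype = genes$biotype,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  if (anyDuplicated(out[c("chrom", "pos")]))
    out$pos <- out$pos + seq_len(nrow(out)) * 1e-9   # enforce strict order
  rownames(out) <- NULL
  attr(out, "species") <- species
  class(out) <- c("gene_order", "data.frame")
  out
}

#' Gene-level table from an annotation set
#'
#' Gene span = union of member transcript spans; gene biotype is `coding` if
#' any member transcript is coding.
#'
#' @param annot an `annotation_set`.
#' @return data.frame suitable for [gene_order()].
#' @export
gene_table <- function(annot) {
  sp <- tx_span(annot)
  sp$gene_id <- annot$transcripts$gene_id
  sp$biotype <- annot$transcripts$biotype
  agg <- lapply(split(sp, sp$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1L],
               biotype = if (any(d$biotype == "coding")) "coding" else "noncoding",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

## Smith-Waterman over two anchor sequences with linear gap penalty.
## Tie-break on traceback: diagonal > up > left. Masked indices score 0.
sw_order_once <- function(sa, sb, pair_score, gap, mask_a, mask_b) {
  n <- length(sa); m <- length(sb)
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    if (mask_a[i]) next
    for (j in seq_len(m)) {
      if (mask_b[j]) next
      d <- H[i, j] + pair_score(sa[i], sb[j])
      u <- H[i, j + 1L] + gap
      l <- H[i + 1L, j] + gap
      H[i + 1L, j + 1L] <- max(0, d, u, l)
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)[1L, ]   # first = smallest i, then j
  score <- H[best[1L], best[2L]]
  if (score <= 0) return(list(score = 0, pairs = NULL))
  i <- best[1L]; j <- best[2L]
  pa <- integer(0); pb <- integer(0)
  while (i > 1L && j > 1L && H[i, j] > 0) {
    d <- H[i - 1L, j - 1L] + pair_score(sa[i - 1L], sb[j - 1L])
    u <- H[i - 1L, j] + gap
    l <- H[i, j - 1L] + gap
    if (abs(H[i, j] - d) < 1e-9) {
      pa <- c(i - 1L, pa); pb <- c(j - 1L, pb); i <- i - 1L; j <- j - 1L
    } else if (abs(H[i, j] - u) < 1e-9) {
      i <- i - 1L
    } else if (abs(H[i, j] - l) < 1e-9) {
      j <- j - 1L
    } else break
  }
  list(score = score, a_idx = pa, b_idx = pb)
}

#' Local gene-order (synteny) alignment
#'
#' Smith-Waterman-style local dynamic programming over the protein-coding
#' anchor orders of two species. An aligned anchor pair scores `match` if
#' the protein homology table links the two genes at `match_bits` bits or
#' better, `mismatch` otherwise; gaps cost `gap`. Both orientations of the
#' second species are searched so inverted segments are found. All blocks
#' with score at least `min_score` are reported; non-overlapping blocks are
#' extracted greedily by descending score (an anchor participates in at
#' most one block).
#'
#' @param order_a,order_b [gene_order()] tables (species A = query, e.g.
#'   mouse; species B = e.g. human).
#' @param homology data.frame with columns `qseqid` (species A gene),
#'   `sseqid` (species B gene), `bitscore` — BLASTP-like.
#' @param match_bits bit score at or above which two anchors count as
#'   homologous (default 50).
#' @param match,mismatch,gap alignment scores (defaults +1, -1, -0.5).
#' @param min_score minimum block score (default 3).
#' @return A `synteny_blocks` list: `blocks` (block_id, chrom_a, chrom_b,
#'   orientation, score, n_pairs) and `pairs` (block_id, gene_a, gene_b,
#'   match).
#' @export
align_gene_orders <- function(order_a, order_b, homology, match_bits = 50,
                              match = 1, mismatch = -1, gap = -0.5,
                              min_score = 3) {
  hom_keys <- character(0)
  if (!is.null(homology) && nrow(homology)) {
    ok <- homology$bitscore >= match_bits
    hom_keys <- unique(paste(homology$qseqid[ok], homology$sseqid[ok], sep = "\r"))
  }
  pair_score <- function(a, b)
    if (paste(a, b, sep = "\r") %in% hom_keys) match else mismatch
  anchors_a <- order_a[order_a$biotype == "coding", , drop = FALSE]
  anchors_b <- order_b[order_b$biotype == "coding", , drop = FALSE]
  raw <- list()
  if (nrow(anchors_a) && nrow(anchors_b)) {
    for (ca in unique(anchors_a$chrom)) {
      sa <- anchors_a$gene_id[anchors_a$chrom == ca]
      for (cb in unique(anchors_b$chrom)) {
        sb_fwd <- anchors_b$gene_id[anchors_b$chrom == cb]
        for (ori in c("+", "-")) {
          sb <- if (ori == "+") sb_fwd else rev(sb_fwd)
          mask_a <- rep(FALSE, length(sa)); mask_b <- rep(FALSE, length(sb))
          repeat {
            r <- sw_order_once(sa, sb, pair_score, gap, mask_a, mask_b)
            if (r$score < min_score || is.null(r$a_idx)) break
            raw[[length(raw) + 1L]] <- list(
              chrom_a = ca, chrom_b = cb, orientation = ori, score = r$score,
              gene_a = sa[r$a_idx], gene_b = sb[r$b_idx],
              match = vapply(seq_along(r$a_idx), function(k)
                pair_score(sa[r$a_idx[k]], sb[r$b_idx[k]]) > 0, logical(1)))
            mask_a[r$a_idx] <- TRUE; mask_b[r$b_idx] <- TRUE
          }
        }
      }
    }
  }
  ## greedy non-overlap across chromosome pairs and orientations
  if (length(raw)) {
    scores <- vapply(raw, `[[`, numeric(1), "score")
    keys <- vapply(raw, function(b)
      paste(b$chrom_a, b$chrom_b, b$orientation, b$gene_a[1L]), character(1))
    ord <- order(-scores, keys)
    used_a <- character(0); used_b <- character(0)
    kept <- list()
    for (k in ord) {
      b <- raw[[k]]
      if (any(b$gene_a %in% used_a) || any(b$gene_b %in% used_b)) next
      kept[[length(kept) + 1L]] <- b
      used_a <- c(used_a, b$gene_a); used_b <- c(used_b, b$gene_b)
    }
    raw <- kept
  }
  if (!length(raw)) {
    return(structure(list(
      blocks = data.frame(block_id = character(0), chrom_a = character(0),
                          chrom_b = character(0), orientation = character(0),
                          score = numeric(0), n_pairs = integer(0)),
      pairs = data.frame(block_id = character(0), gene_a = character(0),
                         gene_b = character(0), match = logical(0))),
      class = "synteny_blocks"))
  }
  ids <- sprintf("SYN%04d", seq_along(raw))
  blocks <- do.call(rbind, lapply(seq_along(raw), function(k)
    data.frame(block_id = ids[k], chrom_a = raw[[k]]$chrom_a,
               chrom_b = raw[[k]]$chrom_b, orientation = raw[[k]]$orientation,
               score = raw[[k]]$score, n_pairs = length(raw[[k]]$gene_a),
               stringsAsFactors = FALSE)))
  pairs <- do.call(rbind, lapply(seq_along(raw), function(k)
    data.frame(block_id = ids[k], gene_a = raw[[k]]$gene_a,
               gene_b = raw[[k]]$gene_b, match = raw[[k]]$match,
               stringsAsFactors = FALSE)))
  structure(list(blocks = blocks, pairs = pairs), class = "synteny_blocks")
}

#' Predict lncRNA orthologs by syntenic adjacency
#'
#' For each query lncRNA, its flanking protein-coding anchors are located in
#' the gene order. If a flanking anchor is matched inside a synteny block,
#' every noncoding gene immediately flanking the corresponding anchor of the
#' other species — and within `max_anchor_distance` bp of it — is emitted as
#' a candidate ortholog with evidence `"synteny"`. One aligned flanking
#' anchor suffices.
#'
#' @param lnc_ids ids of query (species A) lncRNA genes, present in
#'   `order_a` with biotype noncoding.
#' @param blocks a `synteny_blocks` object from [align_gene_orders()].
#' @param order_a,order_b [gene_order()] tables including noncoding genes.
#' @param max_anchor_distance maximum distance (bp) between the matched
#'   anchor and the candidate ortholog midpoints (default 1e5).
#' @return data.frame: `lnc_id`, `ortholog_id`, `evidence`, `anchor_a`,
#'   `anchor_b`, `distance`.
#' @export
predict_synteny_orthologs <- function(lnc_ids, blocks, order_a, order_b,
                                      max_anchor_distance = 1e5) {
  empty <- data.frame(lnc_id = character(0), ortholog_id = character(0),
                      evidence = character(0), anchor_a = character(0),
                      anchor_b = character(0), distance = numeric(0))
  mp <- blocks$pairs[blocks$pairs$match, , drop = FALSE]
  if (!nrow(mp)) return(empty)
  out <- list()
  for (lnc in lnc_ids) {
    row <- order_a[order_a$gene_id == lnc, , drop = FALSE]
    if (!nrow(row)) next
    ch <- order_a[order_a$chrom == row$chrom, , drop = FALSE]
    anchors <- ch[ch$biotype == "coding", , drop = FALSE]
    if (!nrow(anchors)) { message("no anchors on ", row$chrom, " for ", lnc); next }
    left <- anchors$gene_id[anchors$pos <= row$pos]
    right <- anchors$gene_id[anchors$pos > row$pos]
    flank <- c(if (length(left)) left[length(left)],
               if (length(right)) right[1L])
    for (a in flank) {
      hits <- mp[mp$gene_a == a, , drop = FALSE]
      for (h in hits$gene_b) {
        brow <- order_b[order_b$gene_id == h, , drop = FALSE]
        bch <- order_b[order_b$chrom == brow$chrom, , drop = FALSE]
        ncs <- bch[bch$biotype != "coding", , drop = FALSE]
        if (!nrow(ncs)) next
        nleft <- ncs[ncs$pos <= brow$pos, , drop = FALSE]
        nright <- ncs[ncs$pos > brow$pos, , drop = FALSE]
        cand <- rbind(if (nrow(nleft)) nleft[nrow(nleft), ],
                      if (nrow(nright)) nright[1L, ])
        if (is.null(cand) || !nrow(cand)) next
        d <- abs(cand$pos - brow$pos)
        keep <- d <= max_anchor_distance
        if (any(keep))
          out[[length(out) + 1L]] <- data.frame(
            lnc_id = lnc, ortholog_id = cand$gene_id[keep],
            evidence = "synteny", anchor_a = a, anchor_b = h,
            distance = d[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("lnc_id", "ortholog_id")]), , drop = FALSE]
  res <- res[order(res$lnc_id, res$ortholog_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
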