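#' Local nucleotide alignment of a sequence pair
#'
#' Affine-gap Smith-Waterman local alignment (match +1, mismatch -1, a gap
#' of length k costs `gap_open + k * gap_extend`), delegated to
#' Biostrings. Identity is percent matches over aligned columns (including
#' gap columns); alignment length counts all aligned columns.
#'
#' @param query,subject nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (defaults +1, -1, 2, 0.5; gap costs are positive penalties).
#' @return List with `score`, `identity` (percent), `aln_length`.
#' @export
align_sequences <- function(query, subject, match = 1, mismatch = -1,
                            gap_open = 2, gap_extend = 0.5) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(query, subject, type = "local",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  nm <- Biostrings::nmatch(al)
  nmm <- Biostrings::nmismatch(al)
  ind <- Biostrings::nindel(al)
  gaps <- sum(Biostrings::insertion(ind)[, "WidthSum"]) +
    sum(Biostrings::deletion(ind)[, "WidthSum"])
  len <- nm + nmm + gaps
  list(score = Biostrings::score(al),
       identity = if (len > 0) 100 * nm / len else 0,
       aln_length = len)
}

#' Sequence-conservation ortholog assignment
#'
#' Retains alignments with identity strictly above `min_identity` percent
#' AND aligned length strictly above `min_length` bp, emitting them as
#' ortholog pairs with evidence `"sequence"`. Alignments arrive either as a
#' BLAST outfmt-6 table ([read_blast6()]) or are computed with the internal
#' aligner from two named sequence sets (all query x subject pairs, or the
#' candidate pairs given in `pairs`).
#'
#' @param alignments optional outfmt-6 data.frame (queries = species A
#'   lncRNAs, subjects = species B features).
#' @param query_seqs,subject_seqs optional named sequence vectors used when
#'   `alignments` is NULL.
#' @param pairs optional data.frame (`qseqid`, `sseqid`) restricting which
#'   sequence pairs are aligned.
#' @param min_identity identity threshold in percent (default 80, strict >).
#' @param min_length alignment length threshold in bp (default 100, strict >).
#' @return data.frame: `lnc_id`, `ortholog_id`, `evidence`, `identity`,
#'   `aln_length`.
#' @export
sequence_conservation <- function(alignments = NULL, query_seqs = NULL,
                                  subject_seqs = NULL, pairs = NULL,
                                  min_identity = 80, min_length = 100) {
  if (is.null(alignments)) {
    stopifnot(!is.null(query_seqs), !is.null(subject_seqs))
    if (is.null(pairs))
      pairs <- expand.grid(qseqid = names(query_seqs),
                           sseqid = names(subject_seqs),
                           stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(pairs)), function(k) {
      al <- align_sequences(query_seqs[[pairs$qseqid[k]]],
                            subject_seqs[[pairs$sseqid[k]]])
      data.frame(qseqid = pairs$qseqid[k], sseqid = pairs$sseqid[k],
                 pident = al$identity, length = al$aln_length,
                 stringsAsFactors = FALSE)
    })
    alignments <- do.call(rbind, rows)
  }
  if (any(alignments$pident < 0 | alignments$pident > 100))
    stop("identity outside [0, 100]")
  keep <- alignments$pident > min_identity & alignments$length > min_length
  out <- data.frame(lnc_id = alignments$qseqid[keep],
                    ortholog_id = alignments$sseqid[keep],
                    evidence = "sequence",
                    identity = alignments$pident[keep],
                    aln_length = alignments$length[keep],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("lnc_id", "ortholog_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check expression of predicted orthologs in human samples
#'
#' A pair is flagged `human_expressed` iff the ortholog's expression reaches
#' `min_tpm` (inclusive) in at least `min_samples` samples. Orthologs absent
#' from the table are flagged FALSE and logged.
#'
#' @param pairs ortholog pair data.frame with column `ortholog_id`.
#' @param human_expr an `expression_table` or a features x samples matrix of
#'   kidney-sample expression.
#' @param min_tpm expression threshold (default 1.0).
#' @param min_samples minimum number of samples (default 1).
#' @return `pairs` with a logical `human_expressed` column appended.
#' @export
human_expression_check <- function(pairs, human_expr, min_tpm = 1.0,
                                   min_samples = 1L) {
  v <- if (inherits(human_expr, "expression_table")) human_expr$values
       else as.matrix(human_expr)
  flag <- vapply(pairs$ortholog_id, function(id) {
    if (!id %in% rownames(v)) return(FALSE)
    sum(v[id, ] >= min_tpm) >= min_samples
  }, logical(1))
  missing <- setdiff(unique(pairs$ortholog_id), rownames(v))
  if (length(missing))
    message(length(missing), " ortholog(s) absent from human expression table")
  pairs$human_expressed <- unname(flag)
  pairs
}
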