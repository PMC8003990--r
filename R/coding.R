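#' Select candidate transcripts by length and expression
#'
#' Retains transcripts whose spliced length is at least `min_len` and whose
#' maximum expression across samples is at least `min_fpkm` (both cutoffs
#' inclusive). Transcripts absent from the expression table are treated as
#' unexpressed and logged.
#'
#' @param annot an `annotation_set`.
#' @param expr an `expression_table` (FPKM or TPM).
#' @param min_len minimum spliced length in nt (default 200).
#' @param min_fpkm minimum expression (default 1.0).
#' @return Character vector of retained transcript ids.
#' @export
select_candidates <- function(annot, expr, min_len = 200, min_fpkm = 1.0) {
  stopifnot(inherits(annot, "annotation_set"), inherits(expr, "expression_table"))
  if (any(expr$values < 0)) stop("negative FPKM values")
  len <- spliced_length(annot)
  ids <- names(len)
  mx <- rep(0, length(ids)); names(mx) <- ids
  present <- ids[ids %in% rownames(expr$values)]
  if (length(present) < length(ids))
    message(length(ids) - length(present),
            " transcript(s) missing from expression table; treated as 0")
  if (length(present))
    mx[present] <- apply(expr$values[present, , drop = FALSE], 1, max)
  ids[len >= min_len & mx >= min_fpkm]
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Twelve columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Malformed rows raise an error naming the
#' row number.
#'
#' @param path file path (no header).
#' @return data.frame with the twelve standard columns.
#' @export
read_blast6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
    return(out)
  }
  if (ncol(raw) != 12L)
    stop("expected 12 tab-separated columns in ", path, ", found ", ncol(raw))
  names(raw) <- cols
  num_cols <- cols[3:12]
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    if (anyNA(v))
      stop("malformed value in column ", cl, " at row ",
           which(is.na(v))[1L], " of ", path)
    raw[[cl]] <- v
  }
  raw
}

#' Flag transcripts with protein homology
#'
#' A transcript is flagged coding-by-homology iff it has any hit with bit
#' score at or above `min_bits` (inclusive boundary).
#'
#' @param ids transcript ids to assess.
#' @param hits data.frame as from [read_blast6()] (BLASTX-style, queries =
#'   transcripts).
#' @param min_bits bit-score cutoff (default 50).
#' @return Character vector: the flagged subset of `ids`.
#' @export
apply_homology_filter <- function(ids, hits, min_bits = 50.0) {
  if (is.null(hits) || nrow(hits) == 0L) return(character(0))
  if (any(hits$bitscore < 0)) stop("negative bit score in homology table")
  flagged <- unique(hits$qseqid[hits$bitscore >= min_bits])
  ids[ids %in% flagged]
}

#' Classify transcripts as coding or noncoding
#'
#' Per transcript: all sense-strand ORFs of at least `min_aa` codons are
#' found; the dynamic length cutoff for the transcript's length is computed
#' under `base_freqs`; the longest complete ORF is scored against the
#' hexamer model and start PSSM (when supplied). The verdict is `coding` iff
#' the longest complete ORF reaches the dynamic cutoff AND the composite
#' score favours coding (`ll_score > 0` or `start_pssm_score > 0`; when no
#' scoring model is supplied the score gate is open and length alone
#' decides), OR the transcript has a protein-homology hit at or above
#' `min_bits`. Everything else is `noncoding`.
#'
#' @param seqs named character vector of transcript sequences.
#' @param hits optional [read_blast6()] table of protein-homology hits.
#' @param alpha expected-count threshold of the dynamic cutoff.
#' @param min_bits homology bit-score cutoff (default 50).
#' @param min_aa minimum ORF length considered (default 50).
#' @param base_freqs base composition for the null model; NULL estimates it
#'   from the input sequences.
#' @param hexamer_model,start_pssm optional scoring models.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `length_nt`, `longest_orf_aa` (longest complete ORF; 0 if none),
#'   `dynamic_cutoff_aa`, `ll_score`, `start_pssm_score`, `homology_hit`,
#'   `verdict`.
#' @export
classify_coding <- function(seqs, hits = NULL, alpha = 0.05, min_bits = 50.0,
                            min_aa = 50L, base_freqs = NULL,
                            hexamer_model = NULL, start_pssm = NULL) {
  stopifnot(!is.null(names(seqs)))
  if (is.null(base_freqs)) {
    bases <- strsplit(paste(toupper(seqs), collapse = ""), "")[[1]]
    tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
    base_freqs <- as.vector(tab) / sum(tab)
    names(base_freqs) <- c("A", "C", "G", "T")
  }
  homology_ids <- apply_homology_filter(names(seqs), hits, min_bits = min_bits)
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    L <- nchar(s)
    cutoff <- dynamic_orf_cutoff(L, alpha = alpha, base_freqs = base_freqs,
                                 min_aa = min_aa)
    orfs <- find_orfs(s, min_aa = min_aa, transcript_id = id)
    comp <- orfs[orfs$complete, , drop = FALSE]
    longest <- if (nrow(comp)) max(comp$length_aa) else 0L
    ll <- 0; ps <- 0
    if (nrow(comp)) {
      best <- comp[which.max(comp$length_aa), , drop = FALSE]
      sc <- score_orf(best, s, hexamer_model, start_pssm)
      ll <- unname(sc["ll_score"]); ps <- unname(sc["start_pssm_score"])
    }
    score_gate <- if (is.null(hexamer_model) && is.null(start_pssm)) TRUE
                  else (ll > 0 || ps > 0)
    hom <- id %in% homology_ids
    verdict <- if ((longest >= cutoff && score_gate) || hom) "coding" else "noncoding"
    data.frame(transcript_id = id, length_nt = L, longest_orf_aa = longest,
               dynamic_cutoff_aa = cutoff, ll_score = ll,
               start_pssm_score = ps, homology_hit = hom,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file; record ids are taken up to the first whitespace.
#' @return Named character vector of sequences.
#' @export
read_transcript_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write transcript sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
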