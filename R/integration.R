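FUNNEL_FLAGS <- c("expressed", "novel", "noncoding", "podocyte_expressed",
                  "tsi_specific", "seq_conserved", "synteny_conserved",
                  "homology_clean", "human_expressed", "de_wt1", "de_podocin",
                  "de_adriamycin", "scrna_detected", "scrna_podocyte_specific")

#' Build candidate records
#'
#' Assembles the per-feature boolean flag vector that drives the candidate
#' funnel. All flags in the standard set must be supplied (missing ones
#' default to FALSE only if `fill = TRUE`).
#'
#' @param feature_id character vector of feature ids.
#' @param level `"transcript"` or `"locus"`.
#' @param ... named logical vectors, one per flag, each of the same length
#'   as `feature_id`.
#' @param fill if TRUE, flags not supplied are set to FALSE.
#' @return data.frame of candidate records.
#' @export
candidate_records <- function(feature_id, level = "transcript", ..., fill = FALSE) {
  flags <- list(...)
  out <- data.frame(feature_id = feature_id, level = level,
                    stringsAsFactors = FALSE)
  for (f in FUNNEL_FLAGS) {
    if (f %in% names(flags)) {
      v <- flags[[f]]
      stopifnot(length(v) == length(feature_id))
      out[[f]] <- as.logical(v)
    } else if (fill) {
      out[[f]] <- FALSE
    }
  }
  extra <- setdiff(names(flags), FUNNEL_FLAGS)
  if (length(extra)) stop("unknown flag(s): ", paste(extra, collapse = ", "))
  out
}

check_flags <- function(records, flags) {
  miss <- setdiff(flags, names(records))
  if (length(miss))
    stop("missing flag column(s): ", paste(miss, collapse = ", "))
  for (f in flags) {
    bad <- which(is.na(records[[f]]))
    if (length(bad))
      stop("flag ", f, " is NA for feature ", records$feature_id[bad[1L]])
  }
}

#' Candidate funnel and set-intersection summary
#'
#' Applies the evidence tiers in order: T1 expressed noncoding (lncRNA)
#' features; T2 = T1 and podocyte-expressed; T3 = T2 and TSI-specific;
#' T4 = T3 and conserved (sequence or synteny) and clean of protein
#' homology; T5 = T4 and differentially expressed in at least one disease
#' model. Because the tiers are conjunctions, the final set is independent
#' of the stage order. Alongside, the intersection counts over all observed
#' combinations of the funnel flags are emitted (upset-style); they
#' partition T1.
#'
#' @param records data.frame from [candidate_records()].
#' @return List: `tiers` (tier, n, plus list column `members`), `upset`
#'   (one row per observed flag combination with its count), `records`
#'   (input with a `tier` column = deepest tier reached).
#' @export
build_funnel <- function(records) {
  need <- c("expressed", "noncoding", "podocyte_expressed", "tsi_specific",
            "seq_conserved", "synteny_conserved", "homology_clean",
            "de_wt1", "de_podocin", "de_adriamycin")
  check_flags(records, need)
  t1 <- records$expressed & records$noncoding
  t2 <- t1 & records$podocyte_expressed
  t3 <- t2 & records$tsi_specific
  t4 <- t3 & (records$seq_conserved | records$synteny_conserved) &
    records$homology_clean
  t5 <- t4 & (records$de_wt1 | records$de_podocin | records$de_adriamycin)
  tier_sets <- list(T1 = t1, T2 = t2, T3 = t3, T4 = t4, T5 = t5)
  tiers <- data.frame(
    tier = names(tier_sets),
    n = vapply(tier_sets, sum, integer(1)),
    stringsAsFactors = FALSE)
  tiers$members <- I(lapply(tier_sets, function(s) sort(records$feature_id[s])))
  rownames(tiers) <- NULL
  upset_flags <- c("podocyte_expressed", "tsi_specific", "seq_conserved",
                   "synteny_conserved", "homology_clean",
                   "de_wt1", "de_podocin", "de_adriamycin")
  combo <- apply(records[t1, upset_flags, drop = FALSE], 1,
                 function(r) paste(ifelse(r, "1", "0"), collapse = ""))
  upset <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(upset) <- c("combination", "n")
  attr(upset, "flags") <- upset_flags
  depth <- rowSums(cbind(t1, t2, t3, t4, t5))
  records$tier <- ifelse(depth == 0, NA_character_, paste0("T", depth))
  list(tiers = tiers, upset = upset, records = records)
}

#' Roll transcript-level records up to gene loci
#'
#' Locus flags for specificity/conservation evidence are the OR over member
#' transcripts; DE flags are native to the locus level and supplied
#' separately. Transcripts without a locus assignment raise an error.
#'
#' @param records transcript-level [candidate_records()].
#' @param tx2locus named character vector transcript_id -> locus_id (see
#'   [locus_map()]).
#' @param locus_de optional data.frame (`locus_id`, `de_wt1`, `de_podocin`,
#'   `de_adriamycin`) of locus-level DE calls.
#' @return Locus-level candidate records data.frame.
#' @export
transcript_to_locus_rollup <- function(records, tx2locus, locus_de = NULL) {
  orphan <- setdiff(records$feature_id, names(tx2locus))
  if (length(orphan))
    stop("transcript(s) without locus assignment: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  loc <- tx2locus[records$feature_id]
  or_flags <- setdiff(intersect(FUNNEL_FLAGS, names(records)),
                      c("de_wt1", "de_podocin", "de_adriamycin"))
  agg <- lapply(split(seq_len(nrow(records)), loc), function(idx) {
    row <- data.frame(feature_id = loc[idx][1L], level = "locus",
                      stringsAsFactors = FALSE)
    for (f in or_flags) row[[f]] <- any(records[[f]][idx])
    row
  })
  out <- do.call(rbind, agg)
  for (f in c("de_wt1", "de_podocin", "de_adriamycin")) {
    if (!is.null(locus_de) && f %in% names(locus_de)) {
      m <- match(out$feature_id, locus_de$locus_id)
      out[[f]] <- !is.na(m) & locus_de[[f]][m]
    } else if (f %in% names(records)) {
      out[[f]] <- vapply(split(records[[f]], loc)[out$feature_id], any, logical(1))
    } else out[[f]] <- FALSE
  }
  out <- out[order(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
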