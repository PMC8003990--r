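#' Tissue specificity index across compartments
#'
#' For each feature, expression is averaged per compartment (arithmetic mean
#' of FPKM over that compartment's samples) and the tissue specificity index
#' is the maximal compartment fraction,
#' TSI = max(means) / sum(means), bounded in \[1/N, 1\] for N compartments:
#' 1/N when expression is uniform, 1 when confined to one compartment. A
#' feature with zero expression everywhere gets `tsi = NA` and
#' `specific = FALSE`. The top compartment is the argmax; ties are broken by
#' the fixed priority podocyte > glomerulus > kidney, then alphabetically.
#'
#' @param expr an `expression_table` with at least 2 compartments.
#' @param feature_ids features to score (default: all rows).
#' @param threshold TSI at or above which a feature is called specific
#'   (default 0.8, inclusive).
#' @return data.frame: `feature_id`, one `mean_<compartment>` column per
#'   compartment, `tsi`, `top_compartment`, `specific`.
#' @export
compute_tsi <- function(expr, feature_ids = NULL, threshold = 0.8) {
  stopifnot(inherits(expr, "expression_table"))
  comps <- unique(expr$compartment)
  if (length(comps) < 2L) stop("need at least 2 compartments")
  pri <- c("podocyte", "glomerulus", "kidney")
  comps <- c(intersect(pri, comps), sort(setdiff(comps, pri)))
  if (is.null(feature_ids)) feature_ids <- rownames(expr$values)
  missing <- setdiff(feature_ids, rownames(expr$values))
  if (length(missing)) stop("features not in table: ", paste(missing, collapse = ", "))
  v <- expr$values[feature_ids, , drop = FALSE]
  means <- vapply(comps, function(cc) {
    rowMeans(v[, expr$compartment == cc, drop = FALSE])
  }, numeric(nrow(v)))
  means <- matrix(means, nrow = length(feature_ids),
                  dimnames = list(feature_ids, comps))
  tot <- rowSums(means)
  tsi <- ifelse(tot > 0, apply(means, 1, max) / tot, NA_real_)
  top <- comps[apply(means, 1, which.max)]   # which.max: first max = priority order
  top[tot == 0] <- NA_character_
  out <- data.frame(feature_id = feature_ids, stringsAsFactors = FALSE)
  for (cc in comps) out[[paste0("mean_", cc)]] <- means[, cc]
  out$tsi <- tsi
  out$top_compartment <- top
  out$specific <- !is.na(tsi) & tsi >= threshold
  rownames(out) <- NULL
  out
}

#' Podocyte-specific feature set
#'
#' Features called specific at `threshold` whose top compartment is the
#' podocyte.
#'
#' @param results output of [compute_tsi()].
#' @param threshold TSI threshold (default 0.8, inclusive).
#' @return Character vector of feature ids.
#' @export
podocyte_specific_set <- function(results, threshold = 0.8) {
  keep <- !is.na(results$tsi) & results$tsi >= threshold &
    results$top_compartment == "podocyte"
  results$feature_id[keep]
}
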