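#' Construct an annotation set
#'
#' An `annotation_set` is the package's container for exon-structured
#' transcript models on a genome. It holds two data frames: a transcript
#' table (one row per transcript: `transcript_id`, `gene_id`, `chrom`,
#' `strand`, `biotype`) and an exon table (`transcript_id`, `start`, `end`).
#' Coordinates are 1-based closed throughout, the native convention of GTF
#' and of the Bioconductor ranges infrastructure.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"` or `"-"`), `biotype` (one of `"coding"`,
#'   `"noncoding"`, `"unknown"`).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (1-based closed intervals).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(transcripts, exons) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  need_t <- c("transcript_id", "gene_id", "chrom", "strand", "biotype")
  if (!all(need_t %in% names(transcripts)))
    stop("transcript table must have columns: ", paste(need_t, collapse = ", "))
  if (!all(c("transcript_id", "start", "end") %in% names(exons)))
    stop("exon table must have columns: transcript_id, start, end")
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id in annotation set")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(transcripts$biotype %in% c("coding", "noncoding", "unknown")))
    stop("biotype must be coding, noncoding or unknown")
  if (any(exons$end < exons$start))
    stop("exon end < start")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon rows refer to unknown transcript_id")
  if (!all(transcripts$transcript_id %in% exons$transcript_id))
    stop("transcript without exons")
  ## canonicalize: exons sorted by start within transcript, in transcript order
  ord <- order(match(exons$transcript_id, transcripts$transcript_id), exons$start)
  exons <- exons[ord, c("transcript_id", "start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  ## non-overlap check per transcript
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1L] <= e[-length(e)]))
        stop("overlapping exons within transcript ", exons$transcript_id[idx[1L]])
    }
  }
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  tab <- table(x$transcripts$biotype)
  cat("  biotypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Spliced transcript lengths
#'
#' Sum of exon lengths per transcript.
#'
#' @param annot an `annotation_set`.
#' @return Named integer vector (names = transcript ids).
#' @export
spliced_length <- function(annot) {
  stopifnot(inherits(annot, "annotation_set"))
  len <- tapply(annot$exons$end - annot$exons$start + 1L,
                annot$exons$transcript_id, sum)
  out <- as.integer(len[annot$transcripts$transcript_id])
  names(out) <- annot$transcripts$transcript_id
  out
}

## intron chain key per transcript: "chrom|strand|s1-e1,s2-e2,..." (introns,
## 1-based closed); mono-exonic transcripts have an empty chain part.
intron_chain_keys <- function(annot) {
  ex <- annot$exons
  by_tx <- split(seq_len(nrow(ex)), ex$transcript_id)
  tx <- annot$transcripts
  keys <- vapply(tx$transcript_id, function(id) {
    idx <- by_tx[[id]]
    if (length(idx) < 2L) return(NA_character_)
    s <- ex$start[idx]; e <- ex$end[idx]
    paste0(e[-length(e)] + 1L, "-", s[-1L] - 1L, collapse = ",")
  }, character(1))
  ifelse(is.na(keys), NA_character_,
         paste(tx$chrom, tx$strand, keys, sep = "|"))
}

tx_span <- function(annot) {
  ex <- annot$exons
  s <- tapply(ex$start, ex$transcript_id, min)
  e <- tapply(ex$end, ex$transcript_id, max)
  ids <- annot$transcripts$transcript_id
  data.frame(transcript_id = ids,
             chrom = annot$transcripts$chrom,
             strand = annot$transcripts$strand,
             start = as.integer(s[ids]), end = as.integer(e[ids]),
             stringsAsFactors = FALSE)
}

#' Read a GTF file into an annotation set
#'
#' Parses GTF 2.2 (1-based closed coordinates) via rtracklayer, keeping exon
#' records. Biotype is taken from the `gene_biotype` (or `transcript_biotype`)
#' attribute: `protein_coding` maps to `"coding"`, any other stated biotype to
#' `"noncoding"`, a missing attribute to `"unknown"`.
#'
#' @param path GTF file path.
#' @param on_missing_id what to do with exon records lacking a
#'   `transcript_id` attribute: `"error"` (default) or `"skip"` (drop the
#'   record with a message).
#' @return An `annotation_set`.
#' @export
read_gtf <- function(path, on_missing_id = c("error", "skip")) {
  on_missing_id <- match.arg(on_missing_id)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  mc <- S4Vectors::mcols(gr)
  txid <- as.character(mc$transcript_id)
  bad <- is.na(txid) | txid == ""
  if (any(bad)) {
    if (on_missing_id == "error")
      stop(sum(bad), " exon record(s) without transcript_id in ", path)
    message("skipping ", sum(bad), " exon record(s) without transcript_id")
    gr <- gr[!bad]; mc <- S4Vectors::mcols(gr); txid <- as.character(mc$transcript_id)
  }
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else txid
  gid[is.na(gid) | gid == ""] <- txid[is.na(gid) | gid == ""]
  bt_attr <- rep(NA_character_, length(gr))
  for (col in c("gene_biotype", "transcript_biotype", "gene_type")) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      bt_attr[is.na(bt_attr) & !is.na(v)] <- v[is.na(bt_attr) & !is.na(v)]
    }
  }
  biotype <- ifelse(is.na(bt_attr), "unknown",
                    ifelse(bt_attr == "protein_coding", "coding", "noncoding"))
  exons <- data.frame(transcript_id = txid,
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  first <- !duplicated(txid)
  transcripts <- data.frame(
    transcript_id = txid[first],
    gene_id = gid[first],
    chrom = as.character(GenomicRanges::seqnames(gr))[first],
    strand = as.character(GenomicRanges::strand(gr))[first],
    biotype = biotype[first],
    stringsAsFactors = FALSE)
  annotation_set(transcripts, exons)
}

#' Write an annotation set to GTF
#'
#' Emits one exon record per exon with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes. Output is deterministic (no timestamp header),
#' and `read_gtf(write_gtf(x))` preserves coordinates, strand, ids and
#' biotypes.
#'
#' @param annot an `annotation_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annot, path) {
  stopifnot(inherits(annot, "annotation_set"))
  ex <- annot$exons
  tx <- annot$transcripts
  i <- match(ex$transcript_id, tx$transcript_id)
  bt <- c(coding = "protein_coding", noncoding = "lncRNA", unknown = NA_character_)
  gr <- GenomicRanges::GRanges(
    tx$chrom[i], IRanges::IRanges(ex$start, ex$end), strand = tx$strand[i])
  S4Vectors::mcols(gr)$source <- "podlnc"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- tx$gene_id[i]
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$gene_biotype <- unname(bt[tx$biotype[i]])
  tmp <- tempfile(fileext = ".gtf")
  rtracklayer::export(gr, tmp, format = "gtf")
  lines <- readLines(tmp)
  unlink(tmp)
  writeLines(lines[!startsWith(lines, "##")], path)
  invisible(path)
}

#' Classify assembled transcripts as known or novel
#'
#' A multi-exon transcript is "known" iff some reference transcript on the
#' same chromosome and strand has an identical intron chain (identical set of
#' intron intervals; terminal exon ends are ignored). A mono-exonic
#' transcript is "known" iff a same-strand mono-exonic reference transcript
#' reciprocally overlaps at least 50 percent of both lengths. Everything else
#' is "novel".
#'
#' @param assembled,reference `annotation_set`s sharing chromosome naming.
#' @return Named character vector (`"known"`/`"novel"`) over assembled
#'   transcript ids.
#' @export
classify_transcripts <- function(assembled, reference) {
  stopifnot(inherits(assembled, "annotation_set"),
            inherits(reference, "annotation_set"))
  ids <- assembled$transcripts$transcript_id
  out <- rep("novel", length(ids)); names(out) <- ids
  if (nrow(reference$transcripts) == 0L) {
    warning("empty reference annotation: all transcripts classified novel")
    return(out)
  }
  a_keys <- intron_chain_keys(assembled)
  r_keys <- intron_chain_keys(reference)
  multi <- !is.na(a_keys)
  out[multi][a_keys[multi] %in% r_keys[!is.na(r_keys)]] <- "known"

  ## mono-exonic: reciprocal >= 50% overlap with a same-strand mono-exonic ref
  a_sp <- tx_span(assembled); r_sp <- tx_span(reference)
  a_mono <- a_sp[is.na(a_keys), , drop = FALSE]
  r_mono <- r_sp[is.na(r_keys), , drop = FALSE]
  if (nrow(a_mono) && nrow(r_mono)) {
    ag <- GenomicRanges::GRanges(a_mono$chrom,
                                 IRanges::IRanges(a_mono$start, a_mono$end),
                                 strand = a_mono$strand)
    rg <- GenomicRanges::GRanges(r_mono$chrom,
                                 IRanges::IRanges(r_mono$start, r_mono$end),
                                 strand = r_mono$strand)
    hits <- GenomicRanges::findOverlaps(ag, rg, ignore.strand = FALSE)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- pmin(a_mono$end[qi], r_mono$end[si]) -
        pmax(a_mono$start[qi], r_mono$start[si]) + 1L
      la <- a_mono$end[qi] - a_mono$start[qi] + 1L
      lr <- r_mono$end[si] - r_mono$start[si] + 1L
      ok <- ov >= 0.5 * la & ov >= 0.5 * lr
      out[a_mono$transcript_id[unique(qi[ok])]] <- "known"
    }
  }
  out
}

#' Bundle noncoding transcripts into gene loci
#'
#' Single-linkage clustering of transcripts by same-strand exonic overlap of
#' at least 1 bp; antisense transcripts form separate loci. Locus ids are
#' assigned deterministically from (chrom, span start, strand) as
#' `LOC_<chrom>_<start>_<strand>`, so a locus keeps its id regardless of
#' which other loci are present. Every transcript lands in exactly one
#' locus.
#'
#' @param candidates `annotation_set` containing only noncoding transcripts.
#' @return data.frame with columns `locus_id`, `chrom`, `strand`, `start`,
#'   `end`, `n_transcripts` and a list column `transcript_ids`.
#' @export
bundle_loci <- function(candidates) {
  stopifnot(inherits(candidates, "annotation_set"))
  if (any(candidates$transcripts$biotype == "coding"))
    stop("bundle_loci: coding transcripts present; exclude them first")
  tx <- candidates$transcripts
  ex <- candidates$exons
  i <- match(ex$transcript_id, tx$transcript_id)
  eg <- GenomicRanges::GRanges(tx$chrom[i],
                               IRanges::IRanges(ex$start, ex$end),
                               strand = tx$strand[i])
  ## union-find over transcripts, linked through reduced exonic islands
  n <- nrow(tx)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  red <- GenomicRanges::reduce(eg, ignore.strand = FALSE)
  hits <- GenomicRanges::findOverlaps(eg, red, ignore.strand = FALSE)
  tx_of_exon <- i[S4Vectors::queryHits(hits)]
  island <- S4Vectors::subjectHits(hits)
  for (grp in split(tx_of_exon, island)) {
    u <- unique(grp)
    if (length(u) > 1L) for (k in 2:length(u)) union2(u[1L], u[k])
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sp <- tx_span(candidates)
  loci <- lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom = tx$chrom[idx[1L]], strand = tx$strand[idx[1L]],
               start = min(sp$start[idx]), end = max(sp$end[idx]),
               n_transcripts = length(idx), stringsAsFactors = FALSE,
               transcript_ids = I(list(sort(tx$transcript_id[idx]))))
  })
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  out <- cbind(locus_id = paste0("LOC_", out$chrom, "_", out$start, "_",
                                 ifelse(out$strand == "+", "p", "m")),
               out)
  if (anyDuplicated(out$locus_id))
    out$locus_id <- make.unique(out$locus_id, sep = "_")
  rownames(out) <- NULL
  out
}

#' Map transcript ids to locus ids
#'
#' @param loci output of [bundle_loci()].
#' @return Named character vector transcript_id -> locus_id.
#' @export
locus_map <- function(loci) {
  ids <- rep(loci$locus_id, lengths(loci$transcript_ids))
  names(ids) <- unlist(loci$transcript_ids)
  ids
}

#' Read an expression table with compartment labels
#'
#' The expression table is TSV with feature ids in the first column and one
#' column per sample (FPKM or TPM, non-negative). The sample sheet is a TSV
#' mapping `sample` to `compartment` (e.g. podocyte, glomerulus, kidney);
#' every expression column must appear exactly once.
#'
#' @param path expression TSV.
#' @param samples_path sample sheet TSV with columns `sample`, `compartment`.
#' @return An `expression_table`: list with `values` (features x samples
#'   matrix) and `compartment` (named character vector per sample).
#' @export
read_expression_table <- function(path, samples_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "compartment") %in% names(ss)))
    stop("sample sheet needs columns sample, compartment")
  expression_table(m, stats::setNames(ss$compartment, ss$sample))
}

#' Construct an expression table
#'
#' @param values features x samples numeric matrix, non-negative.
#' @param compartment named character vector: compartment label per sample
#'   (names must cover every column of `values`).
#' @return An `expression_table`.
#' @export
expression_table <- function(values, compartment) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("negative expression values")
  if (!all(colnames(values) %in% names(compartment)))
    stop("every sample column needs a compartment label")
  structure(list(values = values,
                 compartment = compartment[colnames(values)]),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  tab <- table(x$compartment)
  cat("expression_table:", nrow(x$values), "features x", ncol(x$values),
      "samples (", paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}
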