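## Readers and writers. One internal convention: everything is held as
## 1-based closed GRanges / 1-based track positions; every off-by-one
## conversion from a source dialect (BED and refFlat are 0-based half-open,
## WIG is 1-based) happens here and nowhere else.

.readLinesNoEmpty <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track |browser )", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read ChIP peaks (or any intervals) from a BED3+ file
#'
#' Accepts BED3 to BED6. Column 4 is used as the peak identifier and
#' column 5 as the enrichment score (fold over input) when present;
#' otherwise identifiers `peak_00001, ...` are generated after sorting
#' and enrichment is `NA`.
#'
#' @param path path to a BED file (0-based half-open coordinates).
#' @return a [GenomicRanges::GRanges], sorted by chromosome and start,
#'   with metadata columns `peak_id` and `enrichment`. Center positions
#'   (see [peakCenter()]) follow `start + floor(width/2)`.
#' @export
readPeaks <- function(path) {
  src <- .readLinesNoEmpty(path)
  if (!length(src$lines)) {
    gr <- GRanges()
    mcols(gr)$peak_id <- character(0)
    mcols(gr)$enrichment <- numeric(0)
    return(gr)
  }
  fields <- strsplit(src$lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stopf("malformed BED line %d: fewer than 3 fields",
           src$lineno[which(nf < 3L)[1]])
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(s0) | is.na(e0)
  if (any(bad))
    .stopf("malformed BED line %d: non-integer coordinates",
           src$lineno[which(bad)[1]])
  if (any(s0 >= e0))
    .stopf("malformed BED line %d: start >= end", src$lineno[which(s0 >= e0)[1]])
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4L], ""), NA_character_)
  score <- suppressWarnings(
    as.numeric(ifelse(nf >= 5L, vapply(fields, function(f) f[5L], ""), NA)))
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0))
  mcols(gr)$peak_id <- name
  mcols(gr)$enrichment <- score
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  if (anyNA(mcols(gr)$peak_id))
    mcols(gr)$peak_id <- sprintf("peak_%05d", seq_along(gr))
  gr
}

#' Write intervals to BED
#'
#' @param gr a `GRanges` with optional `peak_id` / `enrichment` metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(gr, path) {
  id <- mcols(gr)$peak_id
  if (is.null(id)) id <- sprintf("peak_%05d", seq_along(gr))
  enr <- mcols(gr)$enrichment
  if (is.null(enr)) enr <- rep(NA_real_, length(gr))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                   as.character(seqnames(gr)), start(gr) - 1L, end(gr), id,
                   ifelse(is.na(enr), "0", sprintf("%.6g", enr)))
  writeLines(lines, path)
  invisible(path)
}

.parseCommaInts <- function(x) as.integer(strsplit(x, ",")[[1]])

.validateGeneModel <- function(gene_id, chrom, strandc, s0, e0, ex0s, ex0e, lineno) {
  if (!strandc %in% c("+", "-"))
    .stopf("gene model line %d (%s): unknown strand '%s'", lineno, gene_id, strandc)
  if (is.na(s0) || is.na(e0) || s0 >= e0)
    .stopf("gene model line %d (%s): invalid transcript bounds", lineno, gene_id)
  if (length(ex0s) != length(ex0e) || !length(ex0s))
    .stopf("gene model line %d (%s): malformed exon list", lineno, gene_id)
  o <- order(ex0s)
  ex0s <- ex0s[o]; ex0e <- ex0e[o]
  if (any(ex0s >= ex0e))
    .stopf("gene model line %d (%s): empty exon", lineno, gene_id)
  if (any(ex0s < s0) || any(ex0e > e0))
    .stopf("gene model line %d (%s): exon outside transcript bounds",
           lineno, gene_id)
  if (length(ex0s) > 1L && any(ex0s[-1L] < ex0e[-length(ex0e)]))
    .stopf("gene model line %d (%s): overlapping exons", lineno, gene_id)
  list(s = ex0s, e = ex0e)
}

#' Read gene models from refFlat or BED12
#'
#' The dialect is auto-detected from the column count (11 = refFlat,
#' 12 = BED12). Both dialects are converted to the same internal
#' representation, so a transcript written in one dialect and re-read in
#' the other yields an identical exon structure. The strand-aware TSS is
#' `start` on `+` genes and `end` on `-` genes.
#'
#' @param path path to a refFlat or BED12 file.
#' @param format `"auto"`, `"refflat"` or `"bed12"`.
#' @return a `GRanges` of transcripts with metadata columns `gene_id`
#'   (unique) and `exons` (an `IRangesList` in absolute coordinates,
#'   sorted by genomic start, disjoint).
#' @export
readGeneModels <- function(path, format = c("auto", "refflat", "bed12")) {
  format <- match.arg(format)
  src <- .readLinesNoEmpty(path)
  if (!length(src$lines)) {
    gr <- GRanges()
    mcols(gr)$gene_id <- character(0)
    mcols(gr)$exons <- IRangesList()
    return(gr)
  }
  fields <- strsplit(src$lines, "\t")
  nf <- lengths(fields)
  if (format == "auto") {
    format <- if (all(nf == 12L)) "bed12"
              else if (all(nf == 11L)) "refflat"
              else .stopf("cannot detect gene-model dialect (line %d has %d fields)",
                          src$lineno[1], nf[1])
  }
  n <- length(fields)
  gene_id <- character(n); chrom <- character(n); strandc <- character(n)
  s0 <- integer(n); e0 <- integer(n); exl <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (format == "refflat") {
      if (length(f) != 11L)
        .stopf("malformed refFlat line %d: expected 11 fields", src$lineno[i])
      gene_id[i] <- f[1L]; chrom[i] <- f[3L]; strandc[i] <- f[4L]
      s0[i] <- as.integer(f[5L]); e0[i] <- as.integer(f[6L])
      ex <- .validateGeneModel(gene_id[i], chrom[i], strandc[i], s0[i], e0[i],
                               .parseCommaInts(f[10L]), .parseCommaInts(f[11L]),
                               src$lineno[i])
      exl[[i]] <- ex
    } else {
      if (length(f) != 12L)
        .stopf("malformed BED12 line %d: expected 12 fields", src$lineno[i])
      gene_id[i] <- f[4L]; chrom[i] <- f[1L]; strandc[i] <- f[6L]
      s0[i] <- as.integer(f[2L]); e0[i] <- as.integer(f[3L])
      sizes <- .parseCommaInts(f[11L]); offs <- .parseCommaInts(f[12L])
      ex <- .validateGeneModel(gene_id[i], chrom[i], strandc[i], s0[i], e0[i],
                               s0[i] + offs, s0[i] + offs + sizes, src$lineno[i])
      exl[[i]] <- ex
    }
  }
  if (anyDuplicated(gene_id))
    .stopf("duplicated gene_id: %s", gene_id[duplicated(gene_id)][1])
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0), strand = strandc)
  mcols(gr)$gene_id <- gene_id
  mcols(gr)$exons <- IRangesList(lapply(exl, function(x) IRanges(x$s + 1L, x$e)))
  gr[order(as.character(seqnames(gr)), start(gr))]
}

#' Write gene models to refFlat or BED12
#'
#' @param genes a `GRanges` as returned by [readGeneModels()].
#' @param path output path.
#' @param format `"refflat"` or `"bed12"`.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path, format = c("refflat", "bed12")) {
  format <- match.arg(format)
  lines <- vapply(seq_along(genes), function(i) {
    ex <- mcols(genes)$exons[[i]]
    id <- mcols(genes)$gene_id[i]
    chrom <- as.character(seqnames(genes))[i]
    st <- as.character(strand(genes))[i]
    s0 <- start(genes)[i] - 1L; e0 <- end(genes)[i]
    if (format == "refflat") {
      sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
              id, id, chrom, st, s0, e0, s0, e0, length(ex),
              paste0(paste(start(ex) - 1L, collapse = ","), ","),
              paste0(paste(end(ex), collapse = ","), ","))
    } else {
      sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
              chrom, s0, e0, id, st, s0, e0, length(ex),
              paste0(paste(width(ex), collapse = ","), ","),
              paste0(paste(start(ex) - 1L - s0, collapse = ","), ","))
    }
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base conservation score track
#'
#' Reads bedGraph or fixed-step WIG (via \pkg{rtracklayer}) into a
#' run-length encoded per-chromosome score list. Scores must lie in
#' `[0, 1]` (the PhastCons range); anything else is an error. When records
#' overlap, the later record wins. Positions absent from the track score 0
#' (see [trackScores()]).
#'
#' @param path path to a bedGraph or WIG file.
#' @param format `"auto"` (by extension), `"bedgraph"` or `"wig"`.
#' @return an [IRanges::RleList], one numeric `Rle` per chromosome.
#' @export
readTrack <- function(path, format = c("auto", "bedgraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(wig|wiggle)$", path, ignore.case = TRUE)) "wig"
              else "bedgraph"
  }
  gr <- rtracklayer::import(path,
                            format = if (format == "wig") "wig" else "bedGraph")
  sc <- mcols(gr)$score
  if (any(sc < 0 | sc > 1))
    .stopf("track score outside [0, 1]: %g", sc[which(sc < 0 | sc > 1)[1]])
  chroms <- unique(as.character(seqnames(gr)))
  out <- lapply(chroms, function(ch) {
    g <- gr[as.character(seqnames(gr)) == ch]
    buf <- numeric(max(end(g)))
    s <- start(g); e <- end(g); v <- mcols(g)$score
    for (i in seq_along(g))          # file order: last record wins
      buf[s[i]:e[i]] <- v[i]
    Rle(buf)
  })
  names(out) <- chroms
  RleList(out, compress = FALSE)
}

#' Write a conservation track to bedGraph
#'
#' Zero-score runs are omitted (absent positions default to 0 on reading).
#'
#' @param track an `RleList` of scores in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    r <- track[[ch]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r) + 1L
    keep <- runValue(r) != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.6g", ch, starts[keep] - 1L, ends[keep],
                       runValue(r)[keep]), con)
  }
  invisible(path)
}

#' Look up track scores at positions
#'
#' @param track an `RleList` from [readTrack()].
#' @param chrom a chromosome name.
#' @param pos integer positions (1-based). Positions outside the track
#'   (including unknown chromosomes) score 0.
#' @return numeric vector of scores, same length as `pos`.
#' @export
trackScores <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  if (!chrom %in% names(track)) return(out)
  r <- track[[chrom]]
  ok <- pos >= 1L & pos <= length(r)
  if (any(ok)) out[ok] <- as.numeric(r[pos[ok]])
  out
}

#' Read an expression table
#'
#' Tab-separated with a header; requires columns `gene_id`,
#' `fpkm_control`, `fpkm_sh1`, `fpkm_sh2` (two independent shRNA
#' knockdowns against one control). Additional columns (e.g. raw counts)
#' are carried through untouched.
#'
#' @param path path to the TSV file.
#' @return a `data.frame`.
#' @export
readExpression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "fpkm_control", "fpkm_sh1", "fpkm_sh2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("expression table missing column(s): %s", paste(miss, collapse = ", "))
  fp <- as.matrix(df[, need[-1]])
  if (any(fp < 0)) .stopf("negative FPKM in expression table")
  if (anyDuplicated(df$gene_id))
    .stopf("duplicated gene_id in expression table: %s",
           df$gene_id[duplicated(df$gene_id)][1])
  df
}

#' Write an expression table
#'
#' @param df a `data.frame` as from [readExpression()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
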