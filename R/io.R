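# Readers and writers for BED-like peak files, bedGraph tracks and gene
# tables. Files use the standard 0-based half-open BED convention; objects
# use 1-based closed GRanges coordinates. Writers emit sorted, tab-separated,
# LF-terminated text so that identical inputs give byte-identical files.

#' Read a BED3+ peak file into a PeakSet
#'
#' Columns 1-3 are chrom, start, end (0-based half-open). An optional summit
#' column holds the absolute 0-based summit position; when absent the summit
#' defaults to the floor midpoint of the interval. Column 5, when present,
#' is taken as the peak score.
#'
#' @param path Path to the BED file.
#' @param factorName,genotype,treatment Condition labels for the set.
#' @param summitCol Integer column index (1-based) of the absolute summit
#'   position, or `NULL` (default) for the midpoint rule.
#' @param scoreCol Integer column index of the score; default 5 when the file
#'   has at least 5 columns.
#' @return A [PeakSet-class].
#' @export
readPeakBed <- function(path, factorName, genotype, treatment,
                        summitCol = NULL, scoreCol = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(PeakSet(GenomicRanges::GRanges(summit = integer(),
                                          score = numeric()),
                   factorName, genotype, treatment))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3L)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                 bad[1L], path))
  need <- max(3L, summitCol %||% 0L, scoreCol %||% 0L)
  bad <- which(ncols < need)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: expected >= %d columns",
                 bad[1L], path, need))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-integer coordinates",
                 bad[1L], path))
  bad <- which(end0 <= start0 | start0 < 0L)
  if (length(bad))
    stop(sprintf("invalid interval on line %d in %s: need 0 <= start < end",
                 bad[1L], path))
  key <- paste(chrom, start0, end0)
  if (anyDuplicated(key))
    stop(sprintf("duplicate peak interval on line %d in %s",
                 which(duplicated(key))[1L], path))
  if (is.null(scoreCol) && all(ncols >= 5L)) scoreCol <- 5L
  score <- if (!is.null(scoreCol)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", scoreCol)))
    ifelse(is.na(sc), 0, sc)
  } else rep(0, length(chrom))
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = start0 + 1L, end = end0))
  if (!is.null(summitCol)) {
    s0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", summitCol)))
    bad <- which(is.na(s0))
    if (length(bad))
      stop(sprintf("malformed summit on line %d in %s", bad[1L], path))
    S4Vectors::mcols(gr)$summit <- s0 + 1L
  }
  S4Vectors::mcols(gr)$score <- score
  PeakSet(gr, factorName, genotype, treatment)
}

#' Write a PeakSet as BED6 + absolute summit column (column 7, 0-based)
#'
#' @param x A [PeakSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePeakBed <- function(x, path) {
  p <- peaks(x)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t%d",
                   as.character(GenomicRanges::seqnames(p)),
                   GenomicRanges::start(p) - 1L, GenomicRanges::end(p),
                   paste0("peak_", seq_along(p)),
                   formatNum(S4Vectors::mcols(p)$score),
                   S4Vectors::mcols(p)$summit - 1L)
  writeLinesLF(lines, path)
  invisible(path)
}

#' Read a 4-column bedGraph into a SignalTrack
#'
#' Steps are validated (nonnegative values, no overlapping steps) and sorted.
#' The normalization factor defaults to `1e6 / totalMass` with
#' `totalMass = sum(value * width)`; pass `normFactor` to override (e.g. when
#' tracks are already depth-matched).
#'
#' @param path Path to the bedGraph file.
#' @param normFactor Optional override of the signal-per-million factor.
#' @return A [SignalTrack-class].
#' @export
readBedGraph <- function(path, normFactor = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    return(SignalTrack(GenomicRanges::GRanges(score = numeric()),
                       normFactor = normFactor %||% 1))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1L))
  if (ncol(dt) != 4L)
    stop("bedGraph must have exactly 4 columns: ", path)
  chrom <- dt[[1L]]
  start0 <- as.integer(dt[[2L]]); end0 <- as.integer(dt[[3L]])
  value <- as.numeric(dt[[4L]])
  if (any(is.na(start0) | is.na(end0) | is.na(value)))
    stop("non-numeric coordinates or values in ", path)
  if (any(end0 <= start0 | start0 < 0L))
    stop("invalid step interval (need 0 <= start < end) in ", path)
  if (any(value < 0)) stop("negative signal value in ", path)
  o <- order(chrom, start0)
  chrom <- chrom[o]; start0 <- start0[o]; end0 <- end0[o]; value <- value[o]
  n <- length(chrom)
  if (n > 1L) {
    same <- chrom[-n] == chrom[-1L]
    if (any(same & end0[-n] > start0[-1L]))
      stop("overlapping steps in ", path)
  }
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = start0 + 1L, end = end0), score = value)
  SignalTrack(gr, normFactor = normFactor)
}

#' Write a SignalTrack as bedGraph
#' @param x A [SignalTrack-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(x, path) {
  st <- trackSteps(x)
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(st)),
                   GenomicRanges::start(st) - 1L, GenomicRanges::end(st),
                   formatNum(S4Vectors::mcols(st)$score))
  writeLinesLF(lines, path)
  invisible(path)
}

#' Read a gene table (TSV with header gene_id, chrom, tss, strand)
#'
#' The `tss` column in the file is a 0-based position (BED-style); internally
#' the table carries the 1-based position, consistent with GRanges.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `gene_id`, `chrom`, `tss` (1-based
#'   integer), `strand` (`"+"`/`"-"`), sorted by `gene_id`.
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "character"))
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!identical(names(df), req))
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  geneTable(df$gene_id, df$chrom, df$tss + 1L, df$strand)
}

#' Build and validate a gene table
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param tss 1-based TSS positions.
#' @param strand `"+"` or `"-"`.
#' @return data.frame sorted by `gene_id`.
#' @export
geneTable <- function(gene_id, chrom, tss, strand) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         strand[!strand %in% c("+", "-")][1L])
  if (any(tss < 1L)) stop("tss positions must be >= 1 (1-based)")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   tss = as.integer(tss), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  df[order(df$gene_id), , drop = FALSE]
}

#' Write a gene table as TSV (tss written 0-based)
#' @param genes A gene table data.frame ([geneTable]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  lines <- c("gene_id\tchrom\ttss\tstrand",
             sprintf("%s\t%s\t%d\t%s", genes$gene_id, genes$chrom,
                     genes$tss - 1L, genes$strand))
  writeLinesLF(lines, path)
  invisible(path)
}

#' Convert printed 1-based inclusive coordinates to a GRanges
#'
#' Publication text typically prints regions like "chr5:51553620 to
#' 51554360" in 1-based inclusive coordinates, which map directly onto
#' GRanges; this helper exists to make the convention explicit at call sites.
#'
#' @param chrom,first,last Chromosome and 1-based inclusive bounds.
#' @return A `GRanges` of length 1.
#' @export
printedRegion <- function(chrom, first, last) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(first, last))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic numeric formatting for writers (up to 10 significant digits,
# no scientific notation drift across platforms)
formatNum <- function(x) {
  out <- formatC(x, digits = 10L, format = "g", flag = "")
  trimws(out)
}

writeLinesLF <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con = con, sep = "\n")
  invisible(path)
}
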