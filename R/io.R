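#' Read single-molecule intensity traces from delimited text
#'
#' Expects tab-delimited text with columns `time_s`, `I_dna`, `I_rnap`,
#' `I_probe` and optionally `molecule`; rows are validated and malformed
#' rows reported with their line numbers.
#'
#' @param path File path.
#' @return A list of [intensity_trace()] objects (one per molecule; a single
#'   unnamed trace if no `molecule` column is present).
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE)
  need <- c("time_s", "I_dna", "I_rnap", "I_probe")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort("missing column(s): %s", paste(miss, collapse = ", "))
  num <- suppressWarnings(lapply(df[need], function(x)
    if (is.numeric(x)) x else as.numeric(as.character(x))))
  bad <- which(Reduce(`|`, lapply(num, function(x) !is.finite(x))))
  df[need] <- num
  if (length(bad))
    abort("malformed rows at line(s) %s of %s",
          paste(head(bad + 1L, 5), collapse = ", "), path)
  split_by <- if ("molecule" %in% names(df)) df$molecule else rep(1L, nrow(df))
  lapply(split(df, split_by), function(d)
    intensity_trace(d$time_s, d$I_dna, d$I_rnap, d$I_probe))
}

#' Write intensity traces as delimited text
#'
#' @param traces A list of [intensity_trace()] (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  rows <- lapply(seq_along(traces), function(i) {
    d <- as.data.frame(traces[[i]])
    d$molecule <- if (!is.null(names(traces)) && nzchar(names(traces)[i]))
      names(traces)[i] else i
    d
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Scores of a bedGraph/wig GRanges expanded to a per-position vector
granges_to_counts <- function(gr, genome_length) {
  v <- numeric(genome_length)
  if (length(gr)) {
    if (max(GenomicRanges::end(gr)) > genome_length)
      abort("track extends past the stated genome length")
    cov <- GenomicRanges::coverage(gr, weight = "score")[[1]]
    x <- as.numeric(cov)
    v[seq_along(x)] <- x
  }
  if (any(v < 0)) abort("negative counts in track")
  v
}

#' Read four end-count tracks (bedGraph or wig) into an [end_tracks()]
#'
#' File formats are auto-detected by [rtracklayer::import()]; both 0-based
#' half-open bedGraph and 1-based wig describe the same per-position counts
#' after import, which this function stores 1-based.
#'
#' @param five_plus,five_minus,three_plus,three_minus File paths.
#' @param genome_length Genome length, bp (tracks are padded with zeros).
#' @return An [end_tracks()].
#' @export
read_end_tracks <- function(five_plus, five_minus, three_plus, three_minus,
                            genome_length) {
  check_num(genome_length, "genome_length", lower = 1)
  paths <- c(five_plus = five_plus, five_minus = five_minus,
             three_plus = three_plus, three_minus = three_minus)
  counts <- lapply(paths, function(p) {
    if (!file.exists(p)) abort("file not found: %s", p)
    granges_to_counts(rtracklayer::import(p), genome_length)
  })
  end_tracks(counts$five_plus, counts$five_minus,
             counts$three_plus, counts$three_minus)
}

# Compress a per-position vector into a scored GRanges (zero runs dropped)
counts_to_granges <- function(v, seqname = "genome") {
  r <- S4Vectors::Rle(v)
  rl <- S4Vectors::runLength(r)
  rv <- S4Vectors::runValue(r)
  ends <- cumsum(rl)
  starts <- ends - rl + 1L
  keep <- rv != 0
  gr <- GenomicRanges::GRanges(seqname,
                               IRanges::IRanges(starts[keep], ends[keep]))
  gr$score <- rv[keep]
  gr
}

#' Write an [end_tracks()] as four bedGraph files
#'
#' @param tracks An [end_tracks()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_end_tracks <- function(tracks, dir, prefix = "rendseq") {
  stopifnot(inherits(tracks, "end_tracks"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nms <- c("five_plus", "five_minus", "three_plus", "three_minus")
  paths <- setNames(file.path(dir, paste0(prefix, "_", nms, ".bedgraph")),
                    nms)
  for (nm in nms)
    rtracklayer::export(counts_to_granges(tracks[[nm]],
                                          seqname = "genome"),
                        paths[[nm]], format = "bedGraph")
  invisible(paths)
}

#' Read a terminator list from BED6
#'
#' Single-bp BED features; the 1-based terminator position is the feature
#' start after import.
#'
#' @param path BED file path.
#' @return A data.frame with `position`, `strand`, `name`.
#' @export
read_terminators <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(position = GenomicRanges::start(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             name = if (!is.null(gr$name)) gr$name else
               sprintf("term_%04d", seq_along(gr)))
}

#' Write a terminator list as BED6
#'
#' @param terminators Data.frame with `position`, `strand` and optionally
#'   `name`.
#' @param path Output BED path.
#' @param seqname Sequence name.
#' @return `path`, invisibly.
#' @export
write_terminators <- function(terminators, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqname,
    IRanges::IRanges(terminators$position, width = 1L),
    strand = terminators$strand)
  gr$name <- if (!is.null(terminators$name)) terminators$name
             else sprintf("term_%04d", seq_len(nrow(terminators)))
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default `"gene"`; `NULL` keeps all).
#' @return A data.frame with `start`, `end`, `strand`, `gene_id`.
#' @export
read_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "GFF3")
  if (!is.null(feature) && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == feature]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
         else sprintf("gene_%04d", seq_along(gr))
  data.frame(start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = ids)
}

#' Write gene annotations as GFF3
#'
#' @param genes Data.frame with `start`, `end`, `strand` and optionally
#'   `gene_id`.
#' @param path Output GFF3 path.
#' @param seqname Sequence name.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqname, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- if (!is.null(genes$gene_id)) genes$gene_id
           else sprintf("gene_%04d", nrow(genes))
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
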