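#' Strand-specific 5'/3' end-count tracks
#'
#' Container for the four Rend-seq count vectors: mapped 5' and 3' read ends
#' on each strand, one count per genome position.  Coordinates are 1-based
#' inclusive throughout the package (the Bioconductor convention); BED
#' (0-based) and wig/bedGraph inputs are converted on read.
#'
#' @param five_plus,five_minus,three_plus,three_minus Non-negative integer
#'   count vectors of equal length.
#' @return An object of class `end_tracks`: a list of the four tracks plus
#'   `genome_length` and a `convention` tag.
#' @export
end_tracks <- function(five_plus, five_minus, three_plus, three_minus) {
  tr <- list(five_plus = five_plus, five_minus = five_minus,
             three_plus = three_plus, three_minus = three_minus)
  len <- unique(vapply(tr, length, integer(1)))
  if (length(len) != 1L) abort("the four tracks must have equal length")
  for (nm in names(tr)) {
    if (any(!is.finite(tr[[nm]])) || any(tr[[nm]] < 0))
      abort("track '%s' has negative or non-finite counts", nm)
  }
  structure(c(tr, list(genome_length = len, convention = "1-based")),
            class = "end_tracks")
}

#' @export
print.end_tracks <- function(x, ...) {
  cat(sprintf("end_tracks: genome length %d (%s coordinates)\n",
              x$genome_length, x$convention))
  for (nm in c("five_plus", "five_minus", "three_plus", "three_minus"))
    cat(sprintf("  %-11s total %d\n", nm, sum(x[[nm]])))
  invisible(x)
}

# Pick the relevant track: 3' ends on the terminator strand, or 5' ends on
# the opposite strand
track_for <- function(tracks, strand, which = c("three_sense", "five_anti")) {
  which <- match.arg(which)
  if (which == "three_sense") {
    if (strand == "+") tracks$three_plus else tracks$three_minus
  } else {
    if (strand == "+") tracks$five_minus else tracks$five_plus
  }
}

#' Sense-termination magnitude at a terminator
#'
#' `k_max` is the peak 3'-end count on the terminator's strand within a
#' `window`-bp region centred on the annotated terminator position; the
#' magnitude of sense termination is \eqn{\Delta_S = \log_2(k_{max})}.
#' Ties take the leftmost genomic coordinate.  When the window contains no
#' reads (`k_max = 0`) the magnitude is undefined (`NA`) and the terminator
#' is excluded from downstream scatter summaries.
#'
#' @param tracks An [end_tracks()].
#' @param position Terminator position, 1-based bp.
#' @param strand `"+"` or `"-"`.
#' @param window Window width, bp (default 10; centred, inclusive).
#' @return A list with `k_max`, `Delta_S` and `position` (of the peak).
#' @examples
#' tr <- end_tracks(integer(50), integer(50),
#'                  replace(integer(50), 25, 8L), integer(50))
#' compute_delta_S(tr, 25, "+")
#' @export
compute_delta_S <- function(tracks, position, strand, window = 10L) {
  stopifnot(inherits(tracks, "end_tracks"))
  w <- as.integer(window)
  lo <- position - (w - 1L) %/% 2L
  hi <- lo + w - 1L
  if (lo < 1L || hi > tracks$genome_length)
    abort("Delta_S window [%d, %d] extends outside the genome", lo, hi)
  cnt <- track_for(tracks, strand, "three_sense")[lo:hi]
  k_max <- max(cnt)
  pos <- as.integer(lo + which.max(cnt) - 1L)   # leftmost tie
  list(k_max = k_max,
       Delta_S = if (k_max >= 1) log2(k_max) else NA_real_,
       position = if (k_max >= 1) pos else NA_integer_)
}

#' Antisense-initiation magnitude near a terminator
#'
#' `k_max2` is the peak 5'-end count on the strand opposite the terminator
#' within `position +/- halfwidth` (inclusive);
#' \eqn{\Delta_{AS} = \log_2(k_{max2})}.  The signed distance of the peak is
#' reported in the terminator's own orientation (positive = downstream of
#' the terminator).
#'
#' @inheritParams compute_delta_S
#' @param halfwidth Search half-width, bp (default 500).
#' @return A list with `k_max2`, `Delta_AS`, `position` and `distance`
#'   (signed nt).
#' @export
compute_delta_AS <- function(tracks, position, strand, halfwidth = 500L) {
  stopifnot(inherits(tracks, "end_tracks"))
  lo <- max(1L, position - as.integer(halfwidth))
  hi <- min(tracks$genome_length, position + as.integer(halfwidth))
  cnt <- track_for(tracks, strand, "five_anti")[lo:hi]
  k_max2 <- max(cnt)
  pos <- as.integer(lo + which.max(cnt) - 1L)
  if (k_max2 < 1)
    return(list(k_max2 = 0L, Delta_AS = NA_real_, position = NA_integer_,
                distance = NA_integer_))
  list(k_max2 = k_max2, Delta_AS = log2(k_max2), position = pos,
       distance = as.integer(if (strand == "+") pos - position
                             else position - pos))
}

#' Peak z-score of a single position against its local flanks
#'
#' The z-score compares the count at `position` with the mean and SD of the
#' counts in flanking windows (`exclusion + 1` to `flank` bp on each side;
#' the centre `+/- exclusion` zone is excluded so the peak and its shadow do
#' not contaminate the background).  The SD is floored at the Poisson SD of
#' the flank mean, \eqn{\sqrt{\max(\bar c, 1)}}, which avoids
#' divide-by-zero on empty flanks and anchors the scale to counting noise.
#'
#' @param track Integer count vector.
#' @param position 1-based position.
#' @param flank Flank reach, bp, each side (default 50).
#' @param exclusion Centre exclusion half-width, bp (default 2).
#' @return The z-score (0 for a perfectly flat track, by the floor rule).
#' @export
peak_zscore <- function(track, position, flank = 50L, exclusion = 2L) {
  n <- length(track)
  if (position < 1L || position > n) abort("position outside genome")
  offs <- c(-(flank:(exclusion + 1L)), (exclusion + 1L):flank)
  idx <- position + offs
  idx <- idx[idx >= 1L & idx <= n]
  if (length(idx) < 2L) abort("flank window outside genome")
  m <- mean(track[idx])
  s <- max(sd(track[idx]), sqrt(max(m, 1)))
  (track[position] - m) / s
}

#' z-score transform of a whole count track
#'
#' Vectorised version of [peak_zscore()] for every genome position, using
#' running sums; used for genome-scale peak calling.
#'
#' @inheritParams peak_zscore
#' @param track Integer count vector.
#' @return Numeric vector of z-scores (same length as `track`).
#' @export
zscore_track <- function(track, flank = 50L, exclusion = 2L) {
  n <- length(track)
  x <- as.numeric(track)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  win_sum <- function(half) {
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    list(s = cs[hi + 1L] - cs[lo], s2 = cs2[hi + 1L] - cs2[lo],
         m = hi - lo + 1L)
  }
  big <- win_sum(as.integer(flank))
  ctr <- win_sum(as.integer(exclusion))
  s <- big$s - ctr$s
  s2 <- big$s2 - ctr$s2
  m <- big$m - ctr$m
  mu <- s / m
  va <- pmax(s2 / m - mu^2, 0) * m / pmax(m - 1L, 1L)
  sdv <- pmax(sqrt(va), sqrt(pmax(mu, 1)))
  (x - mu) / sdv
}

#' Mark terminators eligible for the antisense analysis
#'
#' A terminator is eligible when its nearest upstream and nearest downstream
#' genes are both annotated on the same strand as the terminator itself.
#' This excludes terminators near convergent gene pairs, where 3'-end peak
#' shadows could masquerade as antisense 5' ends.
#'
#' @param terminators Data.frame with columns `position` (1-based bp) and
#'   `strand`.
#' @param genes Data.frame with columns `start`, `end`, `strand` (1-based,
#'   inclusive), or a `GRanges`.
#' @return The `terminators` data.frame with added logical column `eligible`
#'   plus `upstream_strand` and `downstream_strand`.
#' @export
filter_terminators <- function(terminators, genes) {
  genes <- as_gene_df(genes)
  up_str <- character(nrow(terminators))
  dn_str <- character(nrow(terminators))
  for (i in seq_len(nrow(terminators))) {
    p <- terminators$position[i]
    up <- genes[genes$end < p, , drop = FALSE]
    dn <- genes[genes$start > p, , drop = FALSE]
    up_str[i] <- if (nrow(up)) up$strand[which.max(up$end)] else NA_character_
    dn_str[i] <- if (nrow(dn)) dn$strand[which.min(dn$start)] else NA_character_
  }
  terminators$upstream_strand <- up_str
  terminators$downstream_strand <- dn_str
  terminators$eligible <- !is.na(up_str) & !is.na(dn_str) &
    up_str == terminators$strand & dn_str == terminators$strand
  terminators
}

as_gene_df <- function(genes) {
  if (inherits(genes, "GRanges")) {
    data.frame(start = GenomicRanges::start(genes),
               end = GenomicRanges::end(genes),
               strand = as.character(GenomicRanges::strand(genes)))
  } else {
    stopifnot(all(c("start", "end", "strand") %in% names(genes)))
    as.data.frame(genes)
  }
}

#' Per-terminator sense/antisense peak summary
#'
#' Runs [compute_delta_S()], [compute_delta_AS()] and the antisense peak
#' z-score for every terminator.
#'
#' @param tracks An [end_tracks()].
#' @param terminators Data.frame with `position`, `strand` (and optionally
#'   `eligible` from [filter_terminators()]; ineligible rows are skipped).
#' @param window Delta_S window, bp.
#' @param halfwidth Delta_AS search half-width, bp.
#' @param flank,exclusion z-score windowing, see [peak_zscore()].
#' @return A data.frame, one row per analysed terminator: `position`,
#'   `strand`, `k_max`, `Delta_S`, `k_max2`, `Delta_AS`,
#'   `antisense_position`, `distance`, `zscore`.
#' @export
terminator_peaks <- function(tracks, terminators, window = 10L,
                             halfwidth = 500L, flank = 50L, exclusion = 2L) {
  if ("eligible" %in% names(terminators))
    terminators <- terminators[terminators$eligible, , drop = FALSE]
  rows <- lapply(seq_len(nrow(terminators)), function(i) {
    p <- terminators$position[i]
    s <- terminators$strand[i]
    ds <- compute_delta_S(tracks, p, s, window = window)
    da <- compute_delta_AS(tracks, p, s, halfwidth = halfwidth)
    z <- if (is.na(da$position)) NA_real_ else
      peak_zscore(track_for(tracks, s, "five_anti"), da$position,
                  flank = flank, exclusion = exclusion)
    data.frame(position = p, strand = s, k_max = ds$k_max,
               Delta_S = ds$Delta_S, k_max2 = da$k_max2,
               Delta_AS = da$Delta_AS, antisense_position = da$position,
               distance = da$distance, zscore = z)
  })
  do.call(rbind, rows)
}

#' Terminator-relative antisense peak frequency profile
#'
#' For each signed distance bin, reports the fraction (with binomial
#' s.e.m.) of `bin`-wide windows, centred `d` nt from the terminators in
#' their own orientation, that contain at least one antisense 5'-end peak
#' with z-score above `z_threshold` on the opposite strand.
#'
#' @param tracks An [end_tracks()].
#' @param locations Data.frame with `position` and `strand` (terminators or
#'   control locations; rows with `eligible == FALSE` are skipped).
#' @param bin Window width, nt (default 200).
#' @param max_dist Profile range, nt (default 2000 each side).
#' @param z_threshold Peak z-score threshold (default 12, strict `>`).
#' @param flank,exclusion z-score windowing, see [peak_zscore()].
#' @return A data.frame with `distance` (bin centre, nt), `fraction`, `sem`
#'   and `n`.
#' @export
distance_profile <- function(tracks, locations, bin = 200L, max_dist = 2000L,
                             z_threshold = 12, flank = 50L, exclusion = 2L) {
  if ("eligible" %in% names(locations))
    locations <- locations[locations$eligible, , drop = FALSE]
  if (!nrow(locations)) abort("no eligible locations")
  zp <- zscore_track(tracks$five_plus, flank, exclusion)
  zm <- zscore_track(tracks$five_minus, flank, exclusion)
  # cumulative counts of above-threshold positions: O(1) window queries
  cs <- list("+" = c(0, cumsum(zm > z_threshold)),   # + location: - strand
             "-" = c(0, cumsum(zp > z_threshold)))
  centers <- seq(-as.integer(max_dist), as.integer(max_dist),
                 by = as.integer(bin))
  half <- as.integer(bin) %/% 2L
  n <- tracks$genome_length
  plus <- locations$strand == "+"
  res <- lapply(centers, function(d) {
    ctr <- ifelse(plus, locations$position + d, locations$position - d)
    lo <- pmax(1L, ctr - half)
    hi <- pmin(n, ctr + half)
    ok <- lo <= hi
    nhit <- ifelse(plus, cs[["+"]][hi + 1L] - cs[["+"]][lo],
                   cs[["-"]][hi + 1L] - cs[["-"]][lo])
    f <- fraction_with_se(nhit[ok] > 0)
    data.frame(distance = d, fraction = f$fraction, sem = f$se, n = f$n)
  })
  do.call(rbind, res)
}

#' Sample constrained random control locations
#'
#' Draws `n` genome positions, uniformly without replacement, from the pool
#' of positions that (i) lie more than `min_dist` nt from every annotated
#' terminator and (ii) fall on the sense strand of a run of at least
#' `min_run` consecutive genes annotated in the same orientation.  These
#' mimic terminator-free transcribed regions for the negative control.
#'
#' @param genes Gene annotation (data.frame or GRanges; see
#'   [filter_terminators()]).
#' @param terminators Data.frame with `position`.
#' @param n Number of locations.
#' @param min_dist Exclusion distance from any terminator, nt (default 700).
#' @param min_run Minimum run length of same-orientation genes (default 3).
#' @param seed Integer seed.
#' @return A data.frame with `position` and `strand` (the run orientation).
#' @export
sample_control_locations <- function(genes, terminators, n, min_dist = 700L,
                                     min_run = 3L, seed = 1L) {
  pool <- control_pool(genes, terminators, min_dist = min_dist,
                       min_run = min_run)
  if (nrow(pool) < n)
    abort("eligible control pool has %d positions; need %d", nrow(pool), n)
  set.seed(seed)
  pool[sample.int(nrow(pool), n), , drop = FALSE]
}

# Eligible control positions: gene bodies within runs of >= min_run
# same-orientation genes, further than min_dist from every terminator.
control_pool <- function(genes, terminators, min_dist = 700L,
                         min_run = 3L) {
  genes <- as_gene_df(genes)
  genes <- genes[order(genes$start), , drop = FALSE]
  r <- rle(genes$strand)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- which(r$lengths >= min_run)
  spans <- lapply(runs, function(k)
    unlist(lapply(run_start[k]:run_end[k],
                  function(gi) genes$start[gi]:genes$end[gi])))
  pool_pos <- unlist(spans)
  pool_str <- rep(r$values[runs],
                  vapply(spans, length, integer(1), USE.NAMES = FALSE))
  if (length(pool_pos)) {
    tp <- sort(terminators$position)
    # distance to the nearest terminator via a sorted lookup
    idx <- findInterval(pool_pos, tp)
    d_left <- ifelse(idx >= 1L, pool_pos - tp[pmax(idx, 1L)], Inf)
    d_right <- ifelse(idx < length(tp), tp[pmin(idx + 1L, length(tp))] -
                        pool_pos, Inf)
    keep <- pmin(d_left, d_right, na.rm = TRUE) > min_dist
    pool_pos <- pool_pos[keep]
    pool_str <- pool_str[keep]
  }
  data.frame(position = pool_pos, strand = pool_str)
}

#' Constrained random-location negative control for the distance profile
#'
#' Repeats the [distance_profile()] analysis `n_reps` times on freshly
#' sampled control locations and compares the terminator-position (distance
#' 0) fraction with the observed one.  The empirical p-value is
#' `(1 + #{replicates >= observed}) / (1 + n_reps)`.
#'
#' @inheritParams distance_profile
#' @param genes,terminators Annotations passed to
#'   [sample_control_locations()].
#' @param observed_fraction Fraction with antisense peak at distance 0 for
#'   the real terminators.
#' @param n_reps Number of control replicates (default 100).
#' @param n_loc Locations per replicate (default: number of terminators).
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @param ... Passed to [distance_profile()] and
#'   [sample_control_locations()] (e.g. `bin`, `z_threshold`, `min_dist`).
#' @return A list with `fractions` (per replicate, at distance 0),
#'   `p_value`, `n_reps` and `observed_fraction`.
#' @export
control_replicates <- function(tracks, genes, terminators,
                               observed_fraction, n_reps = 100L,
                               n_loc = nrow(terminators), seed = 1L,
                               bin = 200L, z_threshold = 12,
                               min_dist = 700L, min_run = 3L,
                               flank = 50L, exclusion = 2L) {
  pool <- control_pool(genes, terminators, min_dist = min_dist,
                       min_run = min_run)
  if (nrow(pool) < n_loc)
    abort("eligible control pool has %d positions; need %d",
          nrow(pool), n_loc)
  # z-score hit lookups computed once, shared by all replicates
  cs_p <- c(0, cumsum(zscore_track(tracks$five_minus, flank, exclusion) >
                        z_threshold))
  cs_m <- c(0, cumsum(zscore_track(tracks$five_plus, flank, exclusion) >
                        z_threshold))
  half <- as.integer(bin) %/% 2L
  n <- tracks$genome_length
  fr <- vapply(seq_len(n_reps), function(i) {
    set.seed(seed + i)
    loc <- pool[sample.int(nrow(pool), n_loc), , drop = FALSE]
    lo <- pmax(1L, loc$position - half)
    hi <- pmin(n, loc$position + half)
    nhit <- ifelse(loc$strand == "+", cs_p[hi + 1L] - cs_p[lo],
                   cs_m[hi + 1L] - cs_m[lo])
    mean(nhit > 0)
  }, numeric(1))
  p <- (1 + sum(fr >= observed_fraction)) / (1 + n_reps)
  list(fractions = fr, p_value = p, n_reps = as.integer(n_reps),
       observed_fraction = observed_fraction)
}

#' Per-position information content around transcription start sites
#'
#' Extracts the `+/- halfwidth` bp sequence window centred on each peak
#' (reverse-complemented for minus-strand peaks) and computes the
#' information content per position, \eqn{R_i = 2 - H_i} bits under a
#' uniform background, optionally with the small-sample correction
#' \eqn{e(n) = 3 / (2 n \ln 2)} subtracted.
#'
#' @param genome A `DNAString`, or a single character string of A/C/G/T.
#' @param positions 1-based peak positions.
#' @param strands `"+"`/`"-"` per peak.
#' @param halfwidth Window half-width, bp (default 3, i.e. a 7-bp window).
#' @param correct Apply the small-sample correction (default TRUE).
#' @return A data.frame with `offset` (-halfwidth..halfwidth relative to the
#'   peak), `bits`, and attribute `freq` (the 4 x width base-frequency
#'   matrix) and `corrected` flag.
#' @export
tss_information_content <- function(genome, positions, strands,
                                    halfwidth = 3L, correct = TRUE) {
  if (length(positions) < 2L) abort("need at least two peak sequences")
  if (length(strands) != length(positions)) abort("input lengths differ")
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  glen <- length(genome)
  hw <- as.integer(halfwidth)
  ok <- positions - hw >= 1L & positions + hw <= glen
  if (!all(ok)) abort("%d window(s) extend outside the genome", sum(!ok))
  segs <- Biostrings::DNAStringSet(lapply(seq_along(positions), function(i) {
    s <- Biostrings::subseq(genome, positions[i] - hw, positions[i] + hw)
    if (strands[i] == "-") Biostrings::reverseComplement(s) else s
  }))
  cm <- Biostrings::consensusMatrix(segs, baseOnly = TRUE)[1:4, , drop = FALSE]
  freq <- sweep(cm, 2, colSums(cm), "/")
  H <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  n <- length(positions)
  corr <- if (correct) 3 / (2 * n * log(2)) else 0
  out <- data.frame(offset = seq(-hw, hw), bits = 2 - H - corr)
  attr(out, "freq") <- freq
  attr(out, "corrected") <- correct
  out
}
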