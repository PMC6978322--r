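#' Build a synthetic genome annotation with operon structure
#'
#' Lays out `n_operons` operons of `genes_per_operon` same-orientation genes
#' along a linear genome, with an intrinsic terminator placed at the 3' end
#' of each operon.  Operon orientation flips every `operon_run` operons, so
#' the genome contains both tandem (eligible) and convergent/divergent
#' (ineligible) terminator contexts, and guarantees runs of at least
#' `genes_per_operon` consecutive same-orientation genes, as required by the
#' constrained random-location control.
#'
#' @param n_operons Number of operons.
#' @param genes_per_operon Genes per operon (>= 3 keeps the control pool
#'   non-empty).
#' @param gene_length Gene length, bp.
#' @param gene_gap Gap between genes within an operon, bp.
#' @param term_offset Distance from the last gene end to the terminator, bp.
#' @param operon_gap Gap between operons, bp.
#' @param margin Genome margin before the first and after the last operon,
#'   bp.
#' @param operon_run Number of consecutive same-orientation operons before
#'   the strand flips.
#' @return A list with `genes` (data.frame `start`, `end`, `strand`,
#'   `gene_id`), `terminators` (data.frame `position`, `strand`, `name`) and
#'   `genome_length`.
#' @examples
#' g <- synthetic_genome(n_operons = 4)
#' table(g$genes$strand)
#' @export
synthetic_genome <- function(n_operons = 10L, genes_per_operon = 4L,
                             gene_length = 900L, gene_gap = 100L,
                             term_offset = 60L, operon_gap = 3000L,
                             margin = 2500L, operon_run = 3L) {
  check_num(n_operons, "n_operons", lower = 1)
  check_num(genes_per_operon, "genes_per_operon", lower = 1)
  genes <- list()
  terms <- list()
  cursor <- margin + 1L
  for (o in seq_len(n_operons)) {
    strand <- if (((o - 1L) %/% operon_run) %% 2L == 0L) "+" else "-"
    starts <- cursor + (seq_len(genes_per_operon) - 1L) *
      (gene_length + gene_gap)
    ends <- starts + gene_length - 1L
    genes[[o]] <- data.frame(
      start = starts, end = ends, strand = strand,
      gene_id = sprintf("op%02d_g%d", o, seq_len(genes_per_operon)))
    # terminator sits just past the operon's 3' end in its own orientation
    tpos <- if (strand == "+") max(ends) + term_offset
            else min(starts) - term_offset
    terms[[o]] <- data.frame(position = tpos, strand = strand,
                             name = sprintf("term_op%02d", o))
    cursor <- max(ends) + operon_gap
  }
  genes <- do.call(rbind, genes)
  terms <- do.call(rbind, terms)
  list(genes = genes, terminators = terms,
       genome_length = max(genes$end) + margin)
}

#' Configuration for the Rend-seq track simulator
#'
#' @param genome_length Genome length, bp.
#' @param genes Gene annotation data.frame (`start`, `end`, `strand`), used
#'   by the eligibility filter and the control sampler.
#' @param terminators Terminator data.frame (`position`, `strand`).
#' @param background_rate Mean Poisson end-count per nt on every track.
#' @param term_peak_height Counts added at each terminator's 3'-end peak.
#' @param antisense_peak_height Counts added at each planted antisense
#'   5'-end peak.  May be a vector (recycled over terminators) to plant
#'   peaks of varying height.
#' @param antisense_offset Signed offsets (nt, in the terminator's own
#'   orientation; positive = downstream) at which antisense peaks are
#'   planted.  Either a fixed vector recycled over terminators or a
#'   function `f(n)` returning `n` sampled offsets.
#' @param fraction_with_antisense Probability that a terminator receives an
#'   antisense peak.
#' @param max_offset Offsets beyond this bound are rejected.
#' @param seed Integer seed.
#' @return An object of class `rend_sim_config`.
#' @export
rend_sim_config <- function(genome_length, genes, terminators,
                            background_rate = 0.2,
                            term_peak_height = 64L,
                            antisense_peak_height = 40L,
                            antisense_offset = function(n)
                              sample(c(-300:-20, 20:300), n, replace = TRUE),
                            fraction_with_antisense = 0.2,
                            max_offset = 500L,
                            seed = 1L) {
  check_num(genome_length, "genome_length", lower = 1)
  check_num(background_rate, "background_rate", lower = 0)
  check_num(fraction_with_antisense, "fraction_with_antisense",
            lower = 0, upper = 1)
  if (any(terminators$position < 1) ||
      any(terminators$position > genome_length))
    abort("terminator positions must lie inside the genome")
  if (any(term_peak_height < 0) || any(antisense_peak_height < 0))
    abort("peak heights must be >= 0")
  structure(list(genome_length = as.integer(genome_length), genes = genes,
                 terminators = terminators,
                 background_rate = background_rate,
                 term_peak_height = term_peak_height,
                 antisense_peak_height = antisense_peak_height,
                 antisense_offset = antisense_offset,
                 fraction_with_antisense = fraction_with_antisense,
                 max_offset = as.integer(max_offset),
                 seed = as.integer(seed)),
            class = "rend_sim_config")
}

#' Simulate strand-specific 5'/3' end-count tracks with planted peaks
#'
#' Generates i.i.d. Poisson background on the four tracks, plants a 3'-end
#' sense peak at every terminator, and plants a 5'-end antisense peak on the
#' opposite strand at a sampled offset for a configured fraction of
#' terminators.
#'
#' @param config A [rend_sim_config()].
#' @return A list with `tracks` (an [end_tracks()]) and `truth` (data.frame
#'   per terminator: `position`, `strand`, `term_height`, `has_antisense`,
#'   `antisense_offset`, `antisense_position`, `antisense_height`).
#' @examples
#' g <- synthetic_genome(n_operons = 2)
#' cfg <- rend_sim_config(g$genome_length, g$genes, g$terminators,
#'                        background_rate = 0, seed = 3)
#' sim <- simulate_rendseq(cfg)
#' sim$truth
#' @export
simulate_rendseq <- function(config) {
  if (!inherits(config, "rend_sim_config"))
    abort("'config' must be created by rend_sim_config()")
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$genome_length
  bg <- function() if (cfg$background_rate > 0) rpois(L, cfg$background_rate)
                   else integer(L)
  tr <- list(five_plus = bg(), five_minus = bg(),
             three_plus = bg(), three_minus = bg())

  tm <- cfg$terminators
  nt <- nrow(tm)
  th <- rep_len(cfg$term_peak_height, nt)
  ah <- rep_len(cfg$antisense_peak_height, nt)
  has_as <- runif(nt) < cfg$fraction_with_antisense
  offs <- if (is.function(cfg$antisense_offset)) cfg$antisense_offset(nt)
          else rep_len(cfg$antisense_offset, nt)
  if (any(abs(offs) > cfg$max_offset))
    abort("sampled antisense offset exceeds max_offset = %d", cfg$max_offset)

  as_pos <- ifelse(tm$strand == "+", tm$position + offs, tm$position - offs)
  as_pos <- as.integer(as_pos)
  if (any(has_as & (as_pos < 1L | as_pos > L)))
    abort("planted antisense peak falls outside the genome")

  for (i in seq_len(nt)) {
    p <- tm$position[i]
    if (tm$strand[i] == "+") tr$three_plus[p] <- tr$three_plus[p] + th[i]
    else tr$three_minus[p] <- tr$three_minus[p] + th[i]
    if (has_as[i]) {
      q <- as_pos[i]
      if (tm$strand[i] == "+") tr$five_minus[q] <- tr$five_minus[q] + ah[i]
      else tr$five_plus[q] <- tr$five_plus[q] + ah[i]
    }
  }
  truth <- data.frame(position = tm$position, strand = tm$strand,
                      term_height = th, has_antisense = has_as,
                      antisense_offset = ifelse(has_as, offs, NA_integer_),
                      antisense_position = ifelse(has_as, as_pos,
                                                  NA_integer_),
                      antisense_height = ifelse(has_as, ah, NA_integer_))
  if (!is.null(tm$name)) truth$name <- tm$name
  list(tracks = do.call(end_tracks, tr[c("five_plus", "five_minus",
                                         "three_plus", "three_minus")]),
       truth = truth)
}

#' Generate a random genome sequence
#'
#' Uniform i.i.d. bases; used to exercise the sequence-information analysis
#' where the expected per-position information is ~0 bits.
#'
#' @param length Genome length, bp.
#' @param seed Integer seed.
#' @return A `DNAString`.
#' @export
random_genome <- function(length, seed = 1L) {
  set.seed(seed)
  Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), length,
                                     replace = TRUE), collapse = ""))
}
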