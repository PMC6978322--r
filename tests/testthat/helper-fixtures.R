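# Shared fixture builders for the test suite.  Everything is generated in
# code; no stored data.

# Noiseless synthetic decay trace built from the model formula directly
# (independent of the simulator), for calibration oracle tests.
make_decay_trace <- function(I_P = 800, I_mn = 100, lambda = 0.01,
                             t_max = 200, dt = 2) {
  t <- seq(0, t_max, by = dt)
  intensity_trace(t, I_dna = rep(600, length(t)),
                  I_rnap = I_P * exp(-lambda * t) + I_mn,
                  I_probe = rep(I_mn, length(t)))
}

# Small zero-background end-track set with one planted terminator
make_spike_tracks <- function(L = 2000, term_pos = 1000, strand = "+",
                              spike3 = 8L, spike5 = 0L, as_offset = 120L) {
  z <- integer(L)
  three_plus <- z; three_minus <- z; five_plus <- z; five_minus <- z
  if (strand == "+") {
    three_plus[term_pos] <- spike3
    if (spike5 > 0) five_minus[term_pos + as_offset] <- spike5
  } else {
    three_minus[term_pos] <- spike3
    if (spike5 > 0) five_plus[term_pos - as_offset] <- spike5
  }
  end_tracks(five_plus, five_minus, three_plus, three_minus)
}

# Mirror an end-track set: reverse the genome and swap strand labels.
# Under this transformation every strand-aware statistic must be invariant.
mirror_tracks <- function(tracks) {
  end_tracks(rev(tracks$five_minus), rev(tracks$five_plus),
             rev(tracks$three_minus), rev(tracks$three_plus))
}

mirror_position <- function(pos, L) L + 1L - pos

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Slide/stick position path on a wide template (negligible confinement):
# alternating sliding and stuck segments with known state labels.
make_slide_stick_path <- function(D = 3.5e4, dt = 2, n_seg = 8,
                                  seg_frames = 60, L = 5e5, seed = 1) {
  set.seed(seed)
  segs <- vector("list", n_seg)
  cur <- L / 2
  for (s in seq_len(n_seg)) {
    if (s %% 2L == 1L) {
      seg <- simulate_bounded_walk(D, L, dt, seg_frames, x0 = cur)
      cur <- seg[length(seg)]
    } else {
      seg <- rep(cur, seg_frames)
    }
    segs[[s]] <- seg
  }
  z <- unlist(segs)
  state <- rep(rep(c("sliding", "stuck"), length.out = n_seg),
               each = seg_frames)
  list(time_s = dt * (seq_along(z) - 1), z = z, state = state)
}

# 5'-end track on the strand opposite a terminator
track_for_test <- function(tracks, strand) {
  if (strand == "+") tracks$five_minus else tracks$five_plus
}
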