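# Shared fixtures: small, fast configurations used across test files.

tiny_imaging <- function(...) {
  imaging_config(frame_shape = c(128, 128), spots_per_frame = 15, ...)
}

# deterministic synthetic spectrum helpers
flat_spectrum <- function(level = 1, grid = seq(400, 800, by = 1)) {
  new_spectrum(grid, rep(level, length(grid)))
}

# render a small labelled dataset and return frames + truth
small_dataset <- function(concentration = 0, n_spots = 300, seed = 11L,
                          noise = TRUE, ...) {
  generate_dataset(concentration, n_spots = n_spots,
                   img = tiny_imaging(...), seed = seed, noise = noise)
}

# match kept spots to ground-truth positions within a radius (pixels);
# returns data frame of matched pairs (true gamma, measured gamma)
match_spots <- function(spots, truth, radius = 1.5) {
  out <- vector("list", length(unique(truth$frame)))
  k <- 0L
  for (f in unique(truth$frame)) {
    tf <- truth[truth$frame == f, ]
    sf <- spots[spots$frame == f, ]
    if (nrow(sf) == 0L) next
    for (i in seq_len(nrow(tf))) {
      d2 <- (sf$row - tf$row[i])^2 + (sf$col - tf$col[i])^2
      j <- which.min(d2)
      if (d2[j] <= radius^2) {
        k <- k + 1L
        out[[k]] <- data.frame(gamma_true = tf$gamma_true[i],
                               gamma_measured = sf$gamma[j],
                               is_aggregate = tf$is_aggregate[i])
      }
    }
  }
  if (k == 0L) return(data.frame(gamma_true = numeric(0),
                                 gamma_measured = numeric(0),
                                 is_aggregate = logical(0)))
  do.call(rbind, out[seq_len(k)])
}
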