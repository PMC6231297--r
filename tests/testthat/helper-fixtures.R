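# Shared in-code fixtures. Everything is generated at test time; no data
# files. Scales are deliberately small — full-scale counts are exercised
# only where an acceptance criterion requires them.

# a small strongly-contrasted cohort for CNN / pipeline tests
tiny_synth <- function(n = c(AD = 6, NC = 6, MCIc = 5, MCInc = 5),
                       atrophy = c(AD = 0.6, MCIc = 0.4, MCInc = 0.1, NC = 0),
                       seed = 101, ...) {
  synthetic_config(n_per_group = n, atrophy_effect = atrophy, seed = seed, ...)
}

# a reduced CNN that keeps the published layer structure but shrinks the
# channel counts so test-time training stays in seconds
tiny_cnn <- function(epochs = 2, channels = c(8, 8, 16), batch_size = 64,
                     seed = 7, ...) {
  cnn_config(channels = channels, epochs = epochs, batch_size = batch_size,
             seed = seed, ...)
}

# subject CSV with given per-group counts, written to a temp file
write_subject_csv <- function(counts, path = tempfile(fileext = ".csv"),
                              age = 70) {
  groups <- rep(names(counts), times = counts)
  df <- data.frame(id = sprintf("s%04d", seq_along(groups)),
                   group = groups, age = age)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# brute-force pairwise AUC oracle (Mann-Whitney with ties counted 1/2)
pairwise_auc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == -1]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# synthetic hippocampus-like mask: two small blocks inside a grid
block_mask <- function(shape = c(64, 64, 64)) {
  m <- array(0L, shape)
  m[24:32, 28:38, 28:36] <- 1L
  m[36:44, 28:38, 28:36] <- 1L
  hippocampus_mask(m)
}
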