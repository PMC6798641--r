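# Shared fixtures and independent oracles for the test suite.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

can_pair_ref <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# Exhaustive-enumeration maximum base-pair count over all nested
# structures (no memoisation; exponential, for n <= 12 oracle checks).
enum_max_pairs <- function(chars, i, j, min_loop = 3) {
  if (j - i <= min_loop) return(0L)
  best <- enum_max_pairs(chars, i + 1, j, min_loop)
  for (k in (i + min_loop + 1):j) {
    if (can_pair_ref(chars[i], chars[k])) {
      best <- max(best, 1L + enum_max_pairs(chars, i + 1, k - 1, min_loop) +
                    enum_max_pairs(chars, k + 1, j, min_loop))
    }
  }
  best
}

nussinov_oracle <- function(seq, min_loop = 3) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < 2) return(0L)
  enum_max_pairs(chars, 1L, length(chars), min_loop)
}

# Loop-based convolution oracle: filter bank w is n_filters x C x k.
conv_oracle <- function(x, w, b) {
  nf <- dim(w)[1]
  k <- dim(w)[3]
  s <- nrow(x) - k + 1
  out <- matrix(0, nf, s)
  for (i in seq_len(nf)) {
    for (pos in seq_len(s)) {
      acc <- b[i]
      for (r in seq_len(k)) {
        for (ch in seq_len(ncol(x))) {
          acc <- acc + w[i, ch, r] * x[pos + r - 1, ch]
        }
      }
      out[i, pos] <- acc
    }
  }
  out
}

maxpool_oracle <- function(z, m) {
  p <- ncol(z) %/% m
  out <- matrix(0, nrow(z), p)
  for (i in seq_len(nrow(z))) {
    for (j in seq_len(p)) {
      out[i, j] <- max(z[i, ((j - 1) * m + 1):(j * m)])
    }
  }
  out
}

# Threshold-sweep oracles for the ranking metrics.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

aupr_oracle <- function(scores, labels) {
  np <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    recall <- tp / np
    precision <- tp / sum(pred)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Small labelled encoded set for network/training smoke tests.
tiny_encoded <- function(n_pos = 8, ratio = 1, seed = 42, mutation = 0) {
  ds <- simulate_hairpins(synthetic_params(
    n_pos = n_pos, imbalance_ratio = ratio, mutation_rate = mutation,
    seed = seed))
  encode_dataset(ds)
}

tiny_model_config <- function(...) {
  model_config(n_filters = 4, fc_hidden = 16, lstm_hidden = 6, ...)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
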