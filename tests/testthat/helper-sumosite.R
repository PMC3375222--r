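# Shared test helpers: small random fragments and datasets built in code.

# random valid fragment: 2n+1 letters, K center, optional terminal O runs
random_fragment <- function(n = 12L, pad_left = 0L, pad_right = 0L) {
  w <- 2L * n + 1L
  core <- sample(STANDARD_AA, w - pad_left - pad_right, replace = TRUE)
  ch <- c(rep("O", pad_left), core, rep("O", pad_right))
  ch[n + 1L] <- "K"
  paste(ch, collapse = "")
}

random_fragments <- function(m, n = 12L) {
  vapply(seq_len(m), function(i) {
    pl <- sample(0:3, 1); pr <- sample(0:3, 1)
    random_fragment(n, pl, pr)
  }, "")
}

# wrap plain fragment strings as a fragment_dataset
as_fragment_ds <- function(frags, labels, n = 12L) {
  df <- data.frame(fragment = frags, label = as.integer(labels),
                   protein_id = NA_character_, position = NA_integer_,
                   stringsAsFactors = FALSE)
  sumosite:::.new_fragment_dataset(df, n)
}

# tiny separable 2-d blobs for SVM tests
separable_blobs <- function(n_per = 20L, gap = 4) {
  x <- rbind(matrix(rnorm(n_per * 2), ncol = 2) + gap,
             matrix(rnorm(n_per * 2), ncol = 2) - gap)
  y <- rep(c(1L, 0L), each = n_per)
  list(x = x, y = y)
}

# small fully planted proteome + 1:ratio dataset for end-to-end checks
small_planted_dataset <- function(n_pos = 40L, ratio = 5, seed = 5L) {
  pro <- generate_proteome(n_pos = n_pos, nonconsensus_frac = 0, seed = seed)
  ds <- build_candidate_set(pro$proteins, pro$truth[pro$truth$label == 1L, ])
  sample_negatives(ds, ratio, seed = seed)
}
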