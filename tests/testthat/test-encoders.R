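# encoders module: dimension contracts, exact table lookups, and
# brute-force oracles for the positional index arithmetic.

test_that("dimension contracts hold for random fragments", {
  set.seed(11)
  for (f in random_fragments(5)) {
    expect_length(encode_binary(f), 504L)
    expect_length(encode_cksaap(f), 2205L)
    expect_length(encode_reduced(f, "six"), 144L)
    expect_length(encode_reduced(f, "nine"), 216L)
    expect_length(encode_zscales(f), 120L)
    expect_length(encode_hydrobinary(f), 508L)
  }
  refs <- random_fragments(40)
  expect_length(encode_knn(random_fragment(), refs[1:20], refs[21:40]), 6L)
  # pssm: toy profile over a 30-residue protein with a K at 15
  seqch <- sample(STANDARD_AA, 30, replace = TRUE); seqch[15] <- "K"
  prof <- list(scores = matrix(rnorm(30 * 20), 30, 20))
  frag <- extract_fragment(paste(seqch, collapse = ""), 15)
  expect_length(encode_pssm(frag, prof, 15), 500L)
})

test_that("one-hot block layout matches a naive per-position oracle", {
  set.seed(12)
  # the block for A is 1 followed by 20 zeros
  fA <- paste0(strrep("A", 12), "K", strrep("A", 12))
  v <- encode_binary(fA)
  expect_equal(which(v == 1), 21 * (0:23) + 1)  # A slot of all 24 blocks
  # naive oracle: loop positions, write one-hot blocks
  for (f in random_fragments(5)) {
    ch <- strsplit(f, "")[[1]][-13]
    oracle <- numeric(0)
    for (c0 in ch) {
      block <- numeric(21)
      block[match(c0, FRAGMENT_ALPHABET)] <- 1
      oracle <- c(oracle, block)
    }
    expect_equal(encode_binary(f), oracle)
    expect_equal(sum(encode_binary(f)), 24)
  }
})

test_that("CKSAAP counts match brute-force pair enumeration", {
  # 12 A's, K, 12 A's at k = 0: AA x22, AK, KA
  f <- paste0(strrep("A", 12), "K", strrep("A", 12))
  v <- encode_cksaap(f)
  k0 <- v[1:441]
  pair_idx <- function(a, b) (match(a, FRAGMENT_ALPHABET) - 1) * 21 +
    match(b, FRAGMENT_ALPHABET)
  expect_equal(k0[pair_idx("A", "A")], 22)
  expect_equal(k0[pair_idx("A", "K")], 1)
  expect_equal(k0[pair_idx("K", "A")], 1)
  expect_equal(sum(k0), 24)
  expect_equal(unname(k0[-c(pair_idx("A", "A"), pair_idx("A", "K"),
                            pair_idx("K", "A"))]), rep(0, 438))
  # per-k sums and full brute-force oracle on random fragments
  set.seed(13)
  for (f in random_fragments(4)) {
    v <- encode_cksaap(f, k_max = 4)
    ch <- strsplit(f, "")[[1]]
    for (k in 0:4) {
      blk <- v[(k * 441 + 1):((k + 1) * 441)]
      expect_equal(sum(blk), 25 - k - 1)
      oracle <- numeric(441)
      for (i in seq_len(25 - k - 1)) {
        s <- pair_idx(ch[i], ch[i + k + 1])
        oracle[s] <- oracle[s] + 1
      }
      expect_equal(unname(blk), oracle)
    }
  }
  expect_error(encode_cksaap(random_fragment(), k_max = -1), "k_max")
})

test_that("reduced alphabets group residues as documented", {
  expect_equal(reduced_group("V", "six"), reduced_group("L", "six"))
  expect_equal(reduced_group("V", "nine"), reduced_group("L", "nine"))
  expect_equal(reduced_group("G", "six"), reduced_group("C", "six"))
  expect_false(reduced_group("G", "nine") == reduced_group("C", "nine"))
  set.seed(14)
  for (f in random_fragments(3)) {
    expect_equal(sum(encode_reduced(f, "six")), 24)
    expect_equal(sum(encode_reduced(f, "nine")), 24)
  }
  expect_error(encode_reduced(random_fragment(), "twelve"))
})

test_that("Z-scale lookups are exact and padding contributes zeros", {
  expect_equal(unname(zscales("A")[1, ]), c(0.24, -2.32, 0.60, -0.14, 1.30))
  expect_equal(unname(zscales("W")[1, ]), c(-4.36, 3.94, 0.59, 3.44, -1.59))
  f <- extract_fragment("MKR", 2)   # 11 O's each side
  v <- encode_zscales(f)
  expect_equal(v[1:55], rep(0, 55))           # 11 upstream O's
  expect_equal(v[66:120], rep(0, 55))         # 11 downstream O's
  expect_equal(v[56:60], unname(zscales("M")[1, ]))
})

test_that("hydrophobicity lookups are exact", {
  expect_equal(hydrophobicity(c("A", "I", "R", "K", "O")),
               c(1.81, 4.92, -14.92, -5.55, 0.0))
  expect_error(hydrophobicity("B"), "unknown")
})

test_that("hydrobinary appends the -1..+2 hydrophobicity tail", {
  # ... E K I D ... around the center
  ch <- rep("A", 25); ch[12] <- "E"; ch[13] <- "K"; ch[14] <- "I"; ch[15] <- "D"
  f <- paste(ch, collapse = "")
  v <- encode_hydrobinary(f)
  expect_length(v, 508L)
  expect_equal(v[505:508], c(-6.81, -5.55, 4.92, -8.72))
  expect_equal(v[1:504], encode_binary(f))
  # center K contributes -5.55 for any fragment
  set.seed(15)
  for (g in random_fragments(3)) expect_equal(encode_hydrobinary(g)[506], -5.55)
  # optional rescaling bounds the tail by 1
  expect_true(all(abs(encode_hydrobinary(f, scale = TRUE)[505:508]) <= 1))
})

test_that("pssm encoding copies profile rows and zero-fills padding", {
  set.seed(16)
  seqch <- sample(STANDARD_AA, 40, replace = TRUE)
  seqch[3] <- "K"; seqch[20] <- "K"
  prot <- paste(seqch, collapse = "")
  prof <- list(scores = matrix(rnorm(40 * 20), 40, 20))
  # interior site: 25 rows copied verbatim (checked against a naive loop)
  f20 <- extract_fragment(prot, 20)
  v <- encode_pssm(f20, prof, 20)
  oracle <- as.vector(t(prof$scores[8:32, ]))
  expect_equal(v, oracle)
  # N-terminal site: first 10 window positions padded -> zeros
  f3 <- extract_fragment(prot, 3)
  v3 <- encode_pssm(f3, prof, 3)
  expect_equal(v3[1:(10 * 20)], rep(0, 200))
  expect_equal(v3[201:500], as.vector(t(prof$scores[1:15, ])))
  # profile/fragment inconsistency is caught
  short <- list(scores = prof$scores[1:10, ])
  expect_error(encode_pssm(f20, short, 20), "outside profile")
  expect_error(encode_pssm(f20, list(scores = prof$scores[, 1:19]), 20), "20")
})

test_that("knn distance is a bounded symmetric metric-like function", {
  expect_equal(knn_distance(strrep("O", 25), strrep("O", 25)), 0.0)
  set.seed(17)
  sim <- normalized_blosum62()
  for (i in 1:10) {
    a <- random_fragment(); b <- random_fragment()
    d1 <- knn_distance(a, b)
    expect_identical(d1, knn_distance(b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_lte(knn_distance(a, a), d1 + 1e-12)  # self-distance dominates
  }
  # hand-evaluated oracle on 4-mers
  a <- "ACDK"; b <- "AWKE"
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  expect_equal(knn_distance(a, b),
               mean(1 - sim[cbind(ca, cb)]))
  expect_error(knn_distance("AAA", "AAAA"), "mismatch")
})

test_that("knn encoding matches an exhaustive nearest-neighbour oracle", {
  set.seed(18)
  pos <- random_fragments(6); neg <- random_fragments(6)
  f <- random_fragment()
  ks <- c(1L, 3L, 5L)
  got <- encode_knn(f, pos, neg, k_list = ks)
  dp <- sort(vapply(pos, function(p) knn_distance(f, p), numeric(1)))
  dn <- sort(vapply(neg, function(p) knn_distance(f, p), numeric(1)))
  expect_equal(got, vapply(ks, function(k)
    mean(dp[1:k]) / mean(dn[1:k]), numeric(1)))
  # identical to one positive reference at k = 1 -> ratio < 1
  got1 <- encode_knn(pos[1], pos, neg, k_list = 1L)
  expect_lt(got1, 1)
  # equidistant references -> all features 1 (same fragment both sides)
  same <- random_fragments(3)
  expect_equal(encode_knn(f, same, same, k_list = c(1L, 3L)), c(1, 1))
  expect_error(encode_knn(f, pos[1:2], neg, k_list = ks), "at least")
})

test_that("encode_dataset is deterministic and leaves self out for knn", {
  set.seed(19)
  ds <- as_fragment_ds(random_fragments(12), c(rep(1, 6), rep(0, 6)))
  e1 <- encode_dataset(ds, "binary")
  expect_equal(dim(e1$x), c(12L, 504L))
  expect_identical(e1, encode_dataset(ds, "binary"))
  # knn: a reference positive must not find itself at distance zero
  k <- encode_dataset(ds, "knn", list(k_list = c(1L, 3L)))
  expect_equal(dim(k$x), c(12L, 2L))
  expect_true(all(is.finite(k$x)))
  # with self-inclusion the nearest positive of fragment 1 is itself
  # (minimal BLOSUM62 self-distance), so the k = 1 ratio can only grow
  # once the self-match is excluded
  with_self <- encode_knn(ds$fragment[1], ds$fragment[ds$label == 1],
                          ds$fragment[ds$label == 0], k_list = 1L)
  expect_lte(with_self, k$x[1, 1])
  expect_lt(with_self, 1)
  expect_gt(k$x[1, 1], 0)
})
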