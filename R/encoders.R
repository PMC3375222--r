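# Feature encoders: turn a lysine-centered window into a fixed-length
# numeric vector under one of eight schemes. All encoders are pure
# functions of their declared inputs.
#
# Dimension contracts for the default window (half-width n = 12, 25-mer):
#   binary      21 * 2n        = 504
#   cksaap      441 * (kmax+1) = 2205 (kmax = 4)
#   six         6 * 2n         = 144
#   nine        9 * 2n         = 216
#   zscales     5 * 2n         = 120
#   hydrobinary 21 * 2n + 4    = 508
#   pssm        20 * (2n+1)    = 500
#   knn         length(k_list) = 6

.frag_chars <- function(fragment) {
  ch <- strsplit(fragment, "", fixed = TRUE)[[1]]
  w <- length(ch)
  if (w %% 2L == 0L) stop("fragment length must be odd, got ", w)
  center <- (w + 1L) %/% 2L
  if (ch[center] != "K") stop("central residue is not K")
  ch
}

.noncenter <- function(ch) ch[-((length(ch) + 1L) %/% 2L)]

#' One-hot (binary) encoding
#'
#' Each of the `2n` non-center positions is a 21-slot one-hot block over
#' the alphabet `A..Y,O`; the constant central K is omitted. Blocks run
#' upstream to downstream.
#'
#' @param fragment Window string with central K.
#' @return Numeric vector of length `21 * 2n` (504 for a 25-mer).
#' @export
encode_binary <- function(fragment) {
  ch <- .noncenter(.frag_chars(fragment))
  idx <- alphabet_index(ch)
  v <- numeric(21L * length(ch))
  v[(seq_along(ch) - 1L) * 21L + idx] <- 1
  v
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each gap `k` in `0..k_max`, counts every ordered pair
#' `(x_i, x_{i+k+1})` over the whole window (central K included). Pairs
#' are indexed row-major over the 21-letter alphabet, so each gap
#' contributes a 441-slot count block.
#'
#' @param fragment Window string with central K.
#' @param k_max Largest gap considered (default 4).
#' @return Numeric count vector of length `441 * (k_max + 1)` (2205).
#' @export
encode_cksaap <- function(fragment, k_max = 4L) {
  if (k_max < 0L) stop("k_max must be >= 0")
  ch <- .frag_chars(fragment)
  idx <- alphabet_index(ch)
  w <- length(idx)
  v <- numeric(441L * (k_max + 1L))
  for (k in 0:k_max) {
    npair <- w - k - 1L
    if (npair <= 0L) next
    a <- idx[seq_len(npair)]
    b <- idx[seq_len(npair) + k + 1L]
    slot <- k * 441L + (a - 1L) * 21L + b
    tab <- tabulate(slot, nbins = 441L * (k_max + 1L))
    v <- v + tab
  }
  v
}

#' Reduced-alphabet one-hot encoding
#'
#' Maps each non-center residue to a physicochemical group and one-hot
#' encodes the group. The six-letter variant uses aliphatic / charged /
#' polar / cyclic / other / padding; the nine-letter variant splits
#' "other" into G, P, M and C singletons.
#'
#' @param fragment Window string with central K.
#' @param variant `"six"` or `"nine"`.
#' @return Numeric vector of length `6 * 2n` (144) or `9 * 2n` (216).
#' @export
encode_reduced <- function(fragment, variant = c("six", "nine")) {
  variant <- match.arg(variant)
  g <- reduced_group(.noncenter(.frag_chars(fragment)), variant)
  ng <- if (variant == "six") 6L else 9L
  v <- numeric(ng * length(g))
  v[(seq_along(g) - 1L) * ng + g] <- 1
  v
}

#' Z-scale encoding
#'
#' Concatenates the five physicochemical Z-scale descriptors of each
#' non-center residue, upstream to downstream; padding positions
#' contribute zeros.
#'
#' @param fragment Window string with central K.
#' @return Numeric vector of length `5 * 2n` (120).
#' @export
encode_zscales <- function(fragment) {
  ch <- .noncenter(.frag_chars(fragment))
  as.vector(t(zscales(ch)))
}

#' Hydrophobicity-augmented one-hot encoding
#'
#' The one-hot encoding of [encode_binary()] extended with four raw
#' hydrophobicity values covering the recognition region around the
#' modified lysine: offsets -1, 0 (the K itself), +1 and +2, in that
#' order. With `scale = TRUE` the four values are divided by the largest
#' absolute value on the scale so they are bounded by 1 like the one-hot
#' block.
#'
#' @param fragment Window string with central K.
#' @param scale Rescale the hydrophobicity tail to `[-1, 1]`? Default
#'   `FALSE` (raw scale values).
#' @return Numeric vector of length `21 * 2n + 4` (508).
#' @export
encode_hydrobinary <- function(fragment, scale = FALSE) {
  ch <- .frag_chars(fragment)
  center <- (length(ch) + 1L) %/% 2L
  tail4 <- hydrophobicity(ch[center + c(-1L, 0L, 1L, 2L)])
  if (scale) tail4 <- tail4 / max(abs(unlist(.HYDROPHOBICITY)))
  c(encode_binary(fragment), tail4)
}

#' Read an NCBI ASCII PSSM profile
#'
#' Parses the 20-column log-odds block of a PSI-BLAST ASCII position
#' specific scoring matrix (`-out_ascii_pssm`). Columns are reordered
#' from NCBI order (`ARNDCQEGHILKMFPSTWYV`) to alphabetical
#' (`ACDEFGHIKLMNPQRSTVWY`).
#'
#' @param path Path to the ASCII PSSM file.
#' @return List with `residues` (character vector, the protein sequence as
#'   given in the profile) and `scores` (numeric matrix, one row per
#'   residue, 20 alphabetically-ordered columns).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  ncbi <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  # data rows: index, residue letter, then >= 20 numeric fields
  rows <- list(); res <- character()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 22L) next
    if (is.na(suppressWarnings(as.integer(tok[1])))) next
    if (!(tok[2] %in% c(STANDARD_AA, "X"))) next
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) next
    rows[[length(rows) + 1L]] <- vals
    res <- c(res, tok[2])
  }
  if (!length(rows)) stop("no PSSM data rows found in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- ncbi
  list(residues = res, scores = m[, STANDARD_AA, drop = FALSE])
}

#' PSSM (evolutionary profile) encoding
#'
#' Concatenates the 20-score profile row for each of the `2n+1` window
#' positions; positions outside the protein (padding) contribute zeros.
#'
#' @param fragment Window string with central K.
#' @param profile Profile as returned by [read_pssm()] (or a list with a
#'   `scores` matrix of one 20-column row per protein residue).
#' @param position 1-based position of the central lysine on the protein.
#' @return Numeric vector of length `20 * (2n+1)` (500).
#' @export
encode_pssm <- function(fragment, profile, position) {
  ch <- .frag_chars(fragment)
  w <- length(ch)
  n <- (w - 1L) %/% 2L
  scores <- profile$scores
  if (ncol(scores) != 20L) stop("profile must have 20 score columns")
  len <- nrow(scores)
  if (position < 1L || position > len)
    stop("site position ", position, " outside profile of length ", len)
  out <- matrix(0, nrow = w, ncol = 20L)
  for (i in seq_len(w)) {
    p <- position - n + (i - 1L)
    inside <- p >= 1L && p <= len
    if (inside != (ch[i] != "O"))
      stop("fragment padding inconsistent with profile length ", len,
           " at window offset ", i - n - 1L)
    if (inside) out[i, ] <- scores[p, ]
  }
  as.vector(t(out))
}

#' BLOSUM62 fragment distance
#'
#' Mean over aligned positions of `1 - sim(a_i, b_i)`, where `sim` is the
#' min-max normalized BLOSUM62 similarity ([normalized_blosum62()]).
#' Symmetric and bounded in `[0, 1]`; 0 iff every aligned pair attains
#' the maximal similarity.
#'
#' @param a,b Fragment strings of equal length.
#' @return Distance in `[0, 1]`.
#' @export
knn_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("fragment length mismatch: ", nchar(a), " vs ", nchar(b))
  A <- fragment_index_matrix(a)
  B <- fragment_index_matrix(b)
  fragment_distance_matrix(A, B, normalized_blosum62())[1, 1]
}

#' Nearest-neighbour ratio (KNN) encoding
#'
#' For each `k` in `k_list`, computes the mean BLOSUM62 distance from the
#' fragment to its `k` nearest positive references (`D_p`) and to its `k`
#' nearest negative references (`D_n`); the feature is the ratio
#' `D_p / D_n` (small when the fragment sits in the positive
#' neighbourhood). When encoding a fragment that is itself a reference,
#' exclude it from its reference set first (see [encode_dataset()], which
#' does this by index).
#'
#' @param fragment Window string with central K.
#' @param positives,negatives Character vectors of reference fragments.
#' @param k_list Neighbourhood sizes (default `c(1, 3, 5, 7, 9, 15)`).
#' @return Numeric vector of length `length(k_list)`.
#' @export
encode_knn <- function(fragment, positives, negatives,
                       k_list = c(1L, 3L, 5L, 7L, 9L, 15L)) {
  kmax <- max(k_list)
  if (length(positives) < kmax || length(negatives) < kmax)
    stop("reference sets must each contain at least ", kmax, " fragments")
  sim <- normalized_blosum62()
  A <- fragment_index_matrix(fragment)
  dp <- sort(fragment_distance_matrix(A, fragment_index_matrix(positives), sim)[1, ])
  dn <- sort(fragment_distance_matrix(A, fragment_index_matrix(negatives), sim)[1, ])
  vapply(k_list, function(k) {
    Dp <- mean(dp[seq_len(k)]); Dn <- mean(dn[seq_len(k)])
    if (Dn == 0) stop("degenerate reference: D_n = 0 at k = ", k)
    Dp / Dn
  }, numeric(1))
}

.SCHEMES <- c("binary", "cksaap", "six", "nine", "zscales",
              "hydrobinary", "pssm", "knn")

#' Feature-vector dimension of a scheme
#'
#' @param scheme Scheme name.
#' @param n Window half-width.
#' @param k_max CKSAAP gap bound.
#' @param k_list KNN neighbourhood sizes.
#' @return Integer dimension.
#' @export
scheme_dimension <- function(scheme, n = 12L, k_max = 4L,
                             k_list = c(1L, 3L, 5L, 7L, 9L, 15L)) {
  switch(match.arg(scheme, .SCHEMES),
         binary = 21L * 2L * n,
         cksaap = 441L * (k_max + 1L),
         six = 6L * 2L * n,
         nine = 9L * 2L * n,
         zscales = 5L * 2L * n,
         hydrobinary = 21L * 2L * n + 4L,
         pssm = 20L * (2L * n + 1L),
         knn = length(k_list))
}

#' Encode a whole dataset under one scheme
#'
#' Applies the per-fragment encoder to every row of a `fragment_dataset`,
#' in dataset order.
#'
#' Scheme-specific `options`:
#' * `knn`: `positives` / `negatives` — reference fragment vectors. When
#'   omitted, the dataset's own fragments are the references and each
#'   fragment is excluded (by index) from its own reference set, so a
#'   reference fragment never finds itself at distance zero. `k_list`
#'   overrides the neighbourhood sizes.
#' * `pssm`: `profiles` — named list of [read_pssm()] profiles keyed by
#'   `protein_id`.
#' * `cksaap`: `k_max`. `hydrobinary`: `scale`.
#'
#' @param dataset A `fragment_dataset`.
#' @param scheme One of `"binary"`, `"cksaap"`, `"six"`, `"nine"`,
#'   `"zscales"`, `"hydrobinary"`, `"pssm"`, `"knn"`.
#' @param options Named list of scheme options (see above).
#' @return List with `x` (feature matrix, one row per fragment) and `y`
#'   (integer label vector).
#' @export
encode_dataset <- function(dataset, scheme, options = list()) {
  scheme <- match.arg(scheme, .SCHEMES)
  frags <- dataset$fragment
  x <- switch(scheme,
    binary = t(vapply(frags, encode_binary, numeric(scheme_dimension("binary")))),
    cksaap = {
      k_max <- if (is.null(options$k_max)) 4L else as.integer(options$k_max)
      t(vapply(frags, encode_cksaap,
               numeric(scheme_dimension("cksaap", k_max = k_max)), k_max = k_max))
    },
    six = t(vapply(frags, encode_reduced, numeric(scheme_dimension("six")),
                   variant = "six")),
    nine = t(vapply(frags, encode_reduced, numeric(scheme_dimension("nine")),
                    variant = "nine")),
    zscales = t(vapply(frags, encode_zscales, numeric(scheme_dimension("zscales")))),
    hydrobinary = {
      sc <- isTRUE(options$scale)
      t(vapply(frags, encode_hydrobinary,
               numeric(scheme_dimension("hydrobinary")), scale = sc))
    },
    pssm = {
      if (is.null(options$profiles)) stop("pssm encoding requires options$profiles")
      t(mapply(function(f, pid, pos) {
        prof <- options$profiles[[pid]]
        if (is.null(prof)) stop("no PSSM profile for protein ", pid)
        encode_pssm(f, prof, pos)
      }, frags, dataset$protein_id, dataset$position))
    },
    knn = .encode_dataset_knn(dataset, options))
  dimnames(x) <- NULL
  list(x = x, y = dataset$label)
}

.encode_dataset_knn <- function(dataset, options) {
  k_list <- if (is.null(options$k_list)) c(1L, 3L, 5L, 7L, 9L, 15L)
            else as.integer(options$k_list)
  sim <- normalized_blosum62()
  Q <- fragment_index_matrix(dataset$fragment)
  self_ref <- is.null(options$positives) && is.null(options$negatives)
  if (self_ref) {
    pos_idx <- which(dataset$label == 1L)
    neg_idx <- which(dataset$label == 0L)
    P <- Q[pos_idx, , drop = FALSE]
    N <- Q[neg_idx, , drop = FALSE]
  } else {
    if (is.null(options$positives) || is.null(options$negatives))
      stop("provide both positives and negatives references, or neither")
    P <- fragment_index_matrix(options$positives)
    N <- fragment_index_matrix(options$negatives)
  }
  kmax <- max(k_list)
  if (nrow(P) < kmax + self_ref || nrow(N) < kmax + self_ref)
    stop("reference sets must each contain at least ", kmax, " fragments")
  DP <- fragment_distance_matrix(Q, P, sim)
  DN <- fragment_distance_matrix(Q, N, sim)
  out <- matrix(0, nrow(Q), length(k_list))
  for (i in seq_len(nrow(Q))) {
    dp <- DP[i, ]; dn <- DN[i, ]
    if (self_ref) {                      # leave-self-out by index
      if (dataset$label[i] == 1L) dp <- dp[pos_idx != i]
      else dn <- dn[neg_idx != i]
    }
    dp <- sort(dp); dn <- sort(dn)
    for (j in seq_along(k_list)) {
      k <- k_list[j]
      Dn <- mean(dn[seq_len(k)])
      if (Dn == 0) stop("degenerate reference: D_n = 0 for fragment ", i)
      out[i, j] <- mean(dp[seq_len(k)]) / Dn
    }
  }
  out
}
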