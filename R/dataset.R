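# Dataset construction: FASTA and site-table I/O, lysine-window extraction
# with terminal padding, greedy redundancy filtering, and seeded negative
# subsampling.
#
# Conventions: site positions are 1-based indices on the protein sequence;
# a window of half-width n (default 12) is the 2n+1-character string
# centered on the lysine, padded with "O" where it overhangs a terminus.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package operations do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Read a protein FASTA file
#'
#' Reads a multi-record FASTA file of amino-acid sequences. The header
#' token before the first whitespace becomes the record id; sequences are
#' uppercased. Records containing letters outside the 20 standard amino
#' acids (e.g. B, J, O, U, X, Z or `*`) are rejected with the offending
#' id and position, since downstream encoders reserve `O` for padding.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`, one row per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% STANDARD_AA))
    if (length(bad))
      stop("non-standard residue '", ch[bad[1]], "' in record '", ids[i],
           "' at position ", bad[1])
  }
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a site annotation table
#'
#' Tab-separated table with columns `protein_id`, `position` (1-based) and
#' `label` (1 = sumoylation site, 0 = non-site), with a header line.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `protein_id`, `position`, `label`.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(d)))
    stop("site table must have columns ", paste(need, collapse = ", "))
  if (!all(d$label %in% c(0L, 1L)))
    stop("site labels must be 0 or 1")
  d$position <- as.integer(d$position)
  d$label <- as.integer(d$label)
  d[need]
}

#' Write a site annotation table
#'
#' @param sites Data frame with columns `protein_id`, `position`, `label`.
#' @param path Output path.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites[c("protein_id", "position", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a padded lysine-centered window
#'
#' Returns the `2n+1`-character window centered on `position`; positions
#' before residue 1 or beyond the last residue are filled with the padding
#' symbol `O`.
#'
#' @param sequence Protein sequence string (standard amino acids only).
#' @param position 1-based position of the central lysine.
#' @param n Half-width of the window (default 12, window length 25).
#' @return The window string.
#' @examples
#' extract_fragment("ACDKEFG", 4)  # 9 O's, ACDKEFG, 9 O's
#' @export
extract_fragment <- function(sequence, position, n = 12L) {
  len <- nchar(sequence)
  if (position < 1L || position > len)
    stop("position ", position, " out of range 1..", len)
  if (substr(sequence, position, position) != "K")
    stop("residue at position ", position, " is '",
         substr(sequence, position, position), "', not K")
  lo <- position - n
  hi <- position + n
  core <- substr(sequence, max(1L, lo), min(len, hi))
  paste0(strrep("O", max(0L, 1L - lo)), core, strrep("O", max(0L, hi - len)))
}

.validate_fragments <- function(frags, n = 12L) {
  w <- 2L * n + 1L
  stopifnot(all(nchar(frags) == w))
  stopifnot(all(substr(frags, n + 1L, n + 1L) == "K"))
}

.new_fragment_dataset <- function(df, n = 12L, meta = list()) {
  attr(df, "window_n") <- n
  attr(df, "meta") <- meta
  class(df) <- c("fragment_dataset", "data.frame")
  df
}

#' @export
print.fragment_dataset <- function(x, ...) {
  cat("fragment_dataset: ", sum(x$label == 1L), " positives, ",
      sum(x$label == 0L), " negatives (window ",
      2L * attr(x, "window_n") + 1L, ")\n", sep = "")
  invisible(x)
}

#' Build the full candidate dataset from proteins and positive annotations
#'
#' Every annotated lysine becomes a positive fragment; every other lysine
#' in the listed proteins becomes a negative fragment. Fragments are
#' ordered positives first, then negatives, each in (protein order,
#' position) order, so that greedy redundancy filtering preferentially
#' retains positives.
#'
#' @param proteins Data frame from [read_fasta()].
#' @param positives Data frame with columns `protein_id`, `position`
#'   (1-based) of the annotated sumoylation sites.
#' @param n Window half-width.
#' @return A `fragment_dataset`: data frame with columns `fragment`,
#'   `label` (1/0), `protein_id`, `position`.
#' @export
build_candidate_set <- function(proteins, positives, n = 12L) {
  stopifnot(is.data.frame(proteins), is.data.frame(positives))
  key <- paste(positives$protein_id, positives$position)
  if (anyDuplicated(key)) {
    warning("collapsing ", sum(duplicated(key)), " duplicate annotation(s)")
    positives <- positives[!duplicated(key), , drop = FALSE]
  }
  unknown <- setdiff(positives$protein_id, proteins$id)
  if (length(unknown))
    stop("annotations reference unknown protein(s): ",
         paste(unknown, collapse = ", "))

  # offenders: annotated positions that are not lysines
  seq_of <- stats::setNames(proteins$sequence, proteins$id)
  res <- substr(seq_of[positives$protein_id], positives$position,
                positives$position)
  bad <- which(res != "K")
  if (length(bad))
    stop("positive annotation(s) not at a K residue: ",
         paste(sprintf("%s:%d(%s)", positives$protein_id[bad],
                       positives$position[bad], res[bad]), collapse = ", "))

  # positives in (protein order, position) order
  ord <- order(match(positives$protein_id, proteins$id), positives$position)
  positives <- positives[ord, , drop = FALSE]
  pos_key <- paste(positives$protein_id, positives$position)

  rows <- list()
  for (i in seq_len(nrow(proteins))) {
    ks <- which(strsplit(proteins$sequence[i], "", fixed = TRUE)[[1]] == "K")
    if (!length(ks)) next
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = proteins$id[i], position = ks, stringsAsFactors = FALSE)
  }
  all_k <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), position = integer())
  neg <- all_k[!(paste(all_k$protein_id, all_k$position) %in% pos_key), ,
               drop = FALSE]

  mk <- function(tab, label) {
    if (!nrow(tab)) return(data.frame(fragment = character(),
                                      label = integer(),
                                      protein_id = character(),
                                      position = integer(),
                                      stringsAsFactors = FALSE))
    frg <- mapply(function(p, q) extract_fragment(seq_of[[p]], q, n),
                  tab$protein_id, tab$position, USE.NAMES = FALSE)
    data.frame(fragment = frg, label = label, protein_id = tab$protein_id,
               position = tab$position, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(positives, 1L), mk(neg, 0L))
  rownames(out) <- NULL
  .validate_fragments(out$fragment, n)
  .new_fragment_dataset(out, n)
}

#' Ungapped positional identity between two equal-length fragments
#'
#' Fraction of positions carrying identical characters; the padding symbol
#' matching itself counts as identical. Symmetric by construction.
#'
#' @param a,b Fragment strings of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
fragment_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("fragment length mismatch: ", nchar(a), " vs ", nchar(b))
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca == cb)
}

#' Greedy redundancy filter at a sequence-identity threshold
#'
#' Single deterministic pass in dataset order: a fragment is kept iff its
#' positional identity with every previously kept fragment (positives and
#' negatives pooled) is strictly below `threshold`. Because
#' [build_candidate_set()] lists positives first, positives are
#' preferentially retained. Idempotent.
#'
#' @param dataset A `fragment_dataset`.
#' @param threshold Identity threshold in `(0, 1]` (default 0.40).
#' @return The filtered `fragment_dataset`.
#' @export
redundancy_filter <- function(dataset, threshold = 0.40) {
  if (!nrow(dataset)) stop("empty dataset")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  mat <- fragment_index_matrix(dataset$fragment)
  keep <- greedy_identity_filter(mat, threshold)
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  meta <- attr(dataset, "meta")
  meta$identity_threshold <- threshold
  .new_fragment_dataset(out, attr(dataset, "window_n"), meta)
}

# fragments -> integer matrix (one row per fragment) for C++ kernels
fragment_index_matrix <- function(frags) {
  ch <- strsplit(frags, "", fixed = TRUE)
  t(vapply(ch, alphabet_index, integer(nchar(frags[1]))))
}

#' Subsample negatives to a fixed positive:negative ratio
#'
#' Retains every positive and draws `ratio * n_positives` negatives
#' uniformly without replacement. Reproducible: the same seed yields the
#' same selection, and the caller's RNG state is left untouched.
#'
#' @param dataset A `fragment_dataset`.
#' @param ratio Negatives per positive (default 10).
#' @param seed Integer seed (required).
#' @return A `fragment_dataset` with positives first, then the sampled
#'   negatives in original dataset order.
#' @export
sample_negatives <- function(dataset, ratio = 10, seed) {
  pos <- which(dataset$label == 1L)
  neg <- which(dataset$label == 0L)
  need <- as.integer(round(ratio * length(pos)))
  if (length(neg) < need)
    stop("insufficient negatives: need ", need, ", have ", length(neg))
  pick <- with_seed(seed, sort(sample(neg, need)))
  out <- dataset[c(pos, pick), , drop = FALSE]
  rownames(out) <- NULL
  meta <- attr(dataset, "meta")
  meta$ratio <- ratio
  meta$sampling_seed <- seed
  .new_fragment_dataset(out, attr(dataset, "window_n"), meta)
}

#' Read a plain fragment list (one window per line)
#'
#' Loader for pre-extracted window lists: one fragment string per line,
#' blank lines ignored. All fragments are assigned the given label.
#'
#' @param path Path to the text file.
#' @param label 1 for positives, 0 for negatives.
#' @param n Window half-width the fragments must conform to.
#' @return A `fragment_dataset` (with `protein_id`/`position` set to NA).
#' @export
read_fragment_list <- function(path, label, n = 12L) {
  if (!file.exists(path)) stop("fragment list not found: ", path)
  lines <- trimws(readLines(path))
  lines <- toupper(lines[nzchar(lines)])
  bad <- which(nchar(lines) != 2L * n + 1L)
  if (length(bad))
    stop("line ", bad[1], ": fragment length ", nchar(lines[bad[1]]),
         ", expected ", 2L * n + 1L)
  if (any(substr(lines, n + 1L, n + 1L) != "K"))
    stop("fragment without central K at line ",
         which(substr(lines, n + 1L, n + 1L) != "K")[1])
  ok <- vapply(strsplit(lines, "", fixed = TRUE),
               function(ch) all(ch %in% FRAGMENT_ALPHABET), logical(1))
  if (!all(ok)) stop("illegal character in fragment at line ", which(!ok)[1])
  df <- data.frame(fragment = lines, label = as.integer(label),
                   protein_id = NA_character_, position = NA_integer_,
                   stringsAsFactors = FALSE)
  .new_fragment_dataset(df, n)
}

#' Write a plain fragment list
#'
#' @param dataset A `fragment_dataset` (or data frame with `fragment`).
#' @param path Output path.
#' @export
write_fragment_list <- function(dataset, path) {
  writeLines(dataset$fragment, path)
  invisible(path)
}

#' Combine fragment datasets
#'
#' @param ... `fragment_dataset` objects with the same window size.
#' @return A single `fragment_dataset` (rows concatenated in order).
#' @export
bind_fragments <- function(...) {
  parts <- list(...)
  ns <- unique(vapply(parts, function(p) attr(p, "window_n"), integer(1)))
  if (length(ns) != 1L) stop("window sizes differ")
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  .new_fragment_dataset(out, ns)
}
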