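# dataset module: FASTA/site parsing, window extraction, candidate-set
# construction, identity filtering, negative subsampling.

test_that("read_fasta parses records, preserves order, rejects bad residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKRK", ">P2", "acdk", "efg"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("P1", "P2"))
  expect_equal(rec$sequence, c("MKRK", "ACDKEFG"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKXRK"), bad)
  err <- expect_error(read_fasta(bad), "P1")
  expect_match(conditionMessage(err), "3")   # offending position

  notfasta <- withr::local_tempfile(fileext = ".txt")
  writeLines("MKRK", notfasta)
  expect_error(read_fasta(notfasta), "malformed FASTA")
})

test_that("extract_fragment pads termini and enforces the central K", {
  expect_equal(extract_fragment("MKR", 2),
               paste0(strrep("O", 11), "MKR", strrep("O", 11)))
  expect_equal(extract_fragment("ACDKEFG", 4),
               paste0(strrep("O", 9), "ACDKEFG", strrep("O", 9)))
  long <- paste0(strrep("A", 12), "K", strrep("C", 20))
  expect_equal(extract_fragment(long, 13), substr(long, 1, 25))
  expect_false(grepl("O", extract_fragment(long, 13)))
  expect_error(extract_fragment("MKR", 1), "not K")
  expect_error(extract_fragment("MKR", 9), "out of range")
})

test_that("build_candidate_set enumerates every lysine exactly once", {
  prot <- data.frame(id = c("P1", "P2", "P3"),
                     sequence = c("MKAKEA", "ACDEFG", "KKK"),
                     stringsAsFactors = FALSE)
  pos <- data.frame(protein_id = "P1", position = 2L)
  ds <- build_candidate_set(prot, pos)
  expect_equal(sum(ds$label == 1L), 1L)
  expect_equal(sum(ds$label == 0L), 1L + 3L)  # P1 K4 + P3 KKK; P2 contributes nothing
  expect_equal(ds$position[ds$label == 1L], 2L)
  # every fragment obeys the window contract
  expect_true(all(nchar(ds$fragment) == 25L))
  expect_true(all(substr(ds$fragment, 13, 13) == "K"))
  # positives + negatives = total K count
  total_k <- sum(vapply(strsplit(prot$sequence, ""), function(ch)
    sum(ch == "K"), integer(1)))
  expect_equal(nrow(ds), total_k)
  # positives come first
  expect_equal(ds$label, sort(ds$label, decreasing = TRUE))
})

test_that("build_candidate_set validates annotations", {
  prot <- data.frame(id = "P1", sequence = "MKAKEA", stringsAsFactors = FALSE)
  expect_error(
    build_candidate_set(prot, data.frame(protein_id = "P1", position = 1L)),
    "not at a K")
  expect_error(
    build_candidate_set(prot, data.frame(protein_id = "PX", position = 2L)),
    "unknown protein")
  expect_warning(
    ds <- build_candidate_set(prot, data.frame(protein_id = c("P1", "P1"),
                                               position = c(2L, 2L))),
    "duplicate")
  expect_equal(sum(ds$label == 1L), 1L)
})

test_that("fragment_identity is the fraction of matching positions", {
  f <- random_fragment()
  expect_equal(fragment_identity(f, f), 1.0)
  expect_equal(fragment_identity("AAAA", "AAAT"), 0.75)
  expect_equal(fragment_identity("ACDE", "WYVH"), 0.0)
  expect_error(fragment_identity("AAA", "AAAA"), "mismatch")
  # symmetry on random pairs
  for (i in 1:10) {
    a <- random_fragment(); b <- random_fragment()
    expect_identical(fragment_identity(a, b), fragment_identity(b, a))
  }
})

test_that("redundancy_filter keeps first of each over-threshold pair", {
  # trio: only the (1,3) pair exceeds the threshold -> 1, 2 kept, 3 removed
  set.seed(7)
  base <- strsplit(random_fragment(), "")[[1]]
  f1 <- paste(base, collapse = "")
  f3c <- base                       # 15/25 identity with f1 (> 0.40)
  f3c[c(1:5, 20:24)] <- "W"; f3c[13] <- "K"
  f3 <- paste(f3c, collapse = "")
  f2 <- random_fragment(pad_left = 3, pad_right = 3)  # unrelated
  # verify construction with the brute-force identity oracle
  stopifnot(fragment_identity(f1, f3) >= 0.40,
            fragment_identity(f1, f2) < 0.40,
            fragment_identity(f2, f3) < 0.40)
  ds <- as_fragment_ds(c(f1, f2, f3), c(1, 0, 0))
  out <- redundancy_filter(ds, 0.40)
  expect_equal(out$fragment, c(f1, f2))
  # duplicates: second copy removed
  dup <- as_fragment_ds(c(f1, f1), c(1, 0))
  expect_equal(nrow(redundancy_filter(dup, 0.4)), 1L)
  expect_error(redundancy_filter(ds, 0), "threshold")
  expect_error(redundancy_filter(ds, 1.5), "threshold")
})

test_that("redundancy_filter is idempotent and leaves no pair >= threshold", {
  set.seed(31)
  for (rep in 1:3) {
    frs <- c(random_fragments(30), random_fragments(10))
    frs[6] <- frs[2]                       # force some redundancy
    frs[25] <- frs[9]
    ds <- as_fragment_ds(frs, c(rep(1, 10), rep(0, 30)))
    out <- redundancy_filter(ds, 0.6)
    # brute-force all-pairs bound
    if (nrow(out) > 1) {
      for (i in 1:(nrow(out) - 1)) for (j in (i + 1):nrow(out))
        expect_lt(fragment_identity(out$fragment[i], out$fragment[j]), 0.6)
    }
    again <- redundancy_filter(out, 0.6)
    expect_equal(again$fragment, out$fragment)
  }
})

test_that("sample_negatives honors ratio, seed and errors", {
  ds <- as_fragment_ds(random_fragments(210), c(rep(1, 10), rep(0, 200)))
  out <- sample_negatives(ds, 10, seed = 42)
  expect_equal(sum(out$label == 1L), 10L)
  expect_equal(sum(out$label == 0L), 100L)
  out2 <- sample_negatives(ds, 10, seed = 42)
  expect_identical(out$fragment, out2$fragment)
  out3 <- sample_negatives(ds, 10, seed = 43)
  expect_false(identical(out$fragment, out3$fragment))
  small <- as_fragment_ds(random_fragments(25), c(rep(1, 5), rep(0, 20)))
  expect_error(sample_negatives(small, 10, seed = 1), "need 50.*have 20")
})

test_that("fragment lists round trip and validate", {
  set.seed(8)
  ds <- as_fragment_ds(random_fragments(8), rep(1, 8))
  f <- withr::local_tempfile(fileext = ".txt")
  write_fragment_list(ds, f)
  back <- read_fragment_list(f, 1L)
  expect_equal(back$fragment, ds$fragment)
  writeLines(c(ds$fragment, "SHORT"), f)
  expect_error(read_fragment_list(f, 1L), "length")
  writeLines(strrep("A", 25), f)  # no central K
  expect_error(read_fragment_list(f, 1L), "central K")
})

test_that("site tables round trip", {
  sites <- data.frame(protein_id = c("P1", "P2"), position = c(2L, 7L),
                      label = c(1L, 0L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites, f)
  expect_equal(read_site_table(f), sites)
})
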