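# Seeded synthetic proteomes with planted sumoylation signal. Proteins are
# drawn from a background residue distribution; positive sites are planted
# as the core consensus context (large hydrophobic residue at -1, the
# modified K, any residue at +1, E at +2), with a configurable fraction of
# positives planted *without* that context to mimic the roughly one quarter
# of experimentally confirmed sites that fall in non-consensus motifs.
# The generator exists to make every downstream module testable offline;
# it is a stated world, not a model of real proteomes.

.PSI <- c("V", "I", "L", "M", "F")  # large hydrophobic residues

# Swiss-Prot-like background composition (fractions)
.SWISSPROT_FREQS <- c(
  A = 0.0825, C = 0.0138, D = 0.0545, E = 0.0672, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0986,
  M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
  S = 0.0666, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292)

.background_freqs <- function(background) {
  if (is.character(background)) {
    switch(match.arg(background, c("uniform", "swissprot")),
           uniform = stats::setNames(rep(1 / 20, 20), STANDARD_AA),
           swissprot = .SWISSPROT_FREQS / sum(.SWISSPROT_FREQS))
  } else {
    if (!all(STANDARD_AA %in% names(background)))
      stop("background frequencies must name all 20 standard amino acids")
    background[STANDARD_AA] / sum(background[STANDARD_AA])
  }
}

.has_consensus <- function(chars, p) {
  p > 1L && p + 2L <= length(chars) &&
    chars[p - 1L] %in% .PSI && chars[p + 2L] == "E"
}

#' Generate a synthetic proteome with planted sumoylation sites
#'
#' Draws protein sequences from a background residue distribution, plants
#' `n_pos` positive lysines (a fraction carrying the hydrophobic-K-x-E
#' consensus context, the rest deliberately without it), and labels every
#' remaining lysine negative. Protein count is chosen so that the
#' negative:positive imbalance is close to `imbalance` in expectation.
#'
#' @param n_pos Number of positive sites to plant (default 200).
#' @param imbalance Target negatives-per-positive ratio (default 25).
#' @param nonconsensus_frac Fraction of positives planted without the
#'   consensus context (default 0.26).
#' @param len_range Protein length range, sampled uniformly (default
#'   80..300).
#' @param background `"uniform"`, `"swissprot"`, or a named frequency
#'   vector over the 20 standard amino acids.
#' @param clean_negatives Rewrite accidental consensus contexts at
#'   negative lysines (default TRUE) so the planted signal is the only
#'   consensus signal; set FALSE for a harder, more realistic world.
#' @param seed Integer seed (required; the same seed reproduces the
#'   proteome byte for byte).
#' @return List with `proteins` (data frame `id`, `sequence`),
#'   `positives` (data frame `protein_id`, `position`, `consensus`),
#'   `truth` (data frame `protein_id`, `position`, `label` covering every
#'   lysine) and `config` (the generator settings).
#' @export
generate_proteome <- function(n_pos = 200L, imbalance = 25,
                              nonconsensus_frac = 0.26,
                              len_range = c(80L, 300L),
                              background = "uniform",
                              clean_negatives = TRUE, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_pos < 1L) stop("n_pos must be >= 1")
  freqs <- .background_freqs(background)
  with_seed(seed, {
    # size the proteome so background lysines hit the imbalance target
    target_k <- n_pos + round(imbalance * n_pos)
    total_len <- ceiling(target_k / freqs[["K"]])
    mean_len <- mean(len_range)
    n_prot <- max(5L, as.integer(ceiling(total_len / mean_len)))
    lens <- sample(len_range[1]:len_range[2], n_prot, replace = TRUE)
    chars <- lapply(lens, function(L)
      sample(STANDARD_AA, L, replace = TRUE, prob = freqs))
    ids <- sprintf("SYN%04d", seq_len(n_prot))

    # choose planting slots: interior positions, >= 4 apart per protein
    cand <- do.call(rbind, lapply(seq_len(n_prot), function(i) {
      if (lens[i] < 30L) return(NULL)
      cbind(i, seq(14L, lens[i] - 14L))
    }))
    if (is.null(cand) || nrow(cand) < n_pos)
      stop("unsatisfiable config: not enough sequence space for ", n_pos,
           " sites")
    cand <- cand[sample(nrow(cand)), , drop = FALSE]
    taken <- vector("list", n_prot)
    slots <- matrix(0L, 0, 2)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; p <- cand[r, 2]
      if (!length(taken[[i]]) || all(abs(taken[[i]] - p) >= 4L)) {
        taken[[i]] <- c(taken[[i]], p)
        slots <- rbind(slots, cand[r, , drop = FALSE])
        if (nrow(slots) == n_pos) break
      }
    }
    if (nrow(slots) < n_pos)
      stop("unsatisfiable config: could not place ", n_pos, " sites")

    consensus <- stats::runif(n_pos) >= nonconsensus_frac
    for (s in seq_len(n_pos)) {
      i <- slots[s, 1]; p <- slots[s, 2]
      chars[[i]][p] <- "K"
      if (consensus[s]) {
        chars[[i]][p - 1L] <- sample(.PSI, 1L)
        chars[[i]][p + 2L] <- "E"
      } else if (.has_consensus(chars[[i]], p)) {
        chars[[i]][p - 1L] <- "S"  # break an accidental context
      }
    }

    planted_key <- paste(slots[, 1], slots[, 2])
    truth <- list()
    for (i in seq_len(n_prot)) {
      ks <- which(chars[[i]] == "K")
      if (!length(ks)) next
      lab <- as.integer(paste(i, ks) %in% planted_key)
      if (clean_negatives) {
        for (q in ks[lab == 0L]) {
          if (.has_consensus(chars[[i]], q)) chars[[i]][q + 2L] <- "Q"
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = ids[i], position = ks, label = lab,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    positives <- data.frame(
      protein_id = ids[slots[, 1]], position = slots[, 2],
      consensus = consensus, stringsAsFactors = FALSE)
    ord <- order(match(positives$protein_id, ids), positives$position)
    positives <- positives[ord, , drop = FALSE]
    rownames(positives) <- NULL

    list(
      proteins = data.frame(id = ids,
                            sequence = vapply(chars, paste, "", collapse = ""),
                            stringsAsFactors = FALSE),
      positives = positives,
      truth = truth,
      config = list(n_pos = n_pos, imbalance = imbalance,
                    nonconsensus_frac = nonconsensus_frac,
                    len_range = len_range, clean_negatives = clean_negatives,
                    seed = seed)
    )
  })
}

#' Write a synthetic proteome as on-disk fixtures
#'
#' Emits the same dialects the dataset loaders read: `proteins.fasta`,
#' `sites.tsv` (every lysine with its 0/1 label), and the fragment lists
#' `positive_k.txt` / `negative_k.txt` (one 25-mer window per line).
#'
#' @param proteome Result of [generate_proteome()].
#' @param dir Output directory (created if missing).
#' @param n Window half-width for the fragment lists.
#' @return Named vector of the file paths written.
#' @export
write_fixture <- function(proteome, dir, n = 12L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "proteins.fasta")
  writeLines(paste0(">", proteome$proteins$id, "\n", proteome$proteins$sequence),
             fasta)
  sites <- file.path(dir, "sites.tsv")
  write_site_table(proteome$truth, sites)
  ds <- build_candidate_set(proteome$proteins,
                            proteome$truth[proteome$truth$label == 1L, ], n)
  posf <- file.path(dir, "positive_k.txt")
  negf <- file.path(dir, "negative_k.txt")
  write_fragment_list(ds[ds$label == 1L, ], posf)
  write_fragment_list(ds[ds$label == 0L, ], negf)
  c(fasta = fasta, sites = sites, positive_k = posf, negative_k = negf)
}
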