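#' DNA-word dictionary
#'
#' A `word_dict` collects, for one word length n, every distinct "DNA
#' word" observed on the reference row of a set of promoter alignments,
#' together with the cross-species bookkeeping the downstream stages
#' need:
#' \itemize{
#'   \item `a` — number of appearances (loci) of the word;
#'   \item `c` — number of conserved instances: (locus, species) pairs in
#'     which the species' aligned subsequence equals the reference word
#'     exactly, summed over all loci (the reference row itself counts, so
#'     in the zero-mutation limit c = a * n_species);
#'   \item `profile` — per-base counts of species matching the reference
#'     base, summed over loci (the conservation curve, before
#'     normalisation);
#'   \item `ham` — per-species Hamming distance to the reference word,
#'     summed over loci, used to build the species similarity
#'     permutation. Gap characters count as mismatches.
#' }
#' `loci` records every instance with its promoter, 0-based start and
#' the number of species (including the reference) fully conserving it.
#'
#' @name word_dict
NULL

new_word_dict <- function(n, species, words, a, c, profile, ham, loci) {
  structure(list(n = n, species = species, words = words,
                 a = a, c = c, profile = profile, ham = ham, loci = loci),
            class = "word_dict")
}

#' @export
print.word_dict <- function(x, ...) {
  cat("<word_dict> ", length(x$words), " distinct words of length ", x$n,
      " over ", length(x$species), " species (", nrow(x$loci), " loci)\n",
      sep = "")
  invisible(x)
}

#' @export
length.word_dict <- function(x) length(x$words)

#' Subset a word dictionary by word index
#' @param dict a `word_dict`.
#' @param idx integer or logical index over words.
#' @return the subsetted `word_dict`.
#' @export
dict_subset <- function(dict, idx) {
  if (is.logical(idx)) idx <- which(idx)
  keep_loci <- dict$loci$word %in% idx
  loci <- dict$loci[keep_loci, , drop = FALSE]
  loci$word <- match(loci$word, idx)
  new_word_dict(dict$n, dict$species, dict$words[idx],
                dict$a[idx], dict$c[idx],
                dict$profile[idx, , drop = FALSE],
                dict$ham[idx, , drop = FALSE], loci)
}

# per-block sliding-window statistics; starts_cols selects specific
# 1-based alignment start columns (used when extracting known sites)
block_window_stats <- function(block, n, starts_cols = NULL) {
  r <- block$records
  chars <- t(vapply(r$text, function(s) strsplit(s, "")[[1L]],
                    character(nchar(r$text[1L]))))
  rownames(chars) <- r$species
  L <- ncol(chars)
  if (L < n) return(NULL)
  human <- chars[1L, ]
  valid <- human %in% DNA_BASES
  E <- chars == matrix(human, nrow = nrow(chars), ncol = L, byrow = TRUE)
  # window sums of matches per species via cumulative sums
  cs <- t(apply(E, 1L, cumsum))
  n_win <- L - n + 1L
  wsum <- cs[, n:L, drop = FALSE] -
    cbind(0, cs[, seq_len(n_win - 1L), drop = FALSE])
  vcs <- cumsum(valid)
  win_valid <- (vcs[n:L] - c(0, vcs[seq_len(n_win - 1L)])) == n
  if (is.null(starts_cols)) {
    starts <- which(win_valid)
  } else {
    starts <- starts_cols[starts_cols >= 1L & starts_cols <= n_win]
    starts <- starts[win_valid[starts]]
  }
  if (length(starts) == 0L) return(NULL)
  words <- vapply(starts, function(j)
    paste(human[j:(j + n - 1L)], collapse = ""), character(1L))
  # promoter coordinate (0-based) of each window start
  hpos <- cumsum(human != "-")
  start0 <- r$start[1L] + hpos[starts] - 1L
  colmatch <- colSums(E)
  profile <- matrix(vapply(starts, function(j) colmatch[j:(j + n - 1L)],
                           numeric(n)),
                    ncol = n, byrow = TRUE)
  ws <- wsum[, starts, drop = FALSE]
  conserved_species <- colSums(ws == n)
  ham <- t(ws) # n_win x n_species of match counts; convert below
  ham <- n - ham
  list(words = words, promoter = r$seqid[1L], start0 = start0,
       profile = profile, ham = ham,
       conserved_species = conserved_species)
}

aggregate_words <- function(parts, n, species) {
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  if (length(parts) == 0L) {
    return(new_word_dict(n, species, character(), integer(), numeric(),
                         matrix(0, 0, n), matrix(0, 0, length(species)),
                         data.frame(word = integer(), promoter = character(),
                                    start = integer(),
                                    conserved_species = integer())))
  }
  words_all <- unlist(lapply(parts, `[[`, "words"), use.names = FALSE)
  promoter <- unlist(lapply(parts, function(p)
    rep(p$promoter, length(p$words))), use.names = FALSE)
  start0 <- unlist(lapply(parts, `[[`, "start0"), use.names = FALSE)
  profile <- do.call(rbind, lapply(parts, `[[`, "profile"))
  ham <- do.call(rbind, lapply(parts, `[[`, "ham"))
  consp <- unlist(lapply(parts, `[[`, "conserved_species"),
                  use.names = FALSE)
  uw <- sort(unique(words_all))
  gi <- match(words_all, uw)
  a <- tabulate(gi, nbins = length(uw))
  c_tot <- as.numeric(rowsum(consp, gi)[, 1L])
  prof_sum <- rowsum(profile, gi)
  ham_sum <- rowsum(ham, gi)
  colnames(ham_sum) <- species
  loci <- data.frame(word = gi, promoter = promoter, start = start0,
                     conserved_species = consp, stringsAsFactors = FALSE)
  loci <- loci[order(loci$word, loci$promoter, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  new_word_dict(n, species, uw, a, c_tot, prof_sum, ham_sum, loci)
}

#' Extract the DNA-word dictionary from promoter alignments
#'
#' Slides a length-n window with step 1 over the reference row of every
#' alignment block; windows whose reference bases contain 'N' or a gap
#' are skipped. Per-species subsequences are taken from the same
#' alignment columns. Identical reference words are collapsed into one
#' dictionary entry with their conservation bookkeeping summed over
#' loci.
#'
#' @param blocks list of [new_maf_block()] objects (one or more
#'   promoters; the first record of each block is the reference row).
#' @param n word length (>= 1).
#' @return a [word_dict] (empty if `n` exceeds every block).
#' @export
extract_words <- function(blocks, n) {
  if (n < 1L) stop("word length must be >= 1")
  species <- blocks[[1L]]$records$species
  parts <- lapply(blocks, block_window_stats, n = n)
  aggregate_words(parts, n, species)
}

#' Extract the words at known binding-site loci
#'
#' Builds the learning-set dictionary: words taken at the given site
#' records rather than at every sliding position. All sites must have
#' length `end - start` equal to `n`.
#'
#' @param blocks list of [new_maf_block()] objects.
#' @param sites a [site_records()] data.frame.
#' @param n word length; sites of other lengths are ignored.
#' @return a [word_dict] over the site loci.
#' @export
extract_site_words <- function(blocks, sites, n) {
  species <- blocks[[1L]]$records$species
  sites <- sites[sites$end - sites$start == n, , drop = FALSE]
  parts <- lapply(blocks, function(b) {
    prom <- b$records$seqid[1L]
    s <- sites[sites$promoter == prom, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    # map promoter coordinates to alignment columns of the reference row
    human <- strsplit(b$records$text[1L], "")[[1L]]
    hpos <- cumsum(human != "-")
    cols <- match(s$start - b$records$start[1L] + 1L, hpos)
    cols <- cols[!is.na(cols)]
    if (length(cols) == 0L) return(NULL)
    block_window_stats(b, n, starts_cols = cols)
  })
  aggregate_words(parts, n, species)
}

#' Species similarity permutation of a dictionary word
#'
#' Orders the non-reference species by ascending (locus-summed) Hamming
#' distance between their aligned subsequence and the reference word;
#' ties are broken by the canonical species order of the alignment. The
#' reference row is excluded: its distance to its own word is always 0.
#'
#' @param dict a [word_dict].
#' @param i word index (default: all words).
#' @return for a single `i`, a character vector of species ids; otherwise
#'   a matrix with one row per word.
#' @export
species_permutation <- function(dict, i = NULL) {
  ham <- dict$ham[, -1L, drop = FALSE] # drop reference
  sp <- dict$species[-1L]
  one <- function(row) sp[order(row, seq_along(sp))]
  if (!is.null(i) && length(i) == 1L) return(one(ham[i, ]))
  rows <- if (is.null(i)) seq_len(nrow(ham)) else i
  t(vapply(rows, function(r) one(ham[r, ]), character(length(sp))))
}

prefix_keys <- function(dict, k) {
  perms <- species_permutation(dict)
  if (length(dict) == 0L) return(character())
  apply(perms[, seq_len(k), drop = FALSE], 1L, paste, collapse = "|")
}

#' Permutation-prefix filter
#'
#' Learning phase: collect the set of length-k species-permutation
#' prefixes of the known binding-site words. A dictionary word passes
#' iff its own length-k prefix is in that learned set. The intuition is
#' that true binding sites are conserved in characteristic subsets of
#' species, so their nearest-species orderings recur.
#'
#' @param dict a [word_dict] to filter.
#' @param site_dict a [word_dict] of known binding-site words (nonempty).
#' @param k prefix length (default 5).
#' @return the filtered [word_dict] (a subset of `dict`).
#' @export
prefix_filter <- function(dict, site_dict, k = 5) {
  n_avail <- length(dict$species) - 1L
  if (k < 1L) stop("prefix length k must be >= 1")
  if (k > n_avail)
    stop("prefix length k = ", k, " exceeds the ", n_avail,
         " non-reference species")
  if (length(site_dict) == 0L) stop("the learning set is empty")
  learned <- unique(prefix_keys(site_dict, k))
  keep <- prefix_keys(dict, k) %in% learned
  dict_subset(dict, keep)
}

#' Normalised conservation profiles of a dictionary
#'
#' The per-base fraction of (species, locus) pairs agreeing with the
#' reference base: `profile / (a * n_species)`, in \[0, 1\]. For a word
#' seen at a single locus this is the conservation curve divided by the
#' species count.
#'
#' @param dict a [word_dict].
#' @return numeric matrix, one row per word.
#' @export
conservation_profiles <- function(dict) {
  if (length(dict) == 0L) return(dict$profile)
  dict$profile / (dict$a * length(dict$species))
}

#' Conservation-curve filter
#'
#' Learning phase: store the normalised conservation profiles of the
#' known binding-site words. A dictionary word passes iff the minimum
#' Euclidean distance between its normalised profile and any learned
#' profile is at most `tolerance`. The shape of the conservation curve
#' is an intrinsic property of binding sites that this filter exploits.
#'
#' @param dict a [word_dict] to filter.
#' @param site_dict a [word_dict] of known binding-site words (nonempty).
#' @param tolerance maximum profile distance; see
#'   [calibrate_curve_tolerance()] for a data-driven choice.
#' @return the filtered [word_dict].
#' @export
conservation_curve_filter <- function(dict, site_dict, tolerance) {
  if (length(site_dict) == 0L) stop("the learning set is empty")
  if (site_dict$n != dict$n)
    stop("profile lengths differ: ", dict$n, " vs ", site_dict$n)
  P <- conservation_profiles(dict)
  Q <- conservation_profiles(site_dict)
  if (length(dict) == 0L) return(dict)
  d2 <- pmax(outer(rowSums(P^2), rep(1, nrow(Q))) +
               outer(rep(1, nrow(P)), rowSums(Q^2)) -
               2 * tcrossprod(P, Q), 0)
  mind <- sqrt(apply(d2, 1L, min))
  dict_subset(dict, mind <= tolerance + 1e-12)
}

#' Calibrate the conservation-curve tolerance on the learning set
#'
#' Leave-one-out distances: for each learned profile, the distance to
#' its nearest other learned profile; the tolerance is the given
#' percentile of those distances, so roughly that fraction of held-out
#' true sites would pass the filter.
#'
#' @param site_dict a [word_dict] of known binding-site words.
#' @param prob percentile (default 0.95).
#' @return numeric tolerance (0 if fewer than 2 learned profiles).
#' @export
calibrate_curve_tolerance <- function(site_dict, prob = 0.95) {
  Q <- conservation_profiles(site_dict)
  if (nrow(Q) < 2L) return(0)
  d2 <- as.matrix(stats::dist(Q))^2
  diag(d2) <- Inf
  loo <- sqrt(apply(d2, 1L, min))
  as.numeric(quantile(loo, prob, names = FALSE, type = 7))
}

#' Intersect two dictionaries
#'
#' The merging step: keep the words present in both input dictionaries
#' (which must come from the same extraction, so their bookkeeping
#' agrees), preserving the c/a tallies.
#'
#' @param d1,d2 [word_dict] objects from the same [extract_words()] run.
#' @return the intersection [word_dict].
#' @export
merge_dictionaries <- function(d1, d2) {
  dict_subset(d1, d1$words %in% d2$words)
}
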