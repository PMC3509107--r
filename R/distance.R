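#' Run decomposition of two equal-length sequences
#'
#' Splits the positions where the two sequences agree into maximal runs
#' of consecutive matching positions, left to right. The run lengths
#' satisfy sum(l) + Hamming(a, b) = L, and there are zero runs iff the
#' sequences disagree everywhere.
#'
#' @param a,b character scalars of equal length.
#' @return list with `n_s` (number of runs) and `l` (integer run
#'   lengths).
#' @export
run_decompose <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  if (length(ca) != length(cb))
    stop("sequences must have equal length (", length(ca), " vs ",
         length(cb), ")")
  if (length(ca) == 0L) stop("sequences must be non-empty")
  r <- rle(ca == cb)
  l <- r$lengths[r$values]
  list(n_s = length(l), l = as.integer(l))
}

#' Conglomerate distance between two equal-length sequences
#'
#' A run-aware dissimilarity: d(a, b) = L - (1/L) * sum_i l_i^2, where
#' l_i are the lengths of the maximal runs of matching positions. It is
#' 0 on identical sequences, L when no position matches, symmetric, and
#' at fixed Hamming distance it grows as the matching positions fragment
#' into more, shorter runs -- contiguous agreement ("chunks") is worth
#' more than scattered agreement. It is finer-grained than the Hamming
#' distance; it is a dissimilarity, not a metric (the triangle
#' inequality is not assumed).
#'
#' @param a,b character scalars of equal length.
#' @return non-negative numeric distance.
#' @export
conglomerate_distance <- function(a, b) {
  rd <- run_decompose(a, b)
  L <- nchar(a)
  L - sum(as.numeric(rd$l)^2) / L
}

# integer-code equal-length words into a K x n matrix for the C kernel
encode_words <- function(words, n) {
  matrix(match(unlist(strsplit(words, "", fixed = TRUE), use.names = FALSE),
               DNA_BASES),
         nrow = length(words), ncol = n, byrow = TRUE)
}

#' Conglomerate distances from one query word to many words
#'
#' Batch form of [conglomerate_distance()] (computed in C); equals the
#' scalar function applied elementwise.
#'
#' @param query character scalar.
#' @param words character vector of words of the same length.
#' @return numeric vector of distances.
#' @export
conglomerate_distances <- function(query, words) {
  n <- nchar(query)
  if (length(words) == 0L) return(numeric())
  if (any(nchar(words) != n)) stop("all words must have the query's length")
  cpp_cong_dist_batch(encode_words(words, n),
                      encode_words(query, n)[1L, ])
}
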