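#' Feature fingerprint of a motif cluster
#'
#' Projects a motif cluster of word length n into the (2n+4)-dimensional
#' feature space the DDS filter operates on:
#' \enumerate{
#'   \item n entropy-curve components (per-column PWM entropy, bits);
#'   \item n distance-distribution components: the normalised histogram,
#'     over bins 1..n, of pairwise Hamming distances among member
#'     sequences (all-zero for a singleton cluster, with a warning);
#'   \item a conservation score: the z-score of the total conserved
#'     instance count sum(c) against Binomial(n_species * sum(a),
#'     `background_rate`) -- a one-dimensional over-conservation
#'     statistic;
#'   \item the number of member loci fully conserved in at least one
#'     non-reference species;
#'   \item the average number of conserved species per site base;
#'   \item the average motif entropy per base.
#' }
#' For n = 15 the fingerprint has exactly 34 dimensions.
#'
#' @param cluster a [new_motif_cluster()].
#' @param background_rate probability that a background (non-site)
#'   instance is conserved in one species; used by the z-score segment.
#' @return numeric vector of length 2n+4 with a `segments` attribute.
#' @export
compute_fingerprint <- function(cluster, background_rate = 0.05) {
  n <- nchar(cluster$seqs[1L])
  ent <- cluster$entropy
  nmem <- length(cluster$seqs)
  dd <- numeric(n)
  if (nmem >= 2L) {
    enc <- encode_words(cluster$seqs, n)
    ham <- unlist(lapply(seq_len(nmem - 1L), function(i)
      colSums(t(enc[(i + 1L):nmem, , drop = FALSE]) != enc[i, ])))
    ham <- ham[ham >= 1L]
    if (length(ham)) dd <- tabulate(ham, nbins = n) / length(ham)
  } else {
    warning("singleton cluster: distance distribution is all-zero")
  }
  N <- cluster$n_species * sum(cluster$a)
  p <- background_rate
  z <- (sum(cluster$c) - N * p) / sqrt(N * p * (1 - p))
  n_conserved <- sum(cluster$loci$conserved_species >= 2L)
  cons_per_base <- sum(cluster$profile) / (n * sum(cluster$a))
  fp <- c(ent, dd, z, n_conserved, cons_per_base, mean(ent))
  attr(fp, "segments") <- c(entropy = n, distance = n, scalar = 4L)
  fp
}

# Rank-based component scan: order the database along every component by
# closeness to the query, walk the D lists round-robin one element per
# iteration, and stop at the first object tallied in >= h components (or
# at t_max iterations, falling back to the most-tallied object). The
# returned mask flags the components in which the stopping object was
# encountered. Ties within a component are broken by database order.
dds_scan_mask <- function(query, db, h, t_max) {
  D <- length(query)
  N <- nrow(db)
  mask <- integer(D)
  if (t_max < 1L || N == 0L) return(mask)
  ord <- lapply(seq_len(D), function(d) order(abs(db[, d] - query[d])))
  counts <- integer(N)
  first_seen <- rep(Inf, N)
  hits <- matrix(FALSE, nrow = D, ncol = N)
  step <- 0L
  t_cap <- min(t_max, N)
  for (t in seq_len(t_cap)) {
    for (d in seq_len(D)) {
      o <- ord[[d]][t]
      step <- step + 1L
      counts[o] <- counts[o] + 1L
      if (counts[o] == 1L) first_seen[o] <- step
      hits[d, o] <- TRUE
      if (counts[o] >= h) return(as.integer(hits[, o]))
    }
  }
  if (all(counts == 0L)) return(mask)
  best <- which(counts == max(counts))
  best <- best[which.min(first_seen[best])]
  as.integer(hits[, best])
}

#' Train the dynamic dimension selection (DDS) filter
#'
#' DDS is a one-class filter over cluster fingerprints. It never mixes
#' components into a joint metric: for a query it ranks the database
#' separately along every component and scans those rank lists
#' round-robin until some object has been encountered in at least `h`
#' components (or `t_max` iterations elapse). The components that
#' located that object form a binary mask -- the dynamically selected
#' dimensions. Training computes one mask per training fingerprint,
#' with the training object itself removed from the database while it
#' is processed. Because the scan is rank-based, rescaling any single
#' component across the whole database leaves every mask unchanged, so
#' heterogeneous feature magnitudes need no normalisation.
#'
#' @param train numeric matrix of training fingerprints (rows).
#' @param db numeric matrix of database fingerprints; defaults to
#'   `train` (leave-one-out behaviour).
#' @param h minimum number of component lists an object must appear in
#'   (default 4). Larger h makes masks richer and more stable; with
#'   very small h the mask space is too coarse for the min-Hamming
#'   acceptance rule to discriminate once many masks are learned.
#' @param t_max maximum scan iterations per list (default 64).
#' @param theta mask Hamming acceptance threshold for [dds_accept()].
#'   A mask produced by a quorum stop carries exactly `h` set bits, so
#'   mask distances live on \[0, 2h\]; the default `theta = h` accepts a
#'   query iff it shares more than half of its informative components
#'   with some training mask.
#' @param train_rows optional integer vector: for each training
#'   fingerprint, the row of `db` holding that same object, removed from
#'   the database while the object is processed (NA = not in the
#'   database). When `db` is identical to `train` this is inferred.
#' @return an object of class `dds_model`.
#' @export
dds_train <- function(train, db = train, h = 4, t_max = 64, theta = NULL,
                      train_rows = NULL) {
  train <- as.matrix(train)
  db <- as.matrix(db)
  D <- ncol(train)
  if (h > D) stop("h = ", h, " exceeds the fingerprint dimension ", D)
  if (nrow(db) == 0L) stop("database of fingerprints is empty")
  if (is.null(theta)) theta <- h
  if (is.null(train_rows)) {
    same <- identical(dim(train), dim(db)) &&
      isTRUE(all.equal(unname(train), unname(db)))
    train_rows <- if (same) seq_len(nrow(train)) else
      rep(NA_integer_, nrow(train))
  }
  masks <- t(vapply(seq_len(nrow(train)), function(i) {
    db_i <- if (is.na(train_rows[i])) db else
      db[-train_rows[i], , drop = FALSE]
    dds_scan_mask(train[i, ], db_i, h, t_max)
  }, integer(D)))
  structure(list(db = db, masks = masks, h = h, t_max = t_max,
                 theta = theta, D = D),
            class = "dds_model")
}

#' @export
print.dds_model <- function(x, ...) {
  cat("<dds_model> ", nrow(x$masks), " training masks over D = ", x$D,
      " components (h = ", x$h, ", t_max = ", x$t_max,
      ", theta = ", x$theta, ")\n", sep = "")
  invisible(x)
}

#' Accept or reject a fingerprint under a trained DDS model
#'
#' The query's component mask is computed by the same round-robin scan
#' against the model database; the query is accepted iff the Hamming
#' distance between its mask and the closest training mask is strictly
#' below `theta`.
#'
#' @param query numeric fingerprint vector.
#' @param model a [dds_train()] model.
#' @param theta optional threshold override.
#' @param exclude_row optional row of the model database holding the
#'   query itself, removed before scanning (so an object being screened
#'   never locates itself).
#' @return list with `accept` (logical), `mask_distance` (closest mask
#'   Hamming distance) and `mask`.
#' @export
dds_accept <- function(query, model, theta = model$theta,
                       exclude_row = NULL) {
  if (length(query) != model$D)
    stop("query dimension ", length(query), " != model dimension ", model$D)
  if (nrow(model$masks) == 0L) {
    warning("model has no training masks; rejecting")
    return(list(accept = FALSE, mask_distance = Inf,
                mask = integer(model$D)))
  }
  db <- if (is.null(exclude_row)) model$db else
    model$db[-exclude_row, , drop = FALSE]
  mask <- dds_scan_mask(query, db, model$h, model$t_max)
  dist <- min(colSums(abs(t(model$masks) - mask)))
  list(accept = dist < theta, mask_distance = dist, mask = mask)
}
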