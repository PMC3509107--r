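#' Motif cluster
#'
#' A motif prediction: a set of member DNA words (binding-site
#' candidates) of one length, with the conservation bookkeeping carried
#' over from the dictionary, the PWM built from the member sequences,
#' and its per-column entropy curve. The rank score `S` and average
#' entropy `E` are filled in by [rank_score()] / [average_entropy()].
#'
#' @param seqs character vector of member word sequences (equal length).
#' @param a,c per-member appearance and conservation tallies (see
#'   [word_dict]).
#' @param profile per-member conservation-count matrix (members x n).
#' @param loci data.frame of member loci with columns `member`,
#'   `promoter`, `start`, `conserved_species`.
#' @param n_species species count of the source alignment.
#' @param pseudocount PWM pseudocount.
#' @param id cluster identifier.
#' @return an object of class `motif_cluster`.
#' @export
new_motif_cluster <- function(seqs, a, c, profile, loci, n_species,
                              pseudocount = 0.01, id = "cluster") {
  pwm <- build_pwm(seqs, id = id, pseudocount = pseudocount)
  structure(list(seqs = seqs, a = as.numeric(a), c = as.numeric(c),
                 profile = profile, loci = loci,
                 n_species = n_species, pwm = pwm,
                 entropy = entropy_curve(pwm),
                 E = average_entropy(pwm),
                 S = NA_real_, P_c = NA_real_, P_a = NA_real_, id = id),
            class = "motif_cluster")
}

#' @export
print.motif_cluster <- function(x, ...) {
  cat("<motif_cluster> ", x$id, ": ", length(x$seqs), " members, length ",
      nchar(x$seqs[1L]), ", E = ", round(x$E, 3),
      if (!is.na(x$S)) paste0(", S = ", round(x$S, 3)) else "",
      "\n", sep = "")
  invisible(x)
}

cluster_from_dict <- function(dict, idx, pseudocount = 0.01,
                              id = "cluster") {
  keep <- dict$loci$word %in% idx
  loci <- dict$loci[keep, , drop = FALSE]
  loci <- data.frame(member = match(loci$word, idx),
                     promoter = loci$promoter, start = loci$start,
                     conserved_species = loci$conserved_species,
                     stringsAsFactors = FALSE)
  new_motif_cluster(dict$words[idx], dict$a[idx], dict$c[idx],
                    dict$profile[idx, , drop = FALSE], loci,
                    length(dict$species), pseudocount, id)
}

#' k-nearest-neighbour motif cluster around a dictionary word
#'
#' Builds the initial motif prediction for a query word: the query plus
#' its `k_members` nearest dictionary words under the conglomerate
#' distance, found by exact full scan. Ties at the cutoff distance are
#' broken lexicographically by word sequence.
#'
#' @param query a word present in `dict`.
#' @param dict a [word_dict].
#' @param k_members number of neighbours to retrieve (default 32).
#' @param pseudocount PWM pseudocount.
#' @return a [new_motif_cluster()] whose first member is the query.
#' @export
knn_cluster <- function(query, dict, k_members = 32, pseudocount = 0.01) {
  if (k_members < 1L) stop("k_members must be >= 1")
  qi <- match(query, dict$words)
  if (is.na(qi)) stop("query word is not in the dictionary")
  cand <- setdiff(seq_along(dict$words), qi)
  if (length(cand) < k_members)
    stop("dictionary holds only ", length(cand),
         " other words; k_members = ", k_members)
  d <- conglomerate_distances(query, dict$words[cand])
  ord <- cand[order(d, dict$words[cand])]
  idx <- c(qi, ord[seq_len(k_members)])
  cluster_from_dict(dict, idx, pseudocount, id = paste0("knn:", query))
}

drop_member <- function(cluster, m) {
  keep <- setdiff(seq_along(cluster$seqs), m)
  loci <- cluster$loci[cluster$loci$member %in% keep, , drop = FALSE]
  loci$member <- match(loci$member, keep)
  new_motif_cluster(cluster$seqs[keep], cluster$a[keep], cluster$c[keep],
                    cluster$profile[keep, , drop = FALSE], loci,
                    cluster$n_species, cluster$pwm$pseudocount, cluster$id)
}

min_curve_dist <- function(curve, learned_curves) {
  if (is.null(dim(learned_curves)))
    learned_curves <- matrix(learned_curves, nrow = 1L)
  sqrt(min(colSums((t(learned_curves) - curve)^2)))
}

#' Greedy entropy-profile refinement of a motif cluster
#'
#' Iteratively removes the member whose removal most decreases the
#' minimum Euclidean distance between the cluster's per-column entropy
#' curve and any learned entropy curve, until the distance drops to
#' `tau` or only `min_size` members remain. The PWM and entropy curve
#' are recomputed after each removal. A cluster already within `tau` is
#' returned unchanged.
#'
#' @param cluster a [new_motif_cluster()].
#' @param learned_curves numeric matrix of entropy curves (one row per
#'   known motif of the same length).
#' @param tau distance threshold at which refinement stops.
#' @param min_size smallest allowed cluster (default 5, must be >= 2).
#' @return the refined [new_motif_cluster()].
#' @export
greedy_refine <- function(cluster, learned_curves, tau, min_size = 5) {
  if (min_size < 2L) stop("min_size must be >= 2")
  if (is.null(dim(learned_curves)))
    learned_curves <- matrix(learned_curves, nrow = 1L)
  if (ncol(learned_curves) != length(cluster$entropy))
    stop("learned curves have length ", ncol(learned_curves),
         ", cluster curves have length ", length(cluster$entropy))
  n <- nchar(cluster$seqs[1L])
  nmem <- length(cluster$seqs)
  enc <- encode_words(cluster$seqs, n)
  counts <- vapply(seq_len(n), function(j) tabulate(enc[, j], nbins = 4L),
                   numeric(4L))
  pc <- cluster$pwm$pseudocount
  ent_of <- function(cnt) {
    cc <- cnt + pc
    p <- sweep(cc, 2L, colSums(cc), "/")
    -colSums(ifelse(p > 0, p * log2(p), 0))
  }
  active <- rep(TRUE, nmem)
  cols <- seq_len(n)
  repeat {
    d <- min_curve_dist(ent_of(counts), learned_curves)
    if (d <= tau || sum(active) <= min_size) break
    best_m <- 0L
    best_d <- Inf
    for (m in which(active)) {
      cnt2 <- counts
      ix <- cbind(enc[m, ], cols)
      cnt2[ix] <- cnt2[ix] - 1
      dm <- min_curve_dist(ent_of(cnt2), learned_curves)
      if (dm < best_d - 1e-12) { best_d <- dm; best_m <- m }
    }
    ix <- cbind(enc[best_m, ], cols)
    counts[ix] <- counts[ix] - 1
    active[best_m] <- FALSE
  }
  if (all(active)) return(cluster)
  drop_member(cluster, which(!active))
}

#' Rank score of a motif cluster
#'
#' Two bounded quality components are added: the phylogenetic
#' conservation P_c = sum(c_i) / (n_species * sum(a_i)) -- the fraction
#' of member instances conserved across species -- and the appearance
#' score P_a = sum(a_i) / (n_members * a_max), the members' appearance
#' counts normalised by the dictionary-wide maximum. S = P_c + P_a lies
#' in \[0, 2\]; higher is better. At equal S, clusters are ordered by
#' ascending average entropy (sharper motif first), see
#' [sort_clusters()].
#'
#' @param cluster a [new_motif_cluster()].
#' @param a_max maximum appearance count over the dictionary (must be >=
#'   every member's `a`).
#' @param n_species species count (defaults to the cluster's own).
#' @return the cluster with `S`, `P_c`, `P_a` filled in.
#' @export
rank_score <- function(cluster, a_max, n_species = cluster$n_species) {
  sum_a <- sum(cluster$a)
  if (sum_a == 0) stop("cluster has zero total appearances")
  if (a_max < max(cluster$a))
    stop("a_max is below a member's appearance count")
  cluster$P_c <- sum(cluster$c) / (n_species * sum_a)
  cluster$P_a <- sum_a / (length(cluster$seqs) * a_max)
  cluster$S <- cluster$P_c + cluster$P_a
  cluster
}

#' Order motif clusters by rank score, then average entropy
#'
#' Total order: descending S; ties broken by ascending average entropy
#' E (the sharper motif ranks higher), then by id for determinism.
#'
#' @param clusters list of ranked clusters.
#' @return the reordered list.
#' @export
sort_clusters <- function(clusters) {
  S <- vapply(clusters, `[[`, numeric(1L), "S")
  E <- vapply(clusters, `[[`, numeric(1L), "E")
  id <- vapply(clusters, `[[`, character(1L), "id")
  clusters[order(-S, E, id)]
}
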