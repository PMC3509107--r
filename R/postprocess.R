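#' Best Pearson correlation between two PWMs over offsets and strands
#'
#' Slides the two matrices against each other over every ungapped offset
#' with an overlap of at least `min(min_overlap, shorter length)`
#' columns, on the forward strand and against the reverse complement of
#' `q`, and computes the Pearson correlation of the flattened 4 x w
#' overlapping sub-matrices. Returns the maximum.
#'
#' The offset is the position of `q`'s first column relative to `p`'s
#' first column (may be negative); `strand` is "+" or "-" (reverse
#' complement of `q`).
#'
#' @param p,q [new_pwm()] objects.
#' @param min_overlap minimum overlap in columns (default 4).
#' @return list with `r`, `offset`, `strand`.
#' @export
pwm_pearson <- function(p, q, min_overlap = 4) {
  A <- p$matrix
  best <- list(r = -Inf, offset = 0L, strand = "+")
  minw <- min(min_overlap, ncol(A), ncol(q$matrix))
  warned <- FALSE
  for (strand in c("+", "-")) {
    B <- if (strand == "+") q$matrix else pwm_revcomp(q)$matrix
    ma <- ncol(A); mb <- ncol(B)
    for (s in seq(-(mb - minw), ma - minw)) {
      ja <- max(1L, 1L + s):min(ma, mb + s)
      jb <- ja - s
      x <- as.vector(A[, ja, drop = FALSE])
      y <- as.vector(B[, jb, drop = FALSE])
      r <- if (sd(x) == 0 || sd(y) == 0) {
        if (!warned) {
          warning("zero-variance PWM overlap; correlation set to 0")
          warned <- TRUE
        }
        0
      } else cor(x, y)
      if (r > best$r)
        best <- list(r = r, offset = as.integer(s), strand = strand)
    }
  }
  best
}

cluster_locus_keys <- function(cluster) {
  unique(paste(cluster$loci$promoter, cluster$loci$start, sep = ":"))
}

#' Purge redundant motif predictions
#'
#' Clusters sharing more than `max_share` of their member sites (overlap
#' of locus sets relative to the smaller cluster) are redundant; the
#' lower-ranked one is dropped. The sweep is deterministic: clusters are
#' visited in descending rank score S (ties by ascending E, then id),
#' and a cluster is kept iff it does not over-share with any
#' already-kept cluster.
#'
#' @param clusters list of ranked [new_motif_cluster()] objects.
#' @param max_share maximum tolerated shared-site fraction (default
#'   0.8).
#' @return the surviving clusters, in rank order.
#' @export
purge_similar <- function(clusters, max_share = 0.8) {
  if (length(clusters) <= 1L) return(clusters)
  clusters <- sort_clusters(clusters)
  keys <- lapply(clusters, cluster_locus_keys)
  kept <- integer()
  for (i in seq_along(clusters)) {
    redundant <- FALSE
    for (j in kept) {
      shared <- length(intersect(keys[[i]], keys[[j]]))
      denom <- min(length(keys[[i]]), length(keys[[j]]))
      if (denom > 0 && shared / denom > max_share) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  clusters[kept]
}

merge_min_overlap <- function(a, b) {
  max(4L, ceiling(0.75 * min(pwm_length(a), pwm_length(b))))
}

merge_component <- function(clusters, r_min) {
  # single cluster: nothing to do
  if (length(clusters) == 1L) return(clusters[[1L]])
  clusters <- sort_clusters(clusters)
  rep_c <- clusters[[1L]]
  m <- pwm_length(rep_c$pwm)
  counts <- matrix(0, nrow = 4L, ncol = m, dimnames = list(DNA_BASES, NULL))
  all_seqs <- character(); all_a <- numeric(); all_c <- numeric()
  all_prof <- NULL; all_loci <- NULL
  off <- 0L
  for (cl in clusters) {
    al <- if (identical(cl$id, rep_c$id)) list(offset = 0L, strand = "+")
          else pwm_pearson(rep_c$pwm, cl$pwm,
                           min_overlap = merge_min_overlap(rep_c$pwm,
                                                           cl$pwm))
    seqs <- cl$seqs
    if (al$strand == "-") seqs <- revcomp_seq(seqs)
    enc <- encode_words(seqs, nchar(seqs[1L]))
    for (jj in seq_len(ncol(enc))) {
      col <- al$offset + jj
      if (col >= 1L && col <= m) {
        tab <- tabulate(enc[, jj], nbins = 4L)
        counts[, col] <- counts[, col] + tab
      }
    }
    all_seqs <- c(all_seqs, cl$seqs)
    all_a <- c(all_a, cl$a)
    all_c <- c(all_c, cl$c)
    all_prof <- rbind(all_prof, cl$profile)
    lo <- cl$loci
    lo$member <- lo$member + off
    all_loci <- rbind(all_loci, lo)
    off <- off + length(cl$seqs)
  }
  merged <- new_motif_cluster(all_seqs, all_a, all_c, all_prof, all_loci,
                              rep_c$n_species, rep_c$pwm$pseudocount,
                              id = rep_c$id)
  merged$pwm <- pwm_from_counts(counts, id = rep_c$id,
                                pseudocount = rep_c$pwm$pseudocount)
  merged$entropy <- entropy_curve(merged$pwm)
  merged$E <- average_entropy(merged$pwm)
  merged$S <- rep_c$S; merged$P_c <- rep_c$P_c; merged$P_a <- rep_c$P_a
  merged
}

revcomp_seq <- function(seqs) {
  vapply(seqs, function(s) {
    paste(rev(c(A = "T", C = "G", G = "C", T = "A")[strsplit(s, "")[[1L]]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Merge highly correlated motif predictions
#'
#' Single-linkage grouping: clusters whose pairwise [pwm_pearson()]
#' correlation reaches `r_min` are connected; each connected component
#' is merged into one cluster whose PWM is rebuilt from the pooled
#' member sites placed at their best offsets (and strands) relative to
#' the component's top-ranked cluster -- not by averaging matrices.
#'
#' Because merging declares two predictions redundant, the correlation
#' is required over a substantial overlap (at least 3/4 of the shorter
#' motif, and never below 4 columns): two distinct motifs sharing a
#' half-site must not chain into one prediction.
#'
#' @param clusters list of [new_motif_cluster()] objects.
#' @param r_min correlation threshold (default 0.85).
#' @return list of merged clusters.
#' @export
merge_correlated <- function(clusters, r_min = 0.85) {
  k <- length(clusters)
  if (k <= 1L) return(clusters)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      mo <- merge_min_overlap(clusters[[i]]$pwm, clusters[[j]]$pwm)
      if (pwm_pearson(clusters[[i]]$pwm, clusters[[j]]$pwm,
                      min_overlap = mo)$r >= r_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1L))
  lapply(unique(roots), function(r) {
    merge_component(clusters[roots == r], r_min)
  })
}

#' Validate predictions against a collection of known PWMs
#'
#' For every known motif, finds the best-matching prediction by
#' [pwm_pearson()]; a known motif counts as rediscovered when its best
#' correlation reaches `r_min`. When `shuffle_control` is set, the same
#' matching is run against column-shuffled copies of the known PWMs (a
#' chance-level control with identical per-column value multisets), and
#' the fraction of predictions matching at least one shuffled PWM is
#' reported.
#'
#' @param predictions list of [new_motif_cluster()] objects or
#'   [new_pwm()] objects.
#' @param known list of known [new_pwm()] objects.
#' @param r_min match threshold (default 0.85).
#' @param shuffle_control run the column-shuffled random control.
#' @param seed seed for the control shuffling.
#' @param min_overlap minimum aligned columns for a match to count; by
#'   default 3/4 of the shorter motif (floor 4). A rediscovery claim
#'   must rest on most of the motif, not on a 4-column fragment --
#'   otherwise sharp random controls match constantly.
#' @return list of class `match_report`: `per_known` data.frame (known
#'   id, best prediction, r, offset, strand, matched), `success_rate`,
#'   and `control_match_rate` (NA when the control is off).
#' @export
validate_predictions <- function(predictions, known, r_min = 0.85,
                                 shuffle_control = TRUE, seed = 1L,
                                 min_overlap = NULL) {
  if (length(known) == 0L) stop("the known PWM set is empty")
  pred_pwms <- lapply(predictions, function(p) if (is_pwm(p)) p else p$pwm)
  ov <- function(a, b) min_overlap %||% merge_min_overlap(a, b)
  per_known <- do.call(rbind, lapply(known, function(kp) {
    if (length(pred_pwms) == 0L)
      return(data.frame(known = kp$id, prediction = NA_character_,
                        r = NA_real_, offset = NA_integer_,
                        strand = NA_character_, matched = FALSE))
    hits <- lapply(pred_pwms, function(pp)
      pwm_pearson(kp, pp, min_overlap = ov(kp, pp)))
    rs <- vapply(hits, `[[`, numeric(1L), "r")
    b <- which.max(rs)
    data.frame(known = kp$id, prediction = pred_pwms[[b]]$id,
               r = rs[b], offset = hits[[b]]$offset,
               strand = hits[[b]]$strand, matched = rs[b] >= r_min)
  }))
  success <- if (length(pred_pwms)) mean(per_known$matched) else 0
  control <- NA_real_
  if (shuffle_control && length(pred_pwms)) {
    shuffled <- lapply(seq_along(known), function(i)
      shuffle_pwm_columns(known[[i]], seed = seed + i))
    control <- mean(vapply(pred_pwms, function(pp) {
      any(vapply(shuffled, function(sp)
        pwm_pearson(sp, pp, min_overlap = ov(sp, pp))$r >= r_min,
        logical(1L)))
    }, logical(1L)))
  }
  structure(list(per_known = per_known, success_rate = success,
                 control_match_rate = control, r_min = r_min),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report> ", nrow(x$per_known), " known motifs, success rate ",
      round(100 * x$success_rate, 1), "% at r >= ", x$r_min, sep = "")
  if (!is.na(x$control_match_rate))
    cat("; shuffled-control match rate ",
        round(100 * x$control_match_rate, 1), "%", sep = "")
  cat("\n")
  invisible(x)
}
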