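#' Group motif occurrences along each promoter
#'
#' A "group" is a maximal run of motif occurrences on one promoter in
#' which consecutive occurrences are separated by at most `max_gap`
#' base pairs (gap measured from the end of one occurrence to the start
#' of the next; the boundary value is inclusive). Occurrences are
#' ordered by start, ties by motif id; overlapping occurrences are kept.
#' A motif occurrence and its reverse-strand occurrence are distinct
#' tokens.
#'
#' @param sites a [site_records()] data.frame.
#' @param max_gap maximum intra-group gap in bp (default 1000).
#' @return list of `promoter_group` objects, each with `id`, `promoter`,
#'   `occ` (ordered occurrence data.frame) and `tokens` (the motif
#'   symbol string: "motif/strand" per occurrence).
#' @export
build_groups <- function(sites, max_gap = 1000) {
  out <- list()
  for (prom in unique(sites$promoter)) {
    s <- sites[sites$promoter == prom, , drop = FALSE]
    s <- s[order(s$start, s$motif), , drop = FALSE]
    gap_break <- c(FALSE, s$start[-1L] - s$end[-nrow(s)] > max_gap)
    gid <- cumsum(gap_break)
    for (g in unique(gid)) {
      occ <- s[gid == g, , drop = FALSE]
      rownames(occ) <- NULL
      out[[length(out) + 1L]] <- structure(
        list(id = sprintf("%s.g%d", prom, g + 1L), promoter = prom,
             occ = occ,
             tokens = paste0(occ$motif, "/", occ$strand)),
        class = "promoter_group")
    }
  }
  out
}

#' @export
print.promoter_group <- function(x, ...) {
  cat("<promoter_group> ", x$id, ": ", length(x$tokens), " occurrences [",
      paste(x$tokens, collapse = " "), "]\n", sep = "")
  invisible(x)
}

#' Smith-Waterman local alignment of two motif symbol strings
#'
#' Standard local alignment over the token alphabet (a token is a motif
#' id plus strand; two tokens match iff both agree). Scoring: match
#' `+match_score`, mismatch `-mismatch_cost`, gap open and extension
#' cost 0 -- with the defaults a gap is always preferred to a mismatch.
#'
#' @param t1,t2 character vectors of tokens.
#' @param mismatch_cost positive mismatch cost (default 5).
#' @param gap_open,gap_extend gap penalties (default 0).
#' @param match_score positive match reward (default 1).
#' @return list with `score` and `alignment`, a two-column integer
#'   matrix of aligned indices into `t1`/`t2` (0 denotes a gap).
#' @export
sw_align_symbols <- function(t1, t2, mismatch_cost = 5, gap_open = 0,
                             gap_extend = 0, match_score = 1) {
  if (length(t1) == 0L || length(t2) == 0L)
    return(list(score = 0,
                alignment = matrix(integer(), ncol = 2L,
                                   dimnames = list(NULL, c("a", "b")))))
  universe <- unique(c(t1, t2))
  al <- cpp_sw_align(match(t1, universe), match(t2, universe),
                     match_score, -mismatch_cost, -max(gap_open, gap_extend))
  list(score = al$score,
       alignment = cbind(a = al$a_idx, b = al$b_idx))
}

sw_score_symbols <- function(t1, t2, mismatch_cost = 5, match_score = 1) {
  if (length(t1) == 0L || length(t2) == 0L) return(0)
  universe <- unique(c(t1, t2))
  cpp_sw_score(match(t1, universe), match(t2, universe),
               match_score, -mismatch_cost, 0)
}

#' Candidate groups sharing motifs with a seed group
#'
#' All groups on *other* promoters sharing at least `min_shared`
#' distinct motif ids with the seed, ordered by shared-motif count
#' descending, ties by group id.
#'
#' @param seed a `promoter_group`.
#' @param groups list of `promoter_group` objects (may include the
#'   seed).
#' @param min_shared minimum number of shared distinct motif ids
#'   (default 3).
#' @return ordered list of candidate groups.
#' @export
find_candidates <- function(seed, groups, min_shared = 3) {
  seed_motifs <- unique(seed$occ$motif)
  shared <- vapply(groups, function(g) {
    if (g$promoter == seed$promoter) return(-1L)
    length(intersect(seed_motifs, unique(g$occ$motif)))
  }, integer(1L))
  ids <- vapply(groups, `[[`, character(1L), "id")
  keep <- which(shared >= min_shared)
  keep <- keep[order(-shared[keep], ids[keep])]
  groups[keep]
}

# sum-of-pairs score of an alignment token matrix (NA = gap)
sum_of_pairs <- function(tok, mismatch_cost = 5, match_score = 1) {
  if (is.null(dim(tok)) || nrow(tok) < 2L || ncol(tok) == 0L) return(0)
  total <- 0
  for (j in seq_len(ncol(tok))) {
    col <- tok[, j]
    col <- col[!is.na(col)]
    if (length(col) < 2L) next
    tab <- tabulate(match(col, unique(col)))
    n <- sum(tab)
    same <- sum(tab * (tab - 1L) / 2L)
    total <- total + match_score * same -
      mismatch_cost * (n * (n - 1L) / 2L - same)
  }
  total
}

#' Center-star multiple alignment of promoter groups
#'
#' Picks as center the group maximising the sum of pairwise
#' Smith-Waterman scores against all others, aligns every other group
#' to the center pairwise, and merges the pairwise alignments under the
#' "once a gap, always a gap" rule: unaligned flanks and insertions
#' relative to the center open gap columns shared by all rows. `AL` is
#' the sum-of-pairs score of the final alignment under the
#' Smith-Waterman scoring.
#'
#' @param groups list of at least 2 `promoter_group` objects.
#' @param mismatch_cost,match_score alignment scoring (defaults 5, 1).
#' @param scores optional precomputed pairwise score matrix (as produced
#'   by the same scoring); used by the greedy assembler to avoid
#'   recomputing alignments while candidates accumulate.
#' @return object of class `cbp_alignment`: `tokens` (groups x columns
#'   character matrix, NA = gap), `occ_idx` (parallel matrix of indices
#'   into each group's `occ`), `groups`, `center` (index), `AL`, and
#'   `degenerate` (TRUE when every pairwise score was 0).
#' @export
center_star_align <- function(groups, mismatch_cost = 5, match_score = 1,
                              scores = NULL) {
  k <- length(groups)
  if (k < 2L) stop("center-star alignment needs at least 2 groups")
  toks <- lapply(groups, `[[`, "tokens")
  if (is.null(scores)) {
    scores <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        s <- sw_score_symbols(toks[[i]], toks[[j]], mismatch_cost,
                              match_score)
        scores[i, j] <- s
        scores[j, i] <- s
      }
    }
  }
  center <- which.max(rowSums(scores))
  degenerate <- all(scores == 0)
  ct <- toks[[center]]
  Lc <- length(ct)
  others <- setdiff(seq_len(k), center)
  aligned_at <- list() # per group: center pos -> other occ index (NA gap)
  inserts <- list()    # per group: slot 0..Lc -> other occ indices
  for (g in others) {
    al <- sw_align_symbols(ct, toks[[g]], mismatch_cost, 0, 0, match_score)
    amap <- rep(NA_integer_, Lc)
    ins <- vector("list", Lc + 1L)
    path <- al$alignment
    if (nrow(path)) {
      first_b <- path[path[, "b"] > 0L, "b"]
      last_a <- 0L
      # left flank of the other sequence
      if (length(first_b) && min(first_b) > 1L) {
        pre_slot <- if (any(path[, "a"] > 0L))
          max(0L, min(path[path[, "a"] > 0L, "a"]) - 1L) else 0L
        ins[[pre_slot + 1L]] <- seq_len(min(first_b) - 1L)
        last_a <- pre_slot
      }
      for (r in seq_len(nrow(path))) {
        ai <- path[r, "a"]; bi <- path[r, "b"]
        if (ai > 0L && bi > 0L) {
          amap[ai] <- bi
          last_a <- ai
        } else if (ai > 0L) {
          last_a <- ai
        } else if (bi > 0L) {
          ins[[last_a + 1L]] <- c(ins[[last_a + 1L]], bi)
        }
      }
      # right flank
      bmax <- max(c(0L, path[, "b"]))
      if (bmax < length(toks[[g]]) && bmax > 0L) {
        ins[[last_a + 1L]] <- c(ins[[last_a + 1L]],
                                (bmax + 1L):length(toks[[g]]))
      }
    } else {
      # no local alignment: the whole sequence is one insertion block
      ins[[1L]] <- seq_along(toks[[g]])
    }
    aligned_at[[as.character(g)]] <- amap
    inserts[[as.character(g)]] <- ins
  }
  ins_cap <- vapply(0:Lc, function(slot) {
    max(c(0L, vapply(inserts, function(ins)
      length(ins[[slot + 1L]]), integer(1L))))
  }, integer(1L))
  ncols <- Lc + sum(ins_cap)
  tok_mat <- matrix(NA_character_, nrow = k, ncol = ncols)
  idx_mat <- matrix(NA_integer_, nrow = k, ncol = ncols)
  # column layout: [ins slot 0][center 1][ins slot 1][center 2]...
  col_of_center <- integer(Lc)
  col <- 0L
  ins_cols <- vector("list", Lc + 1L)
  for (slot in 0:Lc) {
    if (ins_cap[slot + 1L] > 0L)
      ins_cols[[slot + 1L]] <- col + seq_len(ins_cap[slot + 1L])
    col <- col + ins_cap[slot + 1L]
    if (slot < Lc) {
      col <- col + 1L
      col_of_center[slot + 1L] <- col
    }
  }
  tok_mat[center, col_of_center] <- ct
  idx_mat[center, col_of_center] <- seq_len(Lc)
  for (g in others) {
    amap <- aligned_at[[as.character(g)]]
    ok <- which(!is.na(amap))
    tok_mat[g, col_of_center[ok]] <- toks[[g]][amap[ok]]
    idx_mat[g, col_of_center[ok]] <- amap[ok]
    ins <- inserts[[as.character(g)]]
    for (slot in 0:Lc) {
      v <- ins[[slot + 1L]]
      if (length(v)) {
        cols <- ins_cols[[slot + 1L]][seq_along(v)]
        tok_mat[g, cols] <- toks[[g]][v]
        idx_mat[g, cols] <- v
      }
    }
  }
  rownames(tok_mat) <- vapply(groups, `[[`, character(1L), "id")
  structure(list(tokens = tok_mat, occ_idx = idx_mat, groups = groups,
                 center = center,
                 AL = sum_of_pairs(tok_mat, mismatch_cost, match_score),
                 degenerate = degenerate,
                 mismatch_cost = mismatch_cost, match_score = match_score),
            class = "cbp_alignment")
}

column_support <- function(tok_mat) {
  vapply(seq_len(ncol(tok_mat)), function(j) {
    col <- tok_mat[, j]
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(0L)
    max(tabulate(match(col, unique(col))))
  }, integer(1L))
}

column_token <- function(tok_mat) {
  vapply(seq_len(ncol(tok_mat)), function(j) {
    col <- tok_mat[, j]
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(NA_character_)
    u <- sort(unique(col))
    u[which.max(tabulate(match(col, u)))]
  }, character(1L))
}

#' Assemble a combinatorial binding pattern from a seed group
#'
#' Greedy CBP construction: candidates sharing at least `min_shared`
#' motifs with the seed are added in similarity order as long as the
#' realigned pattern retains at least `min_shared` distinct shared
#' aligned motifs. After assembly, alignment columns supported by fewer
#' than `min_support` groups are dropped (each retained motif must
#' align in at least `min_support` groups), groups left without any
#' aligned occurrence are removed, and the pattern is emitted only if
#' at least two distinct target genes remain.
#'
#' @param seed a `promoter_group`.
#' @param groups all promoter groups.
#' @param min_shared minimum shared distinct motifs (default 3).
#' @param min_support minimum groups supporting a retained column
#'   (default 3).
#' @return an object of class `cbp`, or `NULL` when support fails.
#' @export
assemble_cbp <- function(seed, groups, min_shared = 3, min_support = 3) {
  cands <- find_candidates(seed, groups, min_shared)
  if (length(cands) == 0L) return(NULL)
  current <- list(seed)
  aln <- NULL
  # incrementally grown pairwise-score cache over current + candidate
  smat <- matrix(0, 1L, 1L)
  for (cand in cands) {
    trial <- c(current, list(cand))
    kt <- length(trial)
    tmat <- rbind(cbind(smat, 0), 0)
    for (i in seq_len(kt - 1L)) {
      s <- sw_score_symbols(trial[[i]]$tokens, cand$tokens)
      tmat[i, kt] <- s
      tmat[kt, i] <- s
    }
    tal <- center_star_align(trial, scores = tmat)
    need <- min(min_support, length(trial))
    sup <- column_support(tal$tokens)
    ctok <- column_token(tal$tokens)
    shared_motifs <- unique(sub("/.*$", "", ctok[sup >= need]))
    if (length(shared_motifs) >= min_shared) {
      current <- trial
      smat <- tmat
      aln <- tal
    }
  }
  if (is.null(aln) || length(current) < 2L) return(NULL)
  sup <- column_support(aln$tokens)
  keep_cols <- which(sup >= min_support)
  if (length(keep_cols) == 0L) return(NULL)
  tok <- aln$tokens[, keep_cols, drop = FALSE]
  idx <- aln$occ_idx[, keep_cols, drop = FALSE]
  # keep only occurrences matching the column's consensus token
  ctok <- column_token(tok)
  for (j in seq_len(ncol(tok))) {
    off <- !is.na(tok[, j]) & tok[, j] != ctok[j]
    tok[off, j] <- NA_character_
    idx[off, j] <- NA_integer_
  }
  keep_rows <- which(rowSums(!is.na(tok)) > 0L)
  if (length(keep_rows) < 2L) return(NULL)
  tok <- tok[keep_rows, , drop = FALSE]
  idx <- idx[keep_rows, , drop = FALSE]
  member_groups <- current[keep_rows]
  proms <- unique(vapply(member_groups, `[[`, character(1L), "promoter"))
  if (length(proms) < 2L) return(NULL)
  cbp <- structure(list(
    id = NA_character_,
    groups = member_groups,
    tokens = tok, occ_idx = idx,
    column_tokens = ctok,
    motifs = sort(unique(sub("/.*$", "", ctok))),
    promoters = sort(proms),
    AL = sum_of_pairs(tok, aln$mismatch_cost, aln$match_score)),
    class = "cbp")
  metrics <- cbp_metrics(cbp)
  cbp[names(metrics)] <- metrics
  class(cbp) <- "cbp"
  cbp
}

#' @export
print.cbp <- function(x, ...) {
  cat("<cbp> ", x$id %||% "?", ": motifs {",
      paste(x$motifs, collapse = ", "), "} across ",
      length(x$promoters), " promoters; GEN = ", x$GEN,
      ", ROB = ", round(x$ROB, 2), ", COV = ", round(x$COV, 1),
      ", AL = ", x$AL, "\n", sep = "")
  invisible(x)
}

#' Topology metrics of a CBP
#'
#' \describe{
#'   \item{GEN}{generality: number of distinct target genes.}
#'   \item{ROB}{robustness: average, over distinct motifs, of the number
#'     of times the motif occurs per member group.}
#'   \item{COV}{coverage: average, over member groups, of the total bp
#'     available for binding (sum of aligned occurrence widths).}
#'   \item{AL}{the multiple alignment sum-of-pairs score.}
#'   \item{D}{per adjacent column pair, the mean bp separation
#'     (next start - previous end) across the groups exhibiting both
#'     occurrences.}
#' }
#'
#' @param cbp a `cbp` object from [assemble_cbp()].
#' @return list with GEN, ROB, COV, AL, D (numeric vector) and
#'   `D_mean`.
#' @export
cbp_metrics <- function(cbp) {
  ng <- length(cbp$groups)
  gen <- length(unique(vapply(cbp$groups, `[[`, character(1L),
                              "promoter")))
  tok <- cbp$tokens
  idx <- cbp$occ_idx
  motif_of <- sub("/.*$", "", tok)
  widths <- matrix(0, nrow = nrow(tok), ncol = ncol(tok))
  starts <- matrix(NA_real_, nrow = nrow(tok), ncol = ncol(tok))
  ends <- matrix(NA_real_, nrow = nrow(tok), ncol = ncol(tok))
  for (g in seq_len(ng)) {
    occ <- cbp$groups[[g]]$occ
    here <- which(!is.na(idx[g, ]))
    widths[g, here] <- occ$end[idx[g, here]] - occ$start[idx[g, here]]
    starts[g, here] <- occ$start[idx[g, here]]
    ends[g, here] <- occ$end[idx[g, here]]
  }
  motifs <- sort(unique(motif_of[!is.na(motif_of)]))
  rob <- mean(vapply(motifs, function(m) {
    sum(motif_of == m, na.rm = TRUE) / ng
  }, numeric(1L)))
  cov <- mean(rowSums(widths))
  D <- if (ncol(tok) >= 2L) {
    vapply(seq_len(ncol(tok) - 1L), function(j) {
      both <- !is.na(starts[, j + 1L]) & !is.na(ends[, j])
      if (!any(both)) return(NA_real_)
      mean(starts[both, j + 1L] - ends[both, j])
    }, numeric(1L))
  } else numeric(0)
  list(GEN = gen, ROB = rob, COV = cov, AL = cbp$AL, D = D,
       D_mean = if (length(D)) mean(D, na.rm = TRUE) else NA_real_)
}

#' Permutation significance of a CBP's generality
#'
#' Null model: motif identities are permuted over all occurrence slots
#' genome-wide, preserving every promoter's occurrence count and
#' positions; this isolates combinatorial co-occurrence from occurrence
#' density. For each permutation the generality of the CBP's motif
#' combination (number of promoters carrying all its motifs within one
#' occurrence group) is recomputed. SIG is the z-score of the observed
#' GEN in that null distribution; a zero null standard deviation is
#' reported as +Inf with a `degenerate` flag.
#'
#' @param cbp a `cbp` object.
#' @param sites the full [site_records()] universe of occurrences.
#' @param n_perm number of permutations (default 100, minimum 2).
#' @param seed RNG seed.
#' @param max_gap group gap used when regrouping (default 1000).
#' @return list with `SIG`, `gen_obs`, `null_mean`, `null_sd`,
#'   `degenerate`.
#' @export
cbp_significance <- function(cbp, sites, n_perm = 100, seed = 1L,
                             max_gap = 1000) {
  if (n_perm < 2L) stop("n_perm must be >= 2")
  set.seed(seed)
  motifs <- cbp$motifs
  gen_count <- function(s) {
    groups <- build_groups(s, max_gap)
    proms <- unique(vapply(
      Filter(function(g) all(motifs %in% unique(g$occ$motif)), groups),
      `[[`, character(1L), "promoter"))
    length(proms)
  }
  null_gen <- vapply(seq_len(n_perm), function(i) {
    s <- sites
    s$motif <- s$motif[sample.int(nrow(s))]
    gen_count(s)
  }, numeric(1L))
  mu <- mean(null_gen)
  sdev <- sd(null_gen)
  degenerate <- sdev == 0
  sig <- if (degenerate) {
    if (cbp$GEN == mu) 0 else Inf * sign(cbp$GEN - mu)
  } else (cbp$GEN - mu) / sdev
  list(SIG = sig, gen_obs = cbp$GEN, null_mean = mu, null_sd = sdev,
       degenerate = degenerate)
}

# batch form of cbp_significance: one set of label permutations shared
# by all patterns (identical null semantics, far fewer regroupings)
cbp_significance_all <- function(cbps, sites, n_perm = 100, seed = 1L,
                                 max_gap = 1000) {
  if (length(cbps) == 0L) return(list())
  set.seed(seed)
  motif_sets <- lapply(cbps, `[[`, "motifs")
  null_gen <- matrix(0, nrow = n_perm, ncol = length(cbps))
  for (i in seq_len(n_perm)) {
    s <- sites
    s$motif <- s$motif[sample.int(nrow(s))]
    groups <- build_groups(s, max_gap)
    gsets <- lapply(groups, function(g) unique(g$occ$motif))
    gprom <- vapply(groups, `[[`, character(1L), "promoter")
    for (ci in seq_along(cbps)) {
      hit <- vapply(gsets, function(ms) all(motif_sets[[ci]] %in% ms),
                    logical(1L))
      null_gen[i, ci] <- length(unique(gprom[hit]))
    }
  }
  lapply(seq_along(cbps), function(ci) {
    mu <- mean(null_gen[, ci])
    sdev <- sd(null_gen[, ci])
    degenerate <- sdev == 0
    gen <- cbps[[ci]]$GEN
    sig <- if (degenerate) {
      if (gen == mu) 0 else Inf * sign(gen - mu)
    } else (gen - mu) / sdev
    list(SIG = sig, gen_obs = gen, null_mean = mu, null_sd = sdev,
         degenerate = degenerate)
  })
}

#' Mine all combinatorial binding patterns from a site track
#'
#' Every promoter group serves once as seed for [assemble_cbp()];
#' duplicate patterns (identical motif set and gene set) are
#' deduplicated keeping the highest AL. Ids are assigned as
#' "c-1", "c-2", ... in order of descending GEN, then AL.
#'
#' @param sites a [site_records()] data.frame.
#' @param max_gap intra-group gap (default 1000).
#' @param min_shared minimum shared motifs (default 3).
#' @param min_support minimum column support (default 3).
#' @return list of `cbp` objects.
#' @export
mine_cbps <- function(sites, max_gap = 1000, min_shared = 3,
                      min_support = 3) {
  groups <- build_groups(sites, max_gap)
  cbps <- list()
  for (seed in groups) {
    cbp <- assemble_cbp(seed, groups, min_shared, min_support)
    if (!is.null(cbp)) cbps[[length(cbps) + 1L]] <- cbp
  }
  if (length(cbps) == 0L) return(cbps)
  key <- vapply(cbps, function(x)
    paste(paste(x$motifs, collapse = ","),
          paste(x$promoters, collapse = ","), sep = "|"), character(1L))
  al <- vapply(cbps, `[[`, numeric(1L), "AL")
  keep <- vapply(split(seq_along(cbps), key), function(ix)
    ix[which.max(al[ix])], integer(1L))
  cbps <- cbps[sort(keep)]
  gen <- vapply(cbps, `[[`, numeric(1L), "GEN")
  al <- vapply(cbps, `[[`, numeric(1L), "AL")
  cbps <- cbps[order(-gen, -al)]
  for (i in seq_along(cbps)) cbps[[i]]$id <- paste0("c-", i)
  cbps
}

#' Extract the significant-motif subset (STFBM)
#'
#' Motifs that participate in at least `min_cbp_count` mined CBPs,
#' with their per-motif CBP counts.
#'
#' @param cbps list of `cbp` objects.
#' @param min_cbp_count minimum CBP membership (default 1).
#' @return list with `motifs` (character) and `counts` (named integer).
#' @export
extract_stfbm <- function(cbps, min_cbp_count = 1) {
  if (length(cbps) == 0L)
    return(list(motifs = character(), counts = integer()))
  all_m <- unlist(lapply(cbps, `[[`, "motifs"), use.names = FALSE)
  counts <- table(all_m)
  counts <- counts[order(names(counts))]
  keep <- counts >= min_cbp_count
  list(motifs = names(counts)[keep],
       counts = setNames(as.integer(counts), names(counts)))
}

#' Write the left-to-right topology of a CBP as a DOT graph
#'
#' One node per motif token; an arrow from token x to token y means y
#' occurs immediately to the right of x in the aligned pattern, with
#' edge weight the fraction of member promoters exhibiting that
#' adjacency.
#'
#' @param cbp a `cbp` object.
#' @param path output DOT file.
#' @return invisibly, `path`.
#' @export
write_cbp_dot <- function(cbp, path) {
  tok <- cbp$tokens
  edges <- list()
  nprom <- length(cbp$promoters)
  if (ncol(tok) >= 2L) {
    for (j in seq_len(ncol(tok) - 1L)) {
      both <- !is.na(tok[, j]) & !is.na(tok[, j + 1L])
      if (!any(both)) next
      proms <- unique(vapply(cbp$groups[which(both)], `[[`,
                             character(1L), "promoter"))
      key <- paste(cbp$column_tokens[j], cbp$column_tokens[j + 1L],
                   sep = " -> ")
      edges[[key]] <- max(edges[[key]] %||% 0, length(proms) / nprom)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("digraph \"%s\" {", cbp$id %||% "cbp"),
               "  rankdir=LR;"), con)
  for (tk in unique(cbp$column_tokens))
    writeLines(sprintf("  \"%s\";", tk), con)
  for (key in names(edges)) {
    pair <- strsplit(key, " -> ", fixed = TRUE)[[1L]]
    writeLines(sprintf("  \"%s\" -> \"%s\" [weight=%.3f, penwidth=%.2f];",
                       pair[1L], pair[2L], edges[[key]],
                       0.5 + 4 * edges[[key]]), con)
  }
  writeLines("}", con)
  invisible(path)
}
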