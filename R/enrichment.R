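#' Scan promoters for motif targets (Berg-von Hippel weights)
#'
#' Scores every window w of every promoter on both strands with the
#' log-ratio-to-consensus weight W(w) = sum_j ln((p[b_j, j] + eps) /
#' (p_max_j + eps)); the consensus window scores 0, every other window
#' scores below. A gene is called a target when its best window reaches
#' the threshold, which is set a fraction `theta` up the score range
#' from the minimum possible window score W_min towards 0:
#' thr = (1 - theta) * W_min.
#'
#' @param pwm a [new_pwm()] object.
#' @param promoters named character vector of promoter sequences (names
#'   are gene ids), or a list of [new_maf_block()] objects (reference
#'   rows are scanned).
#' @param theta fraction of the consensus score range required
#'   (default 0.8); `theta = 1` keeps only perfect consensus windows.
#' @param eps pseudo-probability guarding log(0) (default 0.01).
#' @return list with `genes` (character vector of target gene ids) and
#'   `sites` (a [site_records()] data.frame of the best window per
#'   target gene).
#' @export
scan_targets <- function(pwm, promoters, theta = 0.8, eps = 0.01) {
  if (is.list(promoters) && length(promoters) &&
      inherits(promoters[[1L]], "maf_block")) {
    seqs <- vapply(promoters, function(b)
      gsub("-", "", b$records$text[1L], fixed = TRUE), character(1L))
    names(seqs) <- vapply(promoters, function(b) b$records$seqid[1L],
                          character(1L))
    promoters <- seqs
  }
  m <- pwm_length(pwm)
  W <- log((pwm$matrix + eps) /
             matrix(apply(pwm$matrix, 2L, max) + eps,
                    nrow = 4L, ncol = m, byrow = TRUE))
  w_min <- sum(apply(W, 2L, min))
  thr <- (1 - theta) * w_min
  genes <- character()
  hits <- list()
  for (g in names(promoters)) {
    s <- promoters[[g]]
    L <- nchar(s)
    if (L < m) next
    enc <- match(strsplit(s, "")[[1L]], DNA_BASES)
    best <- list(score = -Inf)
    for (strand in c("+", "-")) {
      Ws <- if (strand == "+") W else W[4:1, m:1, drop = FALSE]
      # score every window: sum over columns of the weight of its base
      sc <- numeric(L - m + 1L)
      ok <- !is.na(enc)
      for (j in seq_len(m)) {
        wj <- Ws[, j][enc[j:(L - m + j)]]
        wj[is.na(wj)] <- min(Ws[, j]) # N treated as worst base
        sc <- sc + wj
      }
      b <- which.max(sc)
      if (sc[b] > best$score)
        best <- list(score = sc[b], start = b - 1L, strand = strand)
    }
    if (best$score >= thr - 1e-12) {
      genes <- c(genes, g)
      hits[[length(hits) + 1L]] <-
        site_records(g, best$start, best$start + m, best$strand, pwm$id,
                     substr(s, best$start + 1L, best$start + m))
    }
  }
  sites <- if (length(hits)) do.call(rbind, hits) else
    site_records(character(), integer(), integer(), character(),
                 character(), character())
  list(genes = genes, sites = sites)
}

#' Annotation set
#'
#' Gene-to-GO-term annotations plus the term parent DAG and the
#' background gene universe.
#'
#' @param gene2term named list: gene id -> character vector of term ids.
#' @param parents named list: term id -> character vector of parent term
#'   ids (missing or empty = root).
#' @param universe background gene ids (default: the annotated genes).
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(gene2term, parents = list(),
                           universe = names(gene2term)) {
  if (!all(names(gene2term) %in% universe))
    stop("every annotated gene must be in the universe")
  structure(list(gene2term = gene2term, parents = parents,
                 universe = universe),
            class = "annotation_set")
}

#' Read a gene-to-term annotation table
#'
#' Two tab-separated columns: gene id, term id (one pair per line).
#'
#' @param path annotation TSV.
#' @param universe optional background universe (default: genes seen).
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, universe = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("gene", "term"),
                   colClasses = "character")
  g2t <- split(df$term, df$gene)
  annotation_set(lapply(g2t, unique), universe = universe %||% names(g2t))
}

#' Propagate annotations up the ontology DAG
#'
#' Replaces each gene's term set by its ancestor closure (the term
#' itself plus all terms reachable through parent links). Idempotent;
#' raises an error on a cyclic parent graph.
#'
#' @param ann an [annotation_set()].
#' @return the propagated [annotation_set()].
#' @export
propagate_annotations <- function(ann) {
  closure <- new.env(parent = emptyenv())
  anc <- function(term, active = character()) {
    if (term %in% active)
      stop("cycle detected in ontology DAG at term ", term)
    hit <- get0(term, envir = closure)
    if (!is.null(hit)) return(hit)
    ps <- ann$parents[[term]]
    out <- term
    for (p in ps) out <- union(out, anc(p, c(active, term)))
    assign(term, out, envir = closure)
    out
  }
  g2t <- lapply(ann$gene2term, function(terms) {
    sort(unique(unlist(lapply(terms, anc), use.names = FALSE)))
  })
  annotation_set(g2t, ann$parents, ann$universe)
}

#' Hypergeometric GO-term enrichment with BH correction
#'
#' For every term annotated in at least one target gene, tests
#' over-representation of the term among the targets against the
#' background universe with the upper-tail hypergeometric probability
#' P(X >= k), k ~ Hypergeom(K annotated in universe, N universe size,
#' n targets); q-values are Benjamini-Hochberg across all tested terms.
#'
#' @param targets character vector of target gene ids (subset of the
#'   universe).
#' @param ann an [annotation_set()] (propagate first if desired).
#' @return data.frame with columns term, k, K, n, N, p, q, sorted by p.
#' @export
hypergeom_enrich <- function(targets, ann) {
  if (length(ann$universe) == 0L) stop("empty gene universe")
  if (!all(targets %in% ann$universe))
    stop("target genes outside the universe: ",
         paste(head(setdiff(targets, ann$universe)), collapse = ", "))
  N <- length(ann$universe)
  n <- length(targets)
  g2t <- ann$gene2term[intersect(names(ann$gene2term), ann$universe)]
  term_genes <- split(rep(names(g2t), lengths(g2t)),
                      unlist(g2t, use.names = FALSE))
  terms <- names(term_genes)
  rows <- lapply(terms, function(t) {
    genes <- unique(term_genes[[t]])
    k <- length(intersect(genes, targets))
    if (k < 1L) return(NULL)
    K <- length(genes)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, K = K, n = n, N = N, p = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L)
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  df <- do.call(rbind, rows)
  df$q <- p.adjust(df$p, method = "BH")
  df <- df[order(df$p, df$term), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Jaccard ontology distance between two term sets
#'
#' d = 1 - |O1 intersect O2| / |O1 union O2|; 0 for identical nonempty
#' sets, 1 for disjoint sets. Two empty sets are maximally distant
#' (d = 1) with a warning.
#'
#' @param o1,o2 character vectors of term ids.
#' @return numeric in \[0, 1\].
#' @export
ontology_distance <- function(o1, o2) {
  o1 <- unique(o1); o2 <- unique(o2)
  u <- length(union(o1, o2))
  if (u == 0L) {
    warning("both term sets empty; distance defined as 1")
    return(1)
  }
  1 - length(intersect(o1, o2)) / u
}

#' Ontology-map neighbour graph
#'
#' Links each object (a motif or CBP, represented by its significant
#' term set) to its `top_n` nearest neighbours under the Jaccard
#' ontology distance, and to its own GO terms whose BH-adjusted
#' enrichment q-value is below `alpha`.
#'
#' @param term_sets named list: object id -> character vector of term
#'   ids.
#' @param enrichments optional named list: object id -> enrichment
#'   data.frame from [hypergeom_enrich()]; supplies the object-term
#'   edges.
#' @param top_n neighbours per object (default 5).
#' @param alpha significance level for object-term edges (default
#'   0.05).
#' @return data.frame of edges: from, to, type ("neighbour" or "term"),
#'   weight (1 - distance, or 1 - q).
#' @export
ontology_map_graph <- function(term_sets, enrichments = NULL, top_n = 5,
                               alpha = 0.05) {
  ids <- names(term_sets)
  edges <- list()
  if (length(ids) >= 2L) {
    dmat <- matrix(0, length(ids), length(ids),
                   dimnames = list(ids, ids))
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i != j)
          dmat[i, j] <- suppressWarnings(
            ontology_distance(term_sets[[i]], term_sets[[j]]))
      }
    }
    for (i in seq_along(ids)) {
      ord <- order(dmat[i, -i], ids[-i])
      nb <- ids[-i][ord][seq_len(min(top_n, length(ids) - 1L))]
      for (b in nb)
        edges[[length(edges) + 1L]] <-
          data.frame(from = ids[i], to = b, type = "neighbour",
                     weight = 1 - dmat[ids[i], b])
    }
  }
  for (id in names(enrichments %||% list())) {
    e <- enrichments[[id]]
    sig <- e[e$q < alpha, , drop = FALSE]
    for (r in seq_len(nrow(sig)))
      edges[[length(edges) + 1L]] <-
        data.frame(from = id, to = sig$term[r], type = "term",
                   weight = 1 - sig$q[r])
  }
  if (length(edges) == 0L)
    return(data.frame(from = character(), to = character(),
                      type = character(), weight = numeric()))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Write an edge list as a DOT graph
#' @param edges edge data.frame from [ontology_map_graph()].
#' @param path output DOT file.
#' @param name graph name.
#' @return invisibly, `path`.
#' @export
write_graph_dot <- function(edges, path, name = "ontology_map") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("graph \"%s\" {", name), con)
  for (r in seq_len(nrow(edges))) {
    style <- if (edges$type[r] == "term") " [style=dashed]" else ""
    writeLines(sprintf("  \"%s\" -- \"%s\"%s;",
                       edges$from[r], edges$to[r], style), con)
  }
  writeLines("}", con)
  invisible(path)
}
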