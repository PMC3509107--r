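#' Generate a random sharp PWM
#'
#' Each column places probability `dominant` on a uniformly chosen base
#' and splits the remainder evenly over the other three -- a simple
#' model of a specific, information-rich binding motif. Uses the
#' current RNG state.
#'
#' @param length motif length in columns.
#' @param dominant probability of the preferred base per column
#'   (default 0.85).
#' @param id identifier.
#' @return a [new_pwm()] object.
#' @export
random_pwm <- function(length, dominant = 0.85, id = "motif") {
  stopifnot(dominant > 0.25, dominant <= 1)
  cols <- vapply(seq_len(length), function(j) {
    v <- rep((1 - dominant) / 3, 4L)
    v[sample.int(4L, 1L)] <- dominant
    v
  }, numeric(4L))
  rownames(cols) <- DNA_BASES
  new_pwm(cols, id = id)
}

#' Configuration for the synthetic promoter-alignment generator
#'
#' Describes a star-phylogeny simulation of multi-species promoter
#' alignments with planted, conserved motif instances and planted
#' combinatorial binding patterns (CBPs). The reference (first) species
#' row of each promoter is drawn uniformly over A,C,G,T except inside
#' planted sites, which are drawn per column from their PWM; every other
#' species is an independently mutated copy of the reference row, with a
#' lower substitution rate inside sites than outside (this is what makes
#' planted sites look phylogenetically conserved).
#'
#' @param n_promoters number of promoters to simulate.
#' @param promoter_length promoter length in bp (default 5000, the span
#'   upstream of the transcription start site that the pipeline targets).
#' @param n_species total species count including the reference
#'   (default 45, mirroring the UCSC multi-species alignment).
#' @param background_rate per-base substitution probability outside
#'   planted sites; scalar or one value per non-reference species.
#' @param site_rate per-base substitution probability inside planted
#'   sites; scalar or per non-reference species. Must be elementwise
#'   strictly below `background_rate`.
#' @param motifs list of [new_pwm()] objects to plant individually.
#' @param sites_per_promoter how many instances of each motif in `motifs`
#'   to plant per promoter (default 1; 0 allowed).
#' @param cbps list of planted CBP specs; each is a list with elements
#'   `motifs` (character ids drawn from `motifs`), `spacings` (bp gaps
#'   between consecutive sites, length = length(motifs) - 1) and
#'   `promoters` (integer indices of target promoters, at least 2).
#' @param seed mandatory integer random seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_promoters,
                              promoter_length = 5000,
                              n_species = 45,
                              background_rate = 0.3,
                              site_rate = 0.02,
                              motifs = list(),
                              sites_per_promoter = 1,
                              cbps = list(),
                              seed) {
  if (missing(seed) || is.null(seed)) stop("a random seed is mandatory")
  if (n_species < 2L) stop("need at least the reference and one species")
  n_other <- n_species - 1L
  background_rate <- rep_len(background_rate, n_other)
  site_rate <- rep_len(site_rate, n_other)
  if (any(site_rate < 0) || any(background_rate > 1) ||
      any(site_rate >= background_rate))
    stop("rates must satisfy 0 <= site_rate < background_rate <= 1")
  ids <- vapply(motifs, function(p) p$id, character(1L))
  if (anyDuplicated(ids)) stop("planted motif ids must be unique")
  for (cb in cbps) {
    if (!all(cb$motifs %in% ids))
      stop("CBP references unknown motif id(s): ",
           paste(setdiff(cb$motifs, ids), collapse = ", "))
    if (length(cb$spacings) != length(cb$motifs) - 1L)
      stop("CBP needs one spacing per consecutive motif pair")
    if (any(cb$spacings < 0)) stop("CBP spacings must be >= 0")
    if (length(unique(cb$promoters)) < 2L)
      stop("each planted CBP must target at least 2 promoters")
  }
  structure(list(n_promoters = as.integer(n_promoters),
                 promoter_length = as.integer(promoter_length),
                 n_species = as.integer(n_species),
                 background_rate = background_rate,
                 site_rate = site_rate,
                 motifs = motifs,
                 sites_per_promoter = as.integer(sites_per_promoter),
                 cbps = cbps,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate multi-species promoter alignments with planted motifs
#'
#' Generates one MAF block per promoter plus a ground-truth table of
#' every planted site and planted CBP. Deterministic given the config
#' seed. Planted sites never overlap; an error is raised if a site
#' cannot be placed.
#'
#' @param config a [simulation_config()].
#' @return list with elements `blocks` (list of [new_maf_block()]),
#'   `truth` (list with `sites`, a [site_records()] data.frame, and
#'   `cbps`, the planted CBP specs with promoter ids resolved), and
#'   `species` (canonical species order, reference first).
#' @export
simulate_promoters <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$promoter_length
  n_other <- config$n_species - 1L
  species <- c("ref", sprintf("sp%02d", seq_len(n_other)))
  promoters <- sprintf("gene%03d", seq_len(config$n_promoters))
  motif_by_id <- setNames(config$motifs,
                          vapply(config$motifs, `[[`, character(1L), "id"))

  # planned placements per promoter: list of (motif, start, len)
  plan <- lapply(seq_len(config$n_promoters), function(i) {
    data.frame(motif = character(), start = integer(), len = integer())
  })
  occupied <- lapply(seq_len(config$n_promoters), function(i) logical(L))

  place <- function(pi, motif_id, start) {
    len <- pwm_length(motif_by_id[[motif_id]])
    if (start < 0 || start + len > L)
      stop("planted site does not fit in promoter ", promoters[pi])
    span <- (start + 1L):(start + len)
    if (any(occupied[[pi]][span]))
      stop("planted sites overlap in promoter ", promoters[pi])
    occupied[[pi]][span] <<- TRUE
    plan[[pi]] <<- rbind(plan[[pi]],
                         data.frame(motif = motif_id, start = start,
                                    len = len))
  }
  rand_place <- function(pi, motif_id) {
    len <- pwm_length(motif_by_id[[motif_id]])
    if (len > L)
      stop("planted site does not fit in promoter ", promoters[pi])
    for (try in 1:200) {
      start <- sample.int(L - len + 1L, 1L) - 1L
      span <- (start + 1L):(start + len)
      if (!any(occupied[[pi]][span])) { place(pi, motif_id, start); return() }
    }
    stop("could not place a site for ", motif_id, " in promoter ",
         promoters[pi], " without overlap")
  }

  truth_cbps <- list()
  for (cb in config$cbps) {
    lens <- vapply(cb$motifs, function(id) pwm_length(motif_by_id[[id]]),
                   integer(1L))
    total <- sum(lens) + sum(cb$spacings)
    if (total > L) stop("planted CBP does not fit in promoter length")
    for (pi in cb$promoters) {
      start <- sample.int(L - total + 1L, 1L) - 1L
      pos <- start
      for (j in seq_along(cb$motifs)) {
        place(pi, cb$motifs[j], pos)
        pos <- pos + lens[j] + if (j < length(cb$motifs)) cb$spacings[j] else 0L
      }
    }
    truth_cbps[[length(truth_cbps) + 1L]] <-
      list(motifs = cb$motifs, promoters = promoters[cb$promoters])
  }
  if (config$sites_per_promoter > 0L) {
    for (pi in seq_len(config$n_promoters)) {
      for (p in config$motifs) {
        for (r in seq_len(config$sites_per_promoter)) rand_place(pi, p$id)
      }
    }
  }

  blocks <- vector("list", config$n_promoters)
  sites_list <- vector("list", config$n_promoters)
  for (pi in seq_len(config$n_promoters)) {
    h <- sample.int(4L, L, replace = TRUE)
    pl <- plan[[pi]]
    in_site <- logical(L)
    if (nrow(pl)) {
      pl <- pl[order(pl$start), , drop = FALSE]
      seqs <- character(nrow(pl))
      for (si in seq_len(nrow(pl))) {
        s <- sample_site(motif_by_id[[pl$motif[si]]])
        seqs[si] <- s
        span <- (pl$start[si] + 1L):(pl$start[si] + pl$len[si])
        h[span] <- match(strsplit(s, "")[[1L]], DNA_BASES)
        in_site[span] <- TRUE
      }
      sites_list[[pi]] <- site_records(promoters[pi], pl$start,
                                       pl$start + pl$len, "+", pl$motif,
                                       seqs)
    }
    rows <- matrix(0L, nrow = config$n_species, ncol = L)
    rows[1L, ] <- h
    for (s in seq_len(n_other)) {
      rates <- ifelse(in_site, config$site_rate[s], config$background_rate[s])
      mut <- runif(L) < rates
      r <- h
      n_mut <- sum(mut)
      if (n_mut) {
        shift <- sample.int(3L, n_mut, replace = TRUE)
        r[mut] <- ((h[mut] - 1L + shift) %% 4L) + 1L
      }
      rows[s + 1L, ] <- r
    }
    texts <- apply(rows, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
    blocks[[pi]] <- new_maf_block(data.frame(
      src = paste0(species, ".", promoters[pi]),
      start = 0L, size = L, strand = "+", srcSize = L,
      text = texts, stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, sites_list[!vapply(sites_list, is.null,
                                             logical(1L))])
  if (is.null(sites))
    sites <- site_records(character(), integer(), integer(),
                          character(), character(), character())
  list(blocks = blocks, truth = list(sites = sites, cbps = truth_cbps),
       species = species)
}
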