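#' Pipeline configuration
#'
#' Validates and completes a nested configuration list (or a YAML file)
#' for [run_pipeline()]. Every stage block mirrors the corresponding
#' function's arguments; unspecified values take the package defaults.
#' A global integer `seed` is mandatory and drives every source of
#' randomness, so identical configurations produce byte-identical run
#' directories.
#'
#' @param config nested list, or path to a YAML file encoding one.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("pipeline config must carry a seed")
  defaults <- list(
    simulate = list(n_promoters = 50, promoter_length = 2000,
                    n_species = 8, background_rate = 0.3,
                    site_rate = 0.02, n_motifs = 5, motif_length = 8,
                    dominant = 0.85, sites_per_promoter = 1,
                    cbps = list()),
    dictionary = list(prefix_k = 5, tolerance = "auto",
                      tolerance_prob = 0.95),
    discovery = list(k_members = 32, tau = "auto", tau_prob = 0.95,
                     min_size = 5, max_seeds = 500, pseudocount = 0.01),
    dds = list(h = 4, t_max = 64, theta = "auto"),
    postprocess = list(max_share = 0.8, merge_r = 0.85),
    validate = list(r_min = 0.85, shuffle_control = TRUE),
    cbp = list(enabled = TRUE, max_gap = 1000, min_shared = 3,
               min_support = 3, n_perm = 100),
    enrichment = list(annotations = NULL, alpha = 0.05, top_n = 5,
                      theta = 0.8))
  for (blk in names(defaults)) {
    user <- config[[blk]] %||% list()
    merged <- defaults[[blk]]
    merged[names(user)] <- user
    config[[blk]] <- merged
  }
  if (!is.null(config$lengths) && any(config$lengths < 4))
    stop("motif lengths below 4 are not supported")
  config$seed <- as.integer(config$seed)
  structure(config, class = c("pipeline_config", "list"))
}

stage_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full motif-discovery pipeline on synthetic data
#'
#' Orchestrates simulate -> dictionary -> discovery -> DDS filter ->
#' post-processing -> validation -> CBP mining (-> enrichment when
#' annotations are supplied), writing every stage's outputs and a
#' checksummed summary into `out_dir`. Deterministic given the config
#' seed.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible
#'   to one).
#' @param out_dir run directory (created if missing).
#' @return invisibly, a list with the key in-memory results: `truth`,
#'   `predictions`, `report`, `cbps`, `stfbm`, `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  summary_rows <- list()
  note <- function(stage, metric, value) {
    mf_log("debug", stage, ": ", metric, " = ", format(value))
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(stage = stage, metric = metric, value = value)
  }

  ## -- simulate ------------------------------------------------------
  sc <- config$simulate
  motifs <- sc$motifs
  if (is.null(motifs)) {
    motifs <- lapply(seq_len(sc$n_motifs), function(i)
      random_pwm(sc$motif_length, sc$dominant, id = sprintf("m%02d", i)))
  }
  sim_cfg <- simulation_config(
    n_promoters = sc$n_promoters, promoter_length = sc$promoter_length,
    n_species = sc$n_species, background_rate = sc$background_rate,
    site_rate = sc$site_rate, motifs = motifs,
    sites_per_promoter = sc$sites_per_promoter, cbps = sc$cbps,
    seed = config$seed)
  mf_log("info", "simulating ", sc$n_promoters, " promoters (",
         sc$n_species, " species, seed ", config$seed, ")")
  sim <- simulate_promoters(sim_cfg)
  write_maf(sim$blocks, file.path(out_dir, "promoters.maf"))
  write_sites_bed(sim$truth$sites, file.path(out_dir, "truth_sites.bed"))
  write_pwm_collection(motifs, file.path(out_dir, "planted_pwms.txt"))
  truth_cbp_df <- if (length(sim$truth$cbps)) {
    do.call(rbind, lapply(sim$truth$cbps, function(cb)
      data.frame(motifs = paste(cb$motifs, collapse = ","),
                 promoters = paste(cb$promoters, collapse = ","))))
  } else data.frame(motifs = character(), promoters = character())
  stage_tsv(truth_cbp_df, file.path(out_dir, "truth_cbps.tsv"))
  note("simulate", "n_promoters", sc$n_promoters)
  note("simulate", "n_planted_sites", nrow(sim$truth$sites))

  lengths <- config$lengths %||%
    sort(unique(vapply(motifs, pwm_length, integer(1L))))

  predictions <- list()
  known_all <- list()
  for (n in lengths) {
    res <- run_length_stage(config, sim, motifs, n, out_dir, note)
    predictions <- c(predictions, res$predictions)
    known_all <- c(known_all, res$known)
  }
  note("postprocess", "n_predictions", length(predictions))
  write_pwm_collection(lapply(predictions, `[[`, "pwm"),
                       file.path(out_dir, "predicted_pwms.txt"))
  ## a prediction's exported binding sites are its member loci with
  ## cross-species support (conserved in the reference plus at least one
  ## other species); unconserved chance occurrences of member words are
  ## not site calls
  pred_sites <- do.call(rbind, lapply(predictions, function(cl) {
    n <- nchar(cl$seqs[1L])
    keep <- cl$loci$conserved_species >= 2L
    lo <- cl$loci[keep, , drop = FALSE]
    site_records(lo$promoter, lo$start, lo$start + n,
                 "+", cl$id, cl$seqs[lo$member])
  })) %||% site_records(character(), integer(), integer(), character(),
                        character(), character())
  write_sites_bed(pred_sites, file.path(out_dir, "predicted_sites.bed"))

  ## -- validation ----------------------------------------------------
  report <- NULL
  if (length(known_all)) {
    report <- validate_predictions(
      predictions, known_all, r_min = config$validate$r_min,
      shuffle_control = config$validate$shuffle_control,
      seed = config$seed + 1000L)
    stage_tsv(report$per_known, file.path(out_dir, "match_report.tsv"))
    note("validate", "success_rate", report$success_rate)
    note("validate", "control_match_rate", report$control_match_rate)
  }

  ## -- CBP mining ----------------------------------------------------
  cbps <- list()
  stfbm <- list(motifs = character(), counts = integer())
  if (isTRUE(config$cbp$enabled) && nrow(pred_sites)) {
    cbps <- mine_cbps(pred_sites, max_gap = config$cbp$max_gap,
                      min_shared = config$cbp$min_shared,
                      min_support = config$cbp$min_support)
    cbp_df <- if (length(cbps)) {
      sigs <- cbp_significance_all(cbps, pred_sites,
                                   n_perm = config$cbp$n_perm,
                                   seed = config$seed + 2000L,
                                   max_gap = config$cbp$max_gap)
      do.call(rbind, lapply(seq_along(cbps), function(i) {
        x <- cbps[[i]]
        write_cbp_dot(x, file.path(out_dir, paste0("cbp_", x$id, ".dot")))
        data.frame(id = x$id,
                   motifs = paste(x$motifs, collapse = ","),
                   genes = paste(x$promoters, collapse = ","),
                   COV = x$COV, GEN = x$GEN, ROB = x$ROB,
                   SIG = sigs[[i]]$SIG, AL = x$AL)
      }))
    } else data.frame(id = character(), motifs = character(),
                      genes = character(), COV = numeric(),
                      GEN = numeric(), ROB = numeric(), SIG = numeric(),
                      AL = numeric())
    stage_tsv(cbp_df, file.path(out_dir, "cbps.tsv"))
    stfbm <- extract_stfbm(cbps)
    stage_tsv(data.frame(motif = names(stfbm$counts),
                         n_cbps = as.integer(stfbm$counts)),
              file.path(out_dir, "stfbm.tsv"))
    note("cbp", "n_cbps", length(cbps))
    note("cbp", "n_stfbm", length(stfbm$motifs))
  }

  ## -- enrichment ----------------------------------------------------
  if (!is.null(config$enrichment$annotations)) {
    ann <- read_annotations(config$enrichment$annotations)
    ann <- propagate_annotations(ann)
    pred_by_id <- setNames(predictions,
                           vapply(predictions, `[[`, character(1L), "id"))
    enr_rows <- list()
    term_sets <- list()
    enrichments <- list()
    for (mid in stfbm$motifs) {
      if (!mid %in% names(pred_by_id)) next
      tg <- scan_targets(pred_by_id[[mid]]$pwm, sim$blocks,
                         theta = config$enrichment$theta)
      targets <- intersect(tg$genes, ann$universe)
      e <- hypergeom_enrich(targets, ann)
      e$motif <- mid
      enr_rows[[length(enr_rows) + 1L]] <- e
      enrichments[[mid]] <- e
      term_sets[[mid]] <- e$term[e$q < config$enrichment$alpha]
    }
    enr <- if (length(enr_rows)) do.call(rbind, enr_rows) else
      data.frame(term = character(), k = integer(), K = integer(),
                 n = integer(), N = integer(), p = numeric(),
                 q = numeric(), motif = character())
    stage_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    if (length(term_sets) >= 1L) {
      edges <- ontology_map_graph(term_sets, enrichments,
                                  top_n = config$enrichment$top_n,
                                  alpha = config$enrichment$alpha)
      write_graph_dot(edges, file.path(out_dir, "ontology_map.dot"))
    }
    note("enrichment", "n_enriched_terms", nrow(enr))
  }

  mf_log("info", "pipeline finished: ", length(predictions),
         " predictions, ", length(cbps), " CBPs -> ", out_dir)
  summary <- do.call(rbind, summary_rows)
  stage_tsv(summary, file.path(out_dir, "summary.tsv"))
  files <- sort(setdiff(list.files(out_dir), "checksums.txt"))
  sums <- tools::md5sum(file.path(out_dir, files))
  writeLines(paste(unname(sums), files, sep = "  "),
             file.path(out_dir, "checksums.txt"))
  invisible(list(truth = sim$truth, predictions = predictions,
                 report = report, cbps = cbps, stfbm = stfbm,
                 summary = summary))
}

# one word-length pass: dictionary filters, clustering, DDS screening
run_length_stage <- function(config, sim, motifs, n, out_dir, note) {
  dc <- config$dictionary
  known_n <- Filter(function(p) pwm_length(p) == n, motifs)
  truth_sites <- sim$truth$sites
  dict_raw <- extract_words(sim$blocks, n)
  site_dict <- extract_site_words(sim$blocks, truth_sites, n)
  note(paste0("dictionary_n", n), "n_words_raw", length(dict_raw))
  if (length(site_dict) == 0L) {
    note(paste0("dictionary_n", n), "n_words_merged", 0)
    return(list(predictions = list(), known = known_n))
  }
  ## learn from the dictionary entries of the known site words: the
  ## word-level aggregation folds chance background occurrences of the
  ## same word into its profile and permutation, so the learning set
  ## must live in the same (aggregated) representation as the queries
  learn_idx <- match(intersect(site_dict$words, dict_raw$words),
                     dict_raw$words)
  learn_dict <- dict_subset(dict_raw, sort(learn_idx))
  k_eff <- min(dc$prefix_k, length(dict_raw$species) - 1L)
  d_prefix <- prefix_filter(dict_raw, learn_dict, k = k_eff)
  tol <- if (identical(dc$tolerance, "auto"))
    calibrate_curve_tolerance(learn_dict, dc$tolerance_prob)
  else dc$tolerance
  d_curve <- conservation_curve_filter(dict_raw, learn_dict, tol)
  dict <- merge_dictionaries(d_prefix, d_curve)
  note(paste0("dictionary_n", n), "n_words_prefix", length(d_prefix))
  note(paste0("dictionary_n", n), "n_words_curve", length(d_curve))
  note(paste0("dictionary_n", n), "n_words_merged", length(dict))
  stage_tsv(data.frame(word = dict$words, a = dict$a, c = dict$c),
            file.path(out_dir, sprintf("dictionary_n%d.tsv", n)))
  if (length(dict) < 3L) return(list(predictions = list(), known = known_n))

  ## learning clusters: the known planted motifs, one cluster per motif,
  ## built from the site words observed in the alignments
  site_by_motif <- split(seq_len(nrow(truth_sites)),
                         truth_sites$motif)
  learn_clusters <- list()
  for (mid in names(site_by_motif)) {
    seqs <- truth_sites$seq[site_by_motif[[mid]]]
    idx <- unique(match(seqs, learn_dict$words))
    idx <- idx[!is.na(idx)]
    if (length(idx) >= 2L)
      learn_clusters[[mid]] <- cluster_from_dict(learn_dict, idx,
                                                 config$discovery$pseudocount,
                                                 id = paste0("known:", mid))
  }
  if (length(learn_clusters) == 0L)
    return(list(predictions = list(), known = known_n))
  learned_curves <- t(vapply(learn_clusters, `[[`, numeric(n), "entropy"))

  tau <- config$discovery$tau
  if (identical(tau, "auto")) {
    if (nrow(learned_curves) >= 2L) {
      d2 <- as.matrix(stats::dist(learned_curves))
      diag(d2) <- Inf
      tau <- as.numeric(quantile(apply(d2, 1L, min),
                                 config$discovery$tau_prob,
                                 names = FALSE))
    } else tau <- 0.1 * sqrt(n)
  }

  k_members <- min(config$discovery$k_members, length(dict) - 1L)
  seeds <- seq_along(dict$words)
  if (!is.null(config$discovery$max_seeds) &&
      length(seeds) > config$discovery$max_seeds) {
    ord <- order(-(dict$c / pmax(dict$a, 1)), dict$words)
    seeds <- sort(ord[seq_len(config$discovery$max_seeds)])
  }
  a_max <- max(dict$a)
  clusters <- lapply(seeds, function(i) {
    cl <- knn_cluster(dict$words[i], dict, k_members,
                      config$discovery$pseudocount)
    cl <- greedy_refine(cl, learned_curves, tau,
                        config$discovery$min_size)
    rank_score(cl, a_max)
  })
  note(paste0("discovery_n", n), "n_clusters", length(clusters))

  ## DDS screening
  bg_rate <- mean(dict_raw$c) / (length(dict_raw$species) *
                                   mean(dict_raw$a))
  bg_rate <- min(max(bg_rate, 1e-6), 1 - 1e-6)
  train_fp <- t(vapply(learn_clusters, compute_fingerprint,
                       numeric(2L * n + 4L), background_rate = bg_rate))
  pred_fp <- t(vapply(clusters, compute_fingerprint,
                      numeric(2L * n + 4L), background_rate = bg_rate))
  db <- rbind(train_fp, pred_fp)
  theta <- config$dds$theta
  if (identical(theta, "auto")) theta <- NULL
  model <- dds_train(train_fp, db, h = config$dds$h,
                     t_max = config$dds$t_max, theta = theta,
                     train_rows = seq_len(nrow(train_fp)))
  accepted <- vapply(seq_along(clusters), function(i) {
    dds_accept(pred_fp[i, ], model,
               exclude_row = nrow(train_fp) + i)$accept
  }, logical(1L))
  clusters <- clusters[accepted]
  note(paste0("dds_n", n), "n_accepted", length(clusters))
  if (length(clusters) == 0L)
    return(list(predictions = list(), known = known_n))

  ## purge redundant, merge correlated, assign final identifiers
  clusters <- purge_similar(clusters, config$postprocess$max_share)
  note(paste0("postprocess_n", n), "n_after_purge", length(clusters))
  clusters <- merge_correlated(clusters, config$postprocess$merge_r)
  clusters <- sort_clusters(clusters)
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- sprintf("b-%d-%d-0", n, i)
    clusters[[i]]$pwm$id <- clusters[[i]]$id
  }
  note(paste0("postprocess_n", n), "n_after_merge", length(clusters))
  cl_df <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(id = cl$id, n_members = length(cl$seqs),
               S = cl$S, P_c = cl$P_c, P_a = cl$P_a, E = cl$E,
               consensus = pwm_consensus(cl$pwm))))
  stage_tsv(cl_df, file.path(out_dir, sprintf("clusters_n%d.tsv", n)))
  list(predictions = clusters, known = known_n)
}
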