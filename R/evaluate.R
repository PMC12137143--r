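#' Bootstrap Cliff's-delta enrichment of a positive pair set
#'
#' Compares embedding similarities of a reference ("positive") pair set
#' against all remaining pairs: each bootstrap draws `pairs_per_sample`
#' positive and background similarities with replacement and computes
#' Cliff's delta; the mean and standard deviation over `n_boot` bootstraps
#' are reported.
#'
#' @param sim symmetric similarity matrix (protein dimnames).
#' @param positive_pairs two-column matrix or data.frame of protein ids.
#' @param n_boot bootstrap resamplings.
#' @param pairs_per_sample pairs drawn per sample per group.
#' @param seed integer seed.
#' @return list with `delta_mean`, `delta_sd`, `n_positive`, `n_background`.
#' @export
pairset_enrichment <- function(sim, positive_pairs, n_boot = 1000,
                               pairs_per_sample = 1000, seed = 1L) {
  stopifnot(is.matrix(sim), nrow(positive_pairs) >= 1)
  prot <- rownames(sim)
  pp <- as.matrix(positive_pairs)[, 1:2, drop = FALSE]
  if (!all(pp %in% prot)) stop("positive pairs contain unknown proteins")
  n <- nrow(sim)
  idx <- setNames(seq_len(n), prot)
  i1 <- idx[pp[, 1]]; i2 <- idx[pp[, 2]]
  pos_lin <- (pmax(i1, i2) - 1L) * n + pmin(i1, i2)  # upper-triangle linear index
  ut <- which(upper.tri(sim))
  pos_vals <- sim[intersect(pos_lin, ut)]
  bg_vals <- sim[setdiff(ut, pos_lin)]
  if (length(pos_vals) == 0L) stop("empty positive set after mapping")
  deltas <- withr::with_seed(derive_seed(seed, 701L), {
    vapply(seq_len(n_boot), function(b) {
      cliffs_delta(sample(pos_vals, pairs_per_sample, replace = TRUE),
                   sample(bg_vals, pairs_per_sample, replace = TRUE))
    }, 1)
  })
  list(delta_mean = mean(deltas), delta_sd = sd(deltas),
       n_positive = length(pos_vals), n_background = length(bg_vals))
}

#' Binomial enrichment of reference complexes for network edges
#'
#' Quality-control statistic: for each reference complex with at least
#' `min_size` members (and, optionally, at least one bait), the observed
#' number of internal network edges is tested against a one-sided binomial
#' null with success probability equal to the overall network density,
#' with BH correction across complexes.
#'
#' @param net an `interaction_network`.
#' @param catalog a `reference_catalog`.
#' @param min_size minimum complex size.
#' @param require_bait require >= 1 bait member.
#' @param fdr significance level on BH-adjusted p-values.
#' @return list with `table` (complex, m, edges, p, q, significant) and
#'   `enriched_fraction`.
#' @export
complex_edge_enrichment <- function(net, catalog, min_size = 3,
                                    require_bait = TRUE, fdr = 0.01) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(catalog, "reference_catalog"))
  if (nrow(net$edges) == 0L) stop("empty network")
  n_nodes <- length(net$nodes)
  density <- nrow(net$edges) / choose(n_nodes, 2)
  ekey <- paste(pmin(net$edges$a, net$edges$b), pmax(net$edges$a, net$edges$b))
  rows <- lapply(names(catalog$sets), function(nm) {
    members <- intersect(catalog$sets[[nm]], net$nodes)
    m <- length(members)
    if (m < min_size) return(NULL)
    if (require_bait && !any(net$is_bait[members])) return(NULL)
    pairs <- combn(sort(members), 2)
    E <- sum(paste(pairs[1, ], pairs[2, ]) %in% ekey)
    data.frame(complex = nm, m = m, edges = E,
               p = pbinom(E - 1, choose(m, 2), density, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    return(list(table = NULL, enriched_fraction = NA_real_))
  tab$q <- bh_adjust(tab$p)
  tab$significant <- tab$q < fdr
  list(table = tab, enriched_fraction = mean(tab$significant))
}

#' Match a protein set against the assemblies of a cell map
#'
#' An assembly matches the target when its Jaccard overlap is at least
#' `jaccard_min` and its BH-adjusted hypergeometric overlap p-value (over
#' the candidate map's protein universe) is below `fdr_max`. The best match
#' is the passing assembly with the highest Jaccard.
#'
#' @param target character vector of proteins.
#' @param candidate_map a `cell_map`.
#' @param jaccard_min minimum Jaccard overlap.
#' @param fdr_max maximum BH-adjusted hypergeometric p.
#' @return list with `matched` (flag) and `best_match` (assembly id or NA).
#' @export
match_assembly <- function(target, candidate_map, jaccard_min = 0.40,
                           fdr_max = 0.001) {
  stopifnot(length(target) >= 1, inherits(candidate_map, "cell_map"))
  universe <- candidate_map$assemblies[[candidate_map$root]]
  target_u <- intersect(target, universe)
  ids <- setdiff(names(candidate_map$assemblies), candidate_map$root)
  if (length(ids) == 0L || length(target_u) == 0L)
    return(list(matched = FALSE, best_match = NA_character_))
  jac <- vapply(ids, function(id)
    jaccard_index(target, candidate_map$assemblies[[id]]), 1)
  p <- vapply(ids, function(id) {
    a <- candidate_map$assemblies[[id]]
    hyper_test(length(intersect(target_u, a)), length(a),
               length(target_u), length(universe))
  }, 1)
  q <- bh_adjust(p)
  pass <- jac >= jaccard_min & q < fdr_max
  if (!any(pass)) return(list(matched = FALSE, best_match = NA_character_))
  list(matched = TRUE, best_match = ids[pass][which.max(jac[pass])])
}

#' Jackknife robustness of cell map assemblies
#'
#' Repeatedly removes a random fraction of proteins, re-runs the full
#' embedding + detection pipeline with identical parameters, and records,
#' for every assembly of the reference map, whether the jackknifed map
#' contains a matching assembly ([match_assembly()]). Robustness is the
#' fraction of successful resamplings containing a match.
#'
#' @param fm_x,fm_y the full feature matrices.
#' @param reference_map the `cell_map` built from the full data.
#' @param config,... pipeline parameters passed to [cellmap_pipeline()].
#' @param n_reps number of jackknife resamplings.
#' @param drop_fraction fraction of proteins removed per resampling.
#' @param seed master seed; per-rep seeds are derived deterministically.
#' @return a `robustness_report`: data.frame (assembly_id, robustness) plus
#'   settings; failed reps are excluded from the denominator with a warning.
#' @export
jackknife_robustness <- function(fm_x, fm_y, reference_map,
                                 config = coembed_config(), n_reps = 300,
                                 drop_fraction = 0.10, seed = 1L, ...) {
  stopifnot(inherits(reference_map, "cell_map"), n_reps >= 1,
            drop_fraction >= 0, drop_fraction < 1)
  ids <- setdiff(names(reference_map$assemblies), reference_map$root)
  hits <- setNames(rep(0L, length(ids)), ids)
  ok <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, r)
    res <- tryCatch({
      common <- intersect(fm_x$protein_ids, fm_y$protein_ids)
      keep <- withr::with_seed(rep_seed, {
        n_drop <- round(drop_fraction * length(common))
        if (n_drop > 0) setdiff(common, sample(common, n_drop)) else common
      })
      cfg <- config; cfg$seed <- rep_seed
      fx <- feature_matrix(fm_x$values[keep, , drop = FALSE], fm_x$modality)
      fy <- feature_matrix(fm_y$values[keep, , drop = FALSE], fm_y$modality)
      suppressMessages(cellmap_pipeline(fx, fy, cfg, seed = rep_seed, ...))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("jackknife rep %d failed: %s", r, conditionMessage(res)))
      next
    }
    ok <- ok + 1L
    for (id in ids) {
      if (match_assembly(reference_map$assemblies[[id]], res$map)$matched)
        hits[id] <- hits[id] + 1L
    }
  }
  if (ok == 0L) stop("all jackknife reps failed")
  structure(list(table = data.frame(assembly_id = ids,
                                    robustness = as.numeric(hits) / ok,
                                    stringsAsFactors = FALSE),
                 n_reps = n_reps, n_ok = ok, drop_fraction = drop_fraction,
                 seed = seed),
            class = "robustness_report")
}

#' Assembly dependence on one modality via feature randomization
#'
#' Replaces the named modality's features with standard-normal vectors
#' (fresh per resampling) and runs the jackknife; assemblies that stay
#' robust depend on the intact modality alone.
#'
#' @param fm_x,fm_y feature matrices.
#' @param reference_map the reference `cell_map`.
#' @param which modality to randomize: "x" or "y".
#' @param config,n_reps,drop_fraction,seed,... as in
#'   [jackknife_robustness()].
#' @return a `robustness_report`.
#' @export
modality_randomization <- function(fm_x, fm_y, reference_map, which = c("x", "y"),
                                   config = coembed_config(), n_reps = 300,
                                   drop_fraction = 0.10, seed = 1L, ...) {
  which <- match.arg(which)
  tgt <- if (which == "x") fm_x else fm_y
  rnd <- withr::with_seed(derive_seed(seed, 809L), {
    m <- matrix(rnorm(length(tgt$protein_ids) * tgt$d),
                nrow = length(tgt$protein_ids),
                dimnames = list(tgt$protein_ids, NULL))
    feature_matrix(m, modality = paste0(tgt$modality, "_randomized"))
  })
  if (which == "x")
    jackknife_robustness(rnd, fm_y, reference_map, config, n_reps,
                         drop_fraction, seed, ...)
  else
    jackknife_robustness(fm_x, rnd, reference_map, config, n_reps,
                         drop_fraction, seed, ...)
}

#' Degree-preserving randomization of a bait-prey network
#'
#' Baseline for enrichment QC: each bait keeps its number of interactions
#' but its prey are reassigned uniformly at random from the node universe.
#'
#' @param net an `interaction_network`.
#' @param seed integer seed.
#' @return a randomized `interaction_network`.
#' @export
randomize_bait_degrees <- function(net, seed = 1L) {
  stopifnot(inherits(net, "interaction_network"))
  baits <- names(net$is_bait)[net$is_bait]
  withr::with_seed(derive_seed(seed, 907L), {
    rows <- lapply(baits, function(b) {
      k <- sum(net$edges$a == b | net$edges$b == b)
      if (k == 0L) return(NULL)
      prey <- sample(setdiff(net$nodes, b), min(k, length(net$nodes) - 1L))
      data.frame(a = b, b = prey, weight = 1, stringsAsFactors = FALSE)
    })
  })
  edges <- do.call(rbind, rows)
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  keep <- !duplicated(paste(lo, hi))
  structure(list(nodes = net$nodes,
                 edges = data.frame(a = lo[keep], b = hi[keep],
                                    weight = 1, stringsAsFactors = FALSE),
                 is_bait = net$is_bait),
            class = "interaction_network")
}
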