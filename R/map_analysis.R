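#' Read a GMT gene-set file as a reference catalog
#'
#' @param path GMT file (component name, description, then members,
#'   tab-separated).
#' @param name catalog name (defaults to the file name).
#' @return a `reference_catalog`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 50))
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  structure(list(name = name, sets = sets), class = "reference_catalog")
}

#' Write a reference catalog as GMT
#' @param catalog a `reference_catalog`.
#' @param path output file.
#' @export
write_gmt <- function(catalog, path) {
  writeLines(vapply(names(catalog$sets), function(nm)
    paste(c(nm, catalog$name, catalog$sets[[nm]]), collapse = "\t"), ""),
    path)
}

#' Annotate assemblies against reference catalogs
#'
#' Hypergeometric overlap tests for every assembly-component pair (universe
#' = proteins in the map), BH-corrected within each catalog; records are
#' kept at Jaccard >= `jaccard_min` and adjusted p < `fdr`. Each assembly
#' is then categorised from its best Jaccard among kept records:
#' `high_overlap` (>= 0.5 in at least one catalog), `substantial_variation`
#' (all < 0.5, at least one >= 0.2) or `novel` (< 0.2 everywhere, or no
#' record).
#'
#' @param map a `cell_map`.
#' @param catalogs list of `reference_catalog` objects.
#' @param jaccard_min minimum Jaccard for a kept record.
#' @param fdr FDR level within catalog.
#' @return list with `records` (assembly, catalog, component, overlap,
#'   jaccard, p, q), `categories` (assembly -> label), `best_components`
#'   (assembly -> union of proteins of the best-matching component per
#'   catalog).
#' @export
annotate_assemblies <- function(map, catalogs, jaccard_min = 0.10, fdr = 0.01) {
  stopifnot(inherits(map, "cell_map"), length(catalogs) >= 1)
  universe <- map$assemblies[[map$root]]
  ids <- setdiff(names(map$assemblies), map$root)
  all_records <- list()
  for (cat in catalogs) {
    if (!any(unlist(cat$sets) %in% universe))
      warning(sprintf("catalog '%s' shares no proteins with the map", cat$name))
    rows <- list()
    for (id in ids) {
      a <- map$assemblies[[id]]
      for (cm in names(cat$sets)) {
        comp <- intersect(cat$sets[[cm]], universe)
        if (length(comp) == 0L) next
        k <- length(intersect(a, comp))
        rows[[length(rows) + 1L]] <- data.frame(
          assembly = id, catalog = cat$name, component = cm,
          overlap = k, jaccard = jaccard_index(a, cat$sets[[cm]]),
          p = hyper_test(k, length(comp), length(a), length(universe)),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) next
    tab <- do.call(rbind, rows)
    tab$q <- bh_adjust(tab$p)
    all_records[[cat$name]] <- tab[tab$jaccard >= jaccard_min & tab$q < fdr, ,
                                   drop = FALSE]
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL

  categories <- setNames(rep("novel", length(ids)), ids)
  best_components <- setNames(vector("list", length(ids)), ids)
  cat_sets <- setNames(lapply(catalogs, `[[`, "sets"),
                       vapply(catalogs, `[[`, "", "name"))
  if (!is.null(records) && nrow(records) > 0) {
    for (id in unique(records$assembly)) {
      rec <- records[records$assembly == id, , drop = FALSE]
      best_j <- max(rec$jaccard)
      categories[id] <- if (best_j >= 0.5) "high_overlap"
        else if (best_j >= 0.2) "substantial_variation" else "novel"
      best <- lapply(unique(rec$catalog), function(cn) {
        rc <- rec[rec$catalog == cn, , drop = FALSE]
        cat_sets[[cn]][[rc$component[which.max(rc$jaccard)]]]
      })
      best_components[[id]] <- sort(unique(unlist(best)))
    }
  }
  list(records = records, categories = categories,
       best_components = best_components)
}

#' Flag a protein as disordered from a per-residue disorder track
#'
#' A protein is called likely disordered when it contains a contiguous run
#' of more than `min_run` residues each with disorder probability above
#' `prob_threshold`.
#'
#' @param track numeric per-residue disorder probabilities.
#' @param prob_threshold per-residue probability cut-off (default 0.5).
#' @param min_run run length that must be exceeded (default 30).
#' @return logical flag.
#' @export
disorder_flag <- function(track, prob_threshold = 0.5, min_run = 30) {
  r <- rle(track > prob_threshold)
  any(r$values & r$lengths > min_run)
}

#' Flag a protein as likely phase-separating
#' @param prob scalar phase-separation probability.
#' @param threshold probability cut-off (default 0.6).
#' @return logical flag.
#' @export
phase_separation_flag <- function(prob, threshold = 0.6) prob > threshold

#' Per-assembly enrichment of boolean protein flags
#'
#' Hypergeometric enrichment (uncorrected, per the condensate-style
#' protocol) of each named flag within each assembly; an assembly is a
#' candidate when significant for at least one flag.
#'
#' @param map a `cell_map`.
#' @param flags named list of character vectors of flagged proteins
#'   (proteins missing from a vector are unflagged).
#' @param p_max significance level.
#' @return list with `table` (assembly, flag, n_flagged, p, significant)
#'   and `candidates` (assembly ids significant for >= 1 flag).
#' @export
flag_enrichment <- function(map, flags, p_max = 0.01) {
  stopifnot(inherits(map, "cell_map"), is.list(flags), length(flags) >= 1)
  universe <- map$assemblies[[map$root]]
  ids <- setdiff(names(map$assemblies), map$root)
  rows <- list()
  for (fn in names(flags)) {
    flagged <- intersect(flags[[fn]], universe)
    for (id in ids) {
      a <- map$assemblies[[id]]
      k <- length(intersect(a, flagged))
      p <- hyper_test(k, length(flagged), length(a), length(universe))
      rows[[length(rows) + 1L]] <- data.frame(
        assembly = id, flag = fn, n_flagged = k, p = p,
        significant = p < p_max, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, candidates = unique(tab$assembly[tab$significant]))
}

#' Multi-localization statistics of a cell map
#'
#' A protein's terminal locations are the assemblies that contain it while
#' none of their children do; its localization count is the number of
#' distinct directed root-to-terminal paths summed over terminals. Proteins
#' with more than one path are multi-localized; assemblies with more than
#' one parent are multi-localized assemblies.
#'
#' @param map a `cell_map`.
#' @return list with `protein_paths` (named integer), `assembly_parents`
#'   (named integer, root = 0), `multi_proteins`, `multi_assemblies`.
#' @export
multilocalization <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  ids <- names(map$assemblies)
  kids <- split(map$edges$child, factor(map$edges$parent, levels = ids))
  parents_n <- table(factor(map$edges$child, levels = ids))
  parents_n[map$root] <- 0L

  # distinct paths from root to each node (DP in topological order)
  g <- igraph::graph_from_data_frame(map$edges[, c("parent", "child")],
                                     vertices = ids)
  topo <- names(igraph::topo_sort(g))
  paths <- setNames(rep(0, length(ids)), ids)
  paths[map$root] <- 1
  for (v in topo) {
    for (ch in kids[[v]] %||% character(0)) paths[ch] <- paths[ch] + paths[v]
  }

  prot <- map$assemblies[[map$root]]
  protein_paths <- setNames(integer(length(prot)), prot)
  for (p in prot) {
    containing <- ids[vapply(map$assemblies, function(m) p %in% m, TRUE)]
    terminal <- containing[vapply(containing, function(id) {
      ch <- kids[[id]] %||% character(0)
      !any(vapply(ch, function(c2) p %in% map$assemblies[[c2]], TRUE))
    }, TRUE)]
    protein_paths[p] <- sum(paths[terminal])
  }
  list(protein_paths = protein_paths,
       assembly_parents = as.integer(parents_n)[match(ids, names(parents_n))] |>
         setNames(ids),
       multi_proteins = names(protein_paths)[protein_paths > 1],
       multi_assemblies = ids[as.integer(parents_n[ids]) > 1])
}

#' Cross-cell-line conservation of assemblies
#'
#' For each assembly, pairwise cosine similarities of member features are
#' computed separately within feature space A and feature space B; the two
#' similarity distributions are compared by a two-sided rank-sum test and
#' summarised by Cliff's delta oriented so positive values mean larger
#' similarities in A (A-specific). Assemblies with delta at or above
#' `delta_threshold` are classified "specific", others "conserved"; a
#' clipped display value floors delta at 0.
#'
#' @param map a `cell_map`.
#' @param features_A,features_B `feature_matrix` objects (e.g. interaction
#'   embeddings from two cell lines).
#' @param delta_threshold classification cut-off.
#' @return data.frame: assembly, n_covered, delta, delta_display, p,
#'   classification (assemblies with < 2 covered proteins in either space
#'   are excluded).
#' @export
conservation <- function(map, features_A, features_B, delta_threshold = 0.5) {
  stopifnot(inherits(map, "cell_map"))
  ids <- setdiff(names(map$assemblies), map$root)
  rows <- list()
  for (id in ids) {
    m <- map$assemblies[[id]]
    ma <- intersect(m, features_A$protein_ids)
    mb <- intersect(m, features_B$protein_ids)
    covered <- intersect(ma, mb)
    if (length(covered) < 2) next
    sa <- cosine_similarity_matrix(features_A$values[covered, , drop = FALSE])
    sb <- cosine_similarity_matrix(features_B$values[covered, , drop = FALSE])
    va <- sa[upper.tri(sa)]; vb <- sb[upper.tri(sb)]
    p <- suppressWarnings(wilcox.test(va, vb)$p.value)
    delta <- cliffs_delta(va, vb)
    rows[[length(rows) + 1L]] <- data.frame(
      assembly = id, n_covered = length(covered), delta = delta,
      delta_display = max(delta, 0), p = p,
      classification = if (delta >= delta_threshold) "specific" else "conserved",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Weighted structure-model confidence score
#'
#' @param iptm,ptm interface and overall predicted template-modelling
#'   scores in \[0, 1\].
#' @return 0.8 * iptm + 0.2 * ptm.
#' @export
model_score <- function(iptm, ptm) 0.8 * iptm + 0.2 * ptm

#' Score predicted structure pairs with a null-calibrated FDR threshold
#'
#' Each pair's score is the median over its models of the weighted
#' confidence [model_score()]. The empirical false-discovery estimate at
#' threshold s is (fraction of null scores >= s) / (fraction of observed
#' scores >= s), capped at 1; the chosen threshold is the smallest observed
#' score with FDR at or below `fdr_target`.
#'
#' @param records data.frame with `pair_id`, `iptm`, `ptm` and optionally
#'   `interface_ok` per model (multiple rows per pair).
#' @param null_records same structure for random non-co-assembly pairs, or
#'   a numeric vector of precomputed null pair scores.
#' @param fdr_target target FDR (default 0.30).
#' @param n_models expected models per pair (fewer triggers a warning and a
#'   median over what is available).
#' @return list with `table` (pair_id, score, n_models, fdr_at_score,
#'   pass, interface_ok), `threshold`, `fdr_curve`.
#' @export
score_structure_pairs <- function(records, null_records, fdr_target = 0.30,
                                  n_models = 5) {
  stopifnot(all(c("pair_id", "iptm", "ptm") %in% names(records)))
  stopifnot(all(records$iptm >= 0 & records$iptm <= 1),
            all(records$ptm >= 0 & records$ptm <= 1))
  agg <- function(df) {
    sc <- model_score(df$iptm, df$ptm)
    top <- which.max(sc)
    data.frame(score = median(sc), n_models = nrow(df),
               interface_ok = if ("interface_ok" %in% names(df))
                 df$interface_ok[top] else NA)
  }
  obs <- do.call(rbind, lapply(split(records, records$pair_id), agg))
  obs <- data.frame(pair_id = rownames(obs), obs, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (any(obs$n_models < n_models))
    warning(sprintf("%d pair(s) have fewer than %d models; median over available",
                    sum(obs$n_models < n_models), n_models))
  null_scores <- if (is.numeric(null_records)) null_records else {
    vapply(split(null_records, null_records$pair_id),
           function(df) median(model_score(df$iptm, df$ptm)), 1)
  }
  if (length(null_scores) == 0L) stop("empty null set")

  cand <- sort(unique(obs$score))
  fdr_at <- vapply(cand, function(s) {
    min(1, mean(null_scores >= s) / mean(obs$score >= s))
  }, 1)
  pass_idx <- which(fdr_at <= fdr_target)
  threshold <- if (length(pass_idx) > 0) cand[min(pass_idx)] else Inf
  obs$fdr_at_score <- fdr_at[match(obs$score, cand)]
  obs$pass <- obs$score >= threshold
  list(table = obs, threshold = threshold,
       fdr_curve = data.frame(score = cand, fdr = fdr_at))
}
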