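#' Pairwise cosine similarities of a multimodal embedding
#'
#' Because embedding rows are unit-norm, cosine similarity equals the dot
#' product of the two rows.
#'
#' @param emb a `multimodal_embedding` (or any matrix with protein rownames).
#' @return symmetric similarity matrix with protein dimnames.
#' @export
pairwise_cosine <- function(emb) {
  z <- if (inherits(emb, "multimodal_embedding")) emb$z else as.matrix(emb)
  if (nrow(z) < 2) stop("need at least 2 proteins")
  cosine_similarity_matrix(z)
}

#' Build nested proximity networks from top similarity fractions
#'
#' For each fraction f, the most similar round(f * P) protein pairs (P =
#' total number of pairs, minimum one edge, banker's rounding, ties broken
#' by lexicographic pair id) define an undirected network. Because every
#' network is a prefix of the same ranking, the edge sets are nested.
#'
#' @param sim symmetric similarity matrix from [pairwise_cosine()].
#' @param fractions ascending fractions in (0, 1\]; defaults to the ten
#'   fractions 0.2\% to 10\%.
#' @return list of igraph graphs (one per fraction, all on the full protein
#'   vertex set), named by fraction.
#' @export
build_threshold_networks <- function(sim,
    fractions = c(0.002, 0.003, 0.004, 0.005, 0.01, 0.02, 0.03, 0.04, 0.05, 0.10)) {
  stopifnot(is.matrix(sim), nrow(sim) >= 2)
  if (any(fractions <= 0 | fractions > 1) || is.unsorted(fractions))
    stop("fractions must be ascending and in (0, 1]")
  prot <- rownames(sim)
  n <- nrow(sim)
  ut <- which(upper.tri(sim), arr.ind = TRUE)
  vals <- sim[upper.tri(sim)]
  pa <- prot[ut[, 1]]; pb <- prot[ut[, 2]]
  lo <- pmin(pa, pb); hi <- pmax(pa, pb)
  ord <- order(-vals, lo, hi)
  P <- length(vals)
  lapply(setNames(fractions, fractions), function(f) {
    k <- max(1L, round(f * P))
    top <- ord[seq_len(k)]
    g <- igraph::graph_from_data_frame(
      data.frame(from = pa[top], to = pb[top], weight = vals[top]),
      directed = FALSE, vertices = prot)
    g
  })
}

#' Pan-resolution community detection with persistence filtering
#'
#' For each proximity network, modularity communities are detected across a
#' log-spaced resolution grid; communities recurring (Jaccard >=
#' `match_jaccard` to a representative) at >= `persistence_k` grid points
#' are kept, represented by the member set observed at the median resolution
#' of their run. Representatives are pooled across networks and deduplicated
#' at Jaccard >= 0.9, keeping the most persistent.
#'
#' @param networks list of igraph graphs (see [build_threshold_networks()]).
#' @param persistence_k minimum number of grid points a community must recur
#'   at.
#' @param max_resolution top of the resolution grid.
#' @param resolution_grid optional explicit grid; default 40 log-spaced
#'   points from 0.01 to `max_resolution`.
#' @param min_size minimum community size.
#' @param match_jaccard Jaccard threshold for matching a community to a
#'   representative across resolutions.
#' @param seed integer seed (detection is seed-deterministic).
#' @return list of assemblies: each a list with `members`, `persistence`,
#'   `source` (data.frame network, resolution).
#' @export
detect_pan_resolution <- function(networks, persistence_k = 10,
                                  max_resolution = 80, resolution_grid = NULL,
                                  min_size = 3, match_jaccard = 0.75,
                                  seed = 1L) {
  stopifnot(length(networks) >= 1)
  grid <- resolution_grid %||% exp(seq(log(0.01), log(max_resolution), length.out = 40))
  if (persistence_k > length(grid))
    stop("persistence_k exceeds the resolution grid length; persistence unreachable")

  pooled <- list()
  withr::with_seed(derive_seed(seed, 601L), {
    for (ni in seq_along(networks)) {
      g <- networks[[ni]]
      reps <- list()  # each: members_by_grid (list), count, sizes
      for (gi in seq_along(grid)) {
        cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                     resolution = grid[gi], n_iterations = 3)
        mem <- igraph::membership(cl)
        comms <- split(names(mem), mem)
        comms <- comms[lengths(comms) >= min_size]
        for (cm in comms) {
          matched <- FALSE
          for (ri in seq_along(reps)) {
            if (jaccard_index(cm, reps[[ri]]$ref) >= match_jaccard) {
              reps[[ri]]$runs[[length(reps[[ri]]$runs) + 1L]] <-
                list(gi = gi, members = cm)
              matched <- TRUE
              break
            }
          }
          if (!matched)
            reps[[length(reps) + 1L]] <- list(ref = cm,
                                              runs = list(list(gi = gi, members = cm)))
        }
      }
      for (r in reps) {
        pers <- length(r$runs)
        if (pers >= persistence_k) {
          med <- r$runs[[ceiling(pers / 2)]]
          pooled[[length(pooled) + 1L]] <- list(
            members = sort(med$members), persistence = pers,
            source = data.frame(network = names(networks)[ni] %||% ni,
                                resolution = grid[med$gi]))
        }
      }
    }
  })
  if (length(pooled) == 0L) return(list())

  # dedupe across networks at Jaccard >= 0.9, keeping the most persistent
  ord <- order(-vapply(pooled, function(a) a$persistence, 1))
  kept <- list()
  for (i in ord) {
    dup <- any(vapply(kept, function(k)
      jaccard_index(pooled[[i]]$members, k$members) >= 0.9, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- pooled[[i]]
  }
  kept
}

#' Assemble detected communities into a containment DAG
#'
#' Adds a root assembly equal to the protein universe; links every assembly
#' to its minimal strictly-larger parents with containment index
#' |child &#8745; parent| / |child| >= `containment_threshold` (transitively
#' implied edges removed); children with Jaccard >= `redundancy_jaccard` to
#' a parent are merged into that parent. Since parents are strictly larger,
#' the result is acyclic by construction.
#'
#' @param assemblies list from [detect_pan_resolution()] (or any list with
#'   `members` / `persistence` elements).
#' @param universe character vector of all proteins.
#' @param containment_threshold minimum containment index for an edge.
#' @param redundancy_jaccard Jaccard threshold at which a child is merged
#'   into its parent.
#' @return a `cell_map`: list with `assemblies` (id -> members), `meta`
#'   (id, n_proteins, persistence), `edges` (parent, child, containment),
#'   `root`, `merged` (ids absorbed by redundancy).
#' @export
build_dag <- function(assemblies, universe, containment_threshold = 0.75,
                      redundancy_jaccard = 0.90) {
  stopifnot(length(assemblies) >= 1, length(universe) >= 1)
  members <- lapply(assemblies, function(a) sort(unique(a$members)))
  pers <- vapply(assemblies, function(a) a$persistence %||% NA_real_, 1)

  # drop duplicates and any assembly equal to the universe (that's the root)
  keys <- vapply(members, paste, "", collapse = "|")
  first <- !duplicated(keys)
  members <- members[first]; pers <- pers[first]
  is_root_dup <- vapply(members, function(m) setequal(m, universe), TRUE)
  members <- members[!is_root_dup]; pers <- pers[!is_root_dup]
  if (length(members) == 0L) stop("no non-root assemblies")

  ids <- sprintf("C%03d", seq_along(members))
  names(members) <- ids
  sizes <- lengths(members)
  ord <- order(-sizes)

  retained <- character(0)
  merged <- character(0)
  parent_of <- list()
  for (i in ord) {
    id <- ids[i]
    cand <- retained[sizes[retained] > sizes[id] &
                       vapply(retained, function(p)
                         containment_index(members[[id]], members[[p]]), 1) >=
                       containment_threshold]
    if (length(cand) > 0) {
      jac <- vapply(cand, function(p) jaccard_index(members[[id]], members[[p]]), 1)
      if (any(jac >= redundancy_jaccard)) {
        merged <- c(merged, id)
        next
      }
      # minimal parents: drop p if some smaller candidate q is contained in p
      minimal <- cand
      for (p in cand) {
        others <- setdiff(cand, p)
        if (any(sizes[others] < sizes[p] &
                vapply(others, function(q)
                  containment_index(members[[q]], members[[p]]), 1) >=
                containment_threshold))
          minimal <- setdiff(minimal, p)
      }
      parent_of[[id]] <- minimal
    } else {
      parent_of[[id]] <- "root"
    }
    retained <- c(retained, id)
  }

  all_assemblies <- c(list(root = sort(unique(universe))), members[retained])
  edges <- do.call(rbind, lapply(retained, function(id) {
    data.frame(parent = parent_of[[id]], child = id,
               containment = vapply(parent_of[[id]], function(p)
                 containment_index(members[[id]],
                                   if (p == "root") universe else members[[p]]), 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  meta <- data.frame(id = names(all_assemblies),
                     n_proteins = lengths(all_assemblies),
                     persistence = c(NA_real_, pers[retained]),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(assemblies = all_assemblies, meta = meta, edges = edges,
                 root = "root", merged = merged),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell_map: %d assemblies (incl. root of %d proteins), %d containment edges\n",
              length(x$assemblies), length(x$assemblies[[x$root]]), nrow(x$edges)))
  invisible(x)
}

# TRUE iff the containment edges form a DAG (always holds by construction;
# asserted in tests)
cell_map_is_dag <- function(map) {
  g <- igraph::graph_from_data_frame(map$edges[, c("parent", "child")])
  igraph::is_dag(g)
}

#' Calibrate physical assembly diameters against protein counts
#'
#' Ordinary least squares of log10 diameter (nm) on log10 protein count
#' using assemblies with literature-documented physical sizes, retaining
#' the quantities needed for prediction intervals.
#'
#' @param pairs data.frame with columns `n_proteins` and `diameter_nm`
#'   (positive; >= 3 rows).
#' @return a `calibration_model`: slope, intercept, n, xbar, Sxx, s_e
#'   (residual standard error), r_squared.
#' @export
fit_size_calibration <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("n_proteins", "diameter_nm") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 calibration points")
  if (any(pairs$n_proteins <= 0 | pairs$diameter_nm <= 0))
    stop("counts and diameters must be positive")
  x <- log10(pairs$n_proteins); y <- log10(pairs$diameter_nm)
  if (var(x) == 0) stop("zero variance in log10 protein count")
  fit <- lm(y ~ x)
  n <- length(x)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 n = n, xbar = mean(x), Sxx = sum((x - mean(x))^2),
                 s_e = sqrt(sse / (n - 2)),
                 r_squared = if (sst > 0) 1 - sse / sst else NA_real_),
            class = "calibration_model")
}

#' Predict assembly diameter with a prediction interval
#'
#' Point estimate 10^(intercept + slope * log10(count)); the (1 - alpha)
#' prediction interval on the log10 scale is
#' yhat +/- t(1 - alpha/2, n - 2) * s_e * sqrt(1 + 1/n + (x - xbar)^2 / Sxx),
#' back-transformed to nanometres.
#'
#' @param model a `calibration_model`.
#' @param protein_count assembly size(s) in proteins (>= 1).
#' @param alpha significance level (default 0.05 for a 95\% PI).
#' @return data.frame with `diameter_nm`, `pi_low_nm`, `pi_high_nm`.
#' @export
predict_diameter <- function(model, protein_count, alpha = 0.05) {
  stopifnot(inherits(model, "calibration_model"), all(protein_count >= 1))
  x <- log10(protein_count)
  yhat <- model$intercept + model$slope * x
  tmult <- qt(1 - alpha / 2, model$n - 2)
  sep <- model$s_e * sqrt(1 + 1 / model$n + (x - model$xbar)^2 / model$Sxx)
  data.frame(diameter_nm = 10^yhat,
             pi_low_nm = 10^(yhat - tmult * sep),
             pi_high_nm = 10^(yhat + tmult * sep))
}
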