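#' Generate a planted hierarchy of protein assemblies
#'
#' Builds a balanced multi-level hierarchy over a synthetic protein universe:
#' a root assembly containing every protein, split recursively according to
#' `branching`, with the childless assemblies ("leaves") partitioning the
#' universe into near-equal sets (sizes differ by at most one). The planted
#' hierarchy is the ground truth against which recovery of the inferred map
#' is measured.
#'
#' @param n_proteins number of proteins in the universe.
#' @param n_levels number of hierarchy levels including the root (>= 1).
#' @param branching integer vector of length `n_levels - 1`; entry `l` is the
#'   number of children under each assembly at level `l - 1`.
#' @param seed integer seed; identical seeds give identical hierarchies.
#' @param overlap fraction of proteins additionally copied into a second,
#'   randomly chosen leaf (and its ancestors), to exercise multi-localized
#'   membership. Default 0: leaves partition the universe.
#' @return an object of class `planted_map`: list with `proteins`,
#'   `assemblies` (id -> character vector), `parent_edges` (data.frame
#'   parent, child), `level` (id -> integer depth, root = 0).
#' @export
generate_planted_hierarchy <- function(n_proteins, n_levels, branching = integer(0),
                                       seed = 1L, overlap = 0) {
  stopifnot(n_proteins >= 1, n_levels >= 1, overlap >= 0, overlap < 1)
  if (length(branching) != n_levels - 1L)
    stop("branching must have length n_levels - 1")
  if (any(branching <= 0)) stop("branching entries must be positive")
  n_leaves <- prod(branching)
  if (n_leaves > n_proteins) stop("branching product exceeds n_proteins")

  proteins <- sprintf("P%05d", seq_len(n_proteins))
  withr::with_seed(seed, {
    ord <- sample(proteins)

    # leaf sizes differ by <= 1
    base <- n_proteins %/% n_leaves
    extra <- n_proteins %% n_leaves
    sizes <- rep(base, n_leaves) + as.integer(seq_len(n_leaves) <= extra)
    leaf_members <- split(ord, rep(seq_len(n_leaves), times = sizes))

    assemblies <- list()
    level <- integer(0)
    parent <- character(0); child <- character(0)

    # ids per level; leaves first, then aggregate upwards
    ids_at <- vector("list", n_levels)
    ids_at[[n_levels]] <- sprintf("A%d_%d", n_levels - 1L, seq_len(n_leaves))
    for (i in seq_len(n_leaves))
      assemblies[[ids_at[[n_levels]][i]]] <- sort(leaf_members[[i]])
    level[ids_at[[n_levels]]] <- n_levels - 1L

    if (n_levels > 1L) {
      for (lv in rev(seq_len(n_levels - 1L))) {     # lv = 1 .. n_levels-1 -> level lv-1
        n_here <- if (lv == 1L) 1L else prod(branching[seq_len(lv - 1L)])
        ids_at[[lv]] <- if (lv == 1L) "A0_1" else sprintf("A%d_%d", lv - 1L, seq_len(n_here))
        kids_per <- branching[lv]
        for (i in seq_len(n_here)) {
          kid_ids <- ids_at[[lv + 1L]][((i - 1L) * kids_per + 1L):(i * kids_per)]
          assemblies[[ids_at[[lv]][i]]] <- sort(unique(unlist(assemblies[kid_ids])))
          level[ids_at[[lv]][i]] <- lv - 1L
          parent <- c(parent, rep(ids_at[[lv]][i], kids_per))
          child <- c(child, kid_ids)
        }
      }
    }

    root <- ids_at[[1L]][1L]
    assemblies[[root]] <- sort(proteins)

    if (overlap > 0 && n_leaves > 1L) {
      n_dup <- round(overlap * n_proteins)
      dups <- sample(proteins, n_dup)
      leaf_ids <- ids_at[[n_levels]]
      leaf_of <- setNames(rep(leaf_ids, times = vapply(assemblies[leaf_ids], length, 1L)),
                          unlist(assemblies[leaf_ids]))
      for (p in dups) {
        home <- leaf_of[[p]]
        target <- sample(setdiff(leaf_ids, home), 1L)
        # add to the second leaf and all its ancestors
        cur <- target
        repeat {
          assemblies[[cur]] <- sort(unique(c(assemblies[[cur]], p)))
          up <- parent[child == cur]
          if (length(up) == 0L) break
          cur <- up[1L]
        }
      }
    }
  })

  structure(list(proteins = proteins,
                 assemblies = assemblies,
                 parent_edges = data.frame(parent = parent, child = child,
                                           stringsAsFactors = FALSE),
                 level = level,
                 root = root),
            class = "planted_map")
}

# childless assemblies of a planted map
planted_leaves <- function(map) {
  setdiff(names(map$assemblies), unique(map$parent_edges$parent))
}

#' @export
print.planted_map <- function(x, ...) {
  cat(sprintf("planted_map: %d proteins, %d assemblies, depth %d\n",
              length(x$proteins), length(x$assemblies), max(x$level) + 1L))
  invisible(x)
}

#' Simulate an AP-MS style interaction network from a planted hierarchy
#'
#' Pairs of proteins sharing a leaf assembly are connected with probability
#' `p_in`; all other pairs with probability `p_out`. A fraction of proteins
#' is flagged as baits, mimicking the bait/prey structure of
#' affinity-purification mass spectrometry networks.
#'
#' @param map a `planted_map`.
#' @param p_in,p_out within-leaf and background edge probabilities
#'   (`p_out < p_in` required, otherwise there is no planted signal).
#' @param bait_fraction fraction of proteins flagged as baits.
#' @param seed integer seed.
#' @return an `interaction_network`: list with `nodes`, `edges`
#'   (data.frame a, b, weight) and `is_bait` (named logical).
#' @export
simulate_apms <- function(map, p_in = 0.8, p_out = 0.01, bait_fraction = 0.3,
                          seed = 1L) {
  stopifnot(inherits(map, "planted_map"))
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("require 0 <= p_out < p_in <= 1")
  prot <- map$proteins
  n <- length(prot)
  leaves <- planted_leaves(map)
  leaf_sets <- map$assemblies[leaves]

  idx <- setNames(seq_len(n), prot)
  same_leaf <- matrix(FALSE, n, n)
  for (s in leaf_sets) {
    ii <- idx[s]
    same_leaf[ii, ii] <- TRUE
  }
  ut <- upper.tri(same_leaf)
  p_pair <- ifelse(same_leaf[ut], p_in, p_out)

  withr::with_seed(derive_seed(seed, 11L), {
    keep <- runif(length(p_pair)) < p_pair
    is_bait <- setNames(rep(FALSE, n), prot)
    is_bait[sample(prot, round(bait_fraction * n))] <- TRUE
  })

  pairs_i <- row(same_leaf)[ut][keep]
  pairs_j <- col(same_leaf)[ut][keep]
  edges <- data.frame(a = prot[pairs_i], b = prot[pairs_j], weight = 1,
                      stringsAsFactors = FALSE)
  structure(list(nodes = prot, edges = edges, is_bait = is_bait),
            class = "interaction_network")
}

#' Simulate image-derived feature vectors with planted hierarchical structure
#'
#' Each assembly receives a Gaussian mean-offset vector whose scale depends
#' on its level; a protein's feature vector is the sum of the offsets of all
#' assemblies containing it plus isotropic Gaussian noise. Proteins in the
#' same leaf therefore share all ancestor offsets and are more similar (in
#' cosine) than proteins that only share higher-level ancestors.
#'
#' @param map a `planted_map`.
#' @param dim feature dimension (>= 2).
#' @param level_shift numeric vector of offset standard deviations, one per
#'   hierarchy level (root first). Default 2 per level.
#' @param noise_sd standard deviation of per-protein noise.
#' @param seed integer seed.
#' @return a `feature_matrix` (see [feature_matrix()]), modality "image".
#' @export
simulate_image_features <- function(map, dim = 256, level_shift = NULL,
                                    noise_sd = 1, seed = 1L) {
  stopifnot(inherits(map, "planted_map"), dim >= 2)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  depth <- max(map$level) + 1L
  level_shift <- level_shift %||% rep(2, depth)
  if (length(level_shift) != depth)
    stop("level_shift must have one entry per hierarchy level")

  n <- length(map$proteins)
  withr::with_seed(derive_seed(seed, 23L), {
    vals <- matrix(if (noise_sd > 0) rnorm(n * dim, sd = noise_sd) else 0, n, dim)
    rownames(vals) <- map$proteins
    for (aid in names(map$assemblies)) {
      off <- rnorm(dim, sd = level_shift[map$level[[aid]] + 1L])
      members <- map$assemblies[[aid]]
      vals[members, ] <- sweep(vals[members, , drop = FALSE], 2, off, "+")
    }
  })
  feature_matrix(vals, modality = "image")
}

#' Simulate SEC-MS elution profiles with planted co-elution
#'
#' Proteins of the same leaf assembly share a Gaussian elution peak (with a
#' small per-replicate jitter of the peak centre); proteins outside any leaf
#' get independent random peaks. Intensities are non-negative Gaussian bumps
#' over the fraction axis plus noise, emulating size-exclusion
#' chromatography profiles of intact complexes.
#'
#' @param map a `planted_map`.
#' @param n_fractions number of chromatography fractions (>= 5).
#' @param n_reps number of replicates (>= 2).
#' @param peak_sd peak width in fractions (> 0).
#' @param noise_sd additive noise level.
#' @param jitter per-replicate peak-centre jitter (fractions).
#' @param seed integer seed.
#' @return a `sec_profiles` object: list with `replicates` (list of
#'   protein-by-fraction matrices), `K`, `proteins`.
#' @export
simulate_sec <- function(map, n_fractions = 40, n_reps = 3, peak_sd = 1.5,
                         noise_sd = 0.05, jitter = 0.5, seed = 1L) {
  stopifnot(inherits(map, "planted_map"), n_fractions >= 5, n_reps >= 2)
  if (peak_sd <= 0) stop("peak_sd must be > 0")
  prot <- map$proteins
  n <- length(prot)
  leaves <- planted_leaves(map)

  withr::with_seed(derive_seed(seed, 37L), {
    centre <- setNames(runif(n, 3, n_fractions - 2), prot)
    for (lf in leaves) {
      members <- map$assemblies[[lf]]
      centre[members] <- runif(1, 3, n_fractions - 2)
    }
    amp <- setNames(exp(rnorm(n, 0, 0.25)), prot)
    reps <- vector("list", n_reps)
    fr <- seq_len(n_fractions)
    for (r in seq_len(n_reps)) {
      jit <- rnorm(n, 0, jitter)
      m <- matrix(0, n, n_fractions, dimnames = list(prot, paste0("frac_", fr)))
      for (i in seq_len(n)) {
        m[i, ] <- amp[i] * exp(-(fr - (centre[i] + jit[i]))^2 / (2 * peak_sd^2))
      }
      if (noise_sd > 0) m <- m + matrix(rnorm(n * n_fractions, 0, noise_sd), n)
      m[m < 0] <- 0
      reps[[r]] <- m
    }
  })
  structure(list(replicates = reps, K = n_fractions, proteins = prot),
            class = "sec_profiles")
}

#' Simulate a patient mutation cohort with planted recurrently mutated assemblies
#'
#' Each gene is mutated independently in each patient at `base_rate`,
#' multiplied by `effect` for genes belonging to any of the `selected`
#' assemblies. Expected per-gene counts are emitted exactly as
#' `n_patients * base_rate` (the background model is an input in the real
#' pipeline, not estimated here).
#'
#' @param map a `planted_map`.
#' @param n_patients cohort size.
#' @param base_rate per-gene per-patient background mutation probability.
#' @param selected character vector of assembly ids under planted selection.
#' @param effect rate multiplier (> 1) for genes in selected assemblies.
#' @param cohorts named numeric vector of cohort proportions (summing to 1).
#' @param seed integer seed.
#' @return a `mutation_cohort`: list with `samples` (data.frame sample,
#'   cohort), `indicator` (gene x patient logical matrix), `expected`
#'   (named numeric), `maf` (MAF-lite data.frame), `allowed_classes`.
#' @export
simulate_mutations <- function(map, n_patients = 200, base_rate = 0.005,
                               selected = character(0), effect = 8,
                               cohorts = c(all = 1), seed = 1L) {
  stopifnot(inherits(map, "planted_map"), effect > 1 || length(selected) == 0L)
  if (!all(selected %in% names(map$assemblies)))
    stop("selected assemblies not in map")
  genes <- map$proteins
  sel_genes <- unique(unlist(map$assemblies[selected]))
  rate <- setNames(rep(base_rate, length(genes)), genes)
  rate[sel_genes] <- base_rate * effect
  if (any(rate > 1)) stop("mutation probability exceeds 1 after effect multiplier")

  withr::with_seed(derive_seed(seed, 53L), {
    patients <- sprintf("S%04d", seq_len(n_patients))
    indicator <- matrix(rbinom(length(genes) * n_patients, 1,
                               rep(rate, times = n_patients)) == 1L,
                        nrow = length(genes),
                        dimnames = list(genes, patients))
    cohort_lab <- sample(rep(names(cohorts),
                             times = diff(round(cumsum(c(0, cohorts)) * n_patients))))
  })
  hit <- which(indicator, arr.ind = TRUE)
  maf <- data.frame(Hugo_Symbol = genes[hit[, 1]],
                    Tumor_Sample_Barcode = patients[hit[, 2]],
                    Variant_Classification = "Missense_Mutation",
                    stringsAsFactors = FALSE)
  maf <- maf[order(maf$Tumor_Sample_Barcode, maf$Hugo_Symbol), , drop = FALSE]
  rownames(maf) <- NULL
  structure(list(samples = data.frame(sample = patients, cohort = cohort_lab,
                                      stringsAsFactors = FALSE),
                 indicator = indicator,
                 expected = setNames(rep(n_patients * base_rate, length(genes)), genes),
                 maf = maf,
                 allowed_classes = maf_nonsilent_classes()),
            class = "mutation_cohort")
}

#' Corrupt the planted leaves into an imperfect reference catalog
#'
#' Produces one reference component per leaf assembly with a fraction of
#' members dropped and a fraction of random outsiders added, for testing
#' annotation and matching statistics at controlled Jaccard overlap.
#'
#' @param map a `planted_map`.
#' @param drop_frac fraction of members removed from each component.
#' @param add_frac outsiders added, as a fraction of the leaf size.
#' @param seed integer seed.
#' @param name catalog name.
#' @return a `reference_catalog`: list with `name` and `sets`
#'   (component -> character vector).
#' @export
corrupt_catalog <- function(map, drop_frac = 0, add_frac = 0, seed = 1L,
                            name = "synthetic") {
  stopifnot(inherits(map, "planted_map"),
            drop_frac >= 0, drop_frac < 1, add_frac >= 0)
  leaves <- planted_leaves(map)
  sets <- list()
  withr::with_seed(derive_seed(seed, 71L), {
    for (lf in leaves) {
      members <- map$assemblies[[lf]]
      n_drop <- round(drop_frac * length(members))
      keep <- if (n_drop > 0) sample(members, length(members) - n_drop) else members
      n_add <- round(add_frac * length(members))
      outsiders <- setdiff(map$proteins, members)
      add <- if (n_add > 0) sample(outsiders, min(n_add, length(outsiders))) else character(0)
      sets[[paste0("ref_", lf)]] <- sort(unique(c(keep, add)))
    }
  })
  structure(list(name = name, sets = sets), class = "reference_catalog")
}

#' Generate a complete synthetic bundle with planted ground truth
#'
#' Convenience constructor tying together the planted hierarchy and all
#' simulated data modalities over one shared protein universe: interaction
#' network, image features, SEC profiles, mutation cohort, and a reference
#' catalog. Regeneration with the same seed reproduces identical content.
#'
#' @param n_proteins,n_levels,branching,seed hierarchy parameters
#'   (see [generate_planted_hierarchy()]).
#' @param n_selected number of leaf assemblies put under planted mutational
#'   selection.
#' @param ... passed through: `p_in`, `p_out`, `dim`, `noise_sd` etc. are
#'   taken from the individual simulators' defaults.
#' @return a `synthetic_bundle` list: `truth`, `network`, `image_features`,
#'   `ppi_features` (NULL until [embed_network()] is run), `sec`,
#'   `mutations`, `catalogs`, `seed`.
#' @export
make_synthetic_bundle <- function(n_proteins = 300, n_levels = 3,
                                  branching = c(4, 5), seed = 1L,
                                  n_selected = 3) {
  truth <- generate_planted_hierarchy(n_proteins, n_levels, branching, seed = seed)
  leaves <- planted_leaves(truth)
  selected <- head(leaves, n_selected)
  structure(list(
    truth = truth,
    network = simulate_apms(truth, seed = seed),
    image_features = simulate_image_features(truth, seed = seed),
    ppi_features = NULL,
    sec = simulate_sec(truth, seed = seed),
    mutations = simulate_mutations(truth, selected = selected, seed = seed),
    catalogs = list(corrupt_catalog(truth, drop_frac = 0.1, add_frac = 0.1,
                                    seed = seed)),
    selected_assemblies = selected,
    seed = seed), class = "synthetic_bundle")
}
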