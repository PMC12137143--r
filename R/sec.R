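#' Replicate-averaged co-elution similarity
#'
#' For every protein pair, computes the Pearson correlation of their
#' elution profiles within each replicate in which both proteins are
#' detected, then averages across those replicates. Analysis is restricted
#' to proteins detected in at least `min_detected` replicates; replicates
#' where either profile has zero variance are skipped for that pair; pairs
#' sharing no usable replicate are NA.
#'
#' @param profiles a `sec_profiles` object.
#' @param min_detected minimum replicates a protein must be detected in.
#' @return list with `sims` (symmetric matrix, unit diagonal where defined)
#'   and `proteins`.
#' @export
coelution_similarity <- function(profiles, min_detected = 2) {
  stopifnot(inherits(profiles, "sec_profiles"))
  reps <- profiles$replicates
  detected <- sapply(reps, function(m) rowSums(m) > 0)
  keep <- profiles$proteins[rowSums(detected) >= min_detected]
  if (length(keep) < 2) stop("fewer than 2 proteins pass the replicate filter")
  n <- length(keep)
  acc <- matrix(0, n, n, dimnames = list(keep, keep))
  cnt <- matrix(0L, n, n)
  for (r in seq_along(reps)) {
    det_r <- keep[detected[keep, r]]
    if (length(det_r) < 2) next
    m <- reps[[r]][det_r, , drop = FALSE]
    ok_var <- apply(m, 1, sd) > 0
    det_r <- det_r[ok_var]
    if (length(det_r) < 2) next
    cc <- cor(t(reps[[r]][det_r, , drop = FALSE]))
    acc[det_r, det_r] <- acc[det_r, det_r] + cc
    cnt[match(det_r, keep), match(det_r, keep)] <-
      cnt[match(det_r, keep), match(det_r, keep)] + 1L
  }
  sims <- acc / cnt
  sims[cnt == 0L] <- NA_real_
  list(sims = sims, proteins = keep)
}

# pairs of proteins (within `proteins`) that share no non-root assembly
.root_only_pairs <- function(map, proteins) {
  ids <- setdiff(names(map$assemblies), map$root)
  n <- length(proteins)
  shared <- matrix(FALSE, n, n, dimnames = list(proteins, proteins))
  for (id in ids) {
    m <- intersect(map$assemblies[[id]], proteins)
    shared[m, m] <- TRUE
  }
  which(upper.tri(shared) & !shared, arr.ind = TRUE)
}

#' Validate assemblies against SEC co-elution
#'
#' For each assembly, the within-assembly pairwise co-elution similarities
#' are compared against a null of similarities between proteins that share
#' no assembly below the root, using a one-sided (greater) Wilcoxon
#' rank-sum test with BH correction across assemblies. Assemblies with
#' adjusted p below `fdr` are flagged validated; assemblies with fewer than
#' two covered proteins are untestable and excluded from the BH family.
#'
#' @param map a `cell_map`.
#' @param coelution result of [coelution_similarity()] (or a compatible
#'   list with `sims` and `proteins`).
#' @param fdr FDR level for validation.
#' @param null_cap maximum null pairs retained (subsampled with `seed`).
#' @param seed integer seed for null subsampling.
#' @return data.frame per assembly: `assembly_id`, `n_pairs`, `median_r`,
#'   `p`, `q`, `validated`, `testable`.
#' @export
validate_assemblies <- function(map, coelution, fdr = 0.05, null_cap = 1e6,
                                seed = 1L) {
  stopifnot(inherits(map, "cell_map"))
  sims <- coelution$sims
  proteins <- intersect(coelution$proteins, map$assemblies[[map$root]])
  if (length(proteins) < 2) stop("map and similarity table share too few proteins")
  sims <- sims[proteins, proteins, drop = FALSE]

  np <- .root_only_pairs(map, proteins)
  null_vals <- sims[np]
  null_vals <- null_vals[is.finite(null_vals)]
  if (length(null_vals) == 0L) stop("no null (root-only) pairs with SEC coverage")
  if (length(null_vals) > null_cap) {
    null_vals <- withr::with_seed(derive_seed(seed, 1009L),
                                  sample(null_vals, null_cap))
  }

  ids <- setdiff(names(map$assemblies), map$root)
  rows <- lapply(ids, function(id) {
    m <- intersect(map$assemblies[[id]], proteins)
    if (length(m) < 2)
      return(data.frame(assembly_id = id, n_pairs = 0L, median_r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    v <- sims[m, m][upper.tri(matrix(0, length(m), length(m)))]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      return(data.frame(assembly_id = id, n_pairs = 0L, median_r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    p <- suppressWarnings(
      wilcox.test(v, null_vals, alternative = "greater")$p.value)
    data.frame(assembly_id = id, n_pairs = length(v), median_r = median(v),
               p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$testable <- !is.na(tab$p)
  tab$q <- NA_real_
  tab$q[tab$testable] <- bh_adjust(tab$p[tab$testable])
  tab$validated <- !is.na(tab$q) & tab$q < fdr
  tab
}

#' Validate unexpected assembly members by co-elution
#'
#' For each assembly smaller than `max_assembly_size`, members absent from
#' the assembly's best-matching reference component(s) are "unexpected";
#' each such protein's similarities to the remaining members are tested
#' against the root-only null as in [validate_assemblies()], with BH
#' correction across all unexpected proteins.
#'
#' @param map a `cell_map`.
#' @param coelution result of [coelution_similarity()].
#' @param best_components named list: assembly id -> proteins of its
#'   best-matching reference component(s) (see [annotate_assemblies()]).
#' @param max_assembly_size assemblies at or above this size are skipped.
#' @param fdr FDR level.
#' @param null_cap,seed null subsampling (as in [validate_assemblies()]).
#' @return data.frame per unexpected protein: `assembly_id`, `protein`,
#'   `n_pairs`, `median_r`, `p`, `q`, `validated` (empty if none).
#' @export
validate_unexpected_members <- function(map, coelution, best_components,
                                        max_assembly_size = 50, fdr = 0.05,
                                        null_cap = 1e6, seed = 1L) {
  stopifnot(inherits(map, "cell_map"))
  sims <- coelution$sims
  proteins <- intersect(coelution$proteins, map$assemblies[[map$root]])
  sims <- sims[proteins, proteins, drop = FALSE]
  np <- .root_only_pairs(map, proteins)
  null_vals <- sims[np]
  null_vals <- null_vals[is.finite(null_vals)]
  if (length(null_vals) > null_cap)
    null_vals <- withr::with_seed(derive_seed(seed, 1013L),
                                  sample(null_vals, null_cap))

  ids <- setdiff(names(map$assemblies), map$root)
  rows <- list()
  for (id in ids) {
    members <- map$assemblies[[id]]
    if (length(members) >= max_assembly_size) next
    expected <- best_components[[id]] %||% character(0)
    unexpected <- setdiff(members, expected)
    for (pr in unexpected) {
      if (!pr %in% proteins) next
      others <- intersect(setdiff(members, pr), proteins)
      if (length(others) == 0L) next
      v <- sims[pr, others]
      v <- v[is.finite(v)]
      if (length(v) == 0L) next
      p <- suppressWarnings(
        wilcox.test(v, null_vals, alternative = "greater")$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        assembly_id = id, protein = pr, n_pairs = length(v),
        median_r = median(v), p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(assembly_id = character(0), protein = character(0),
                      n_pairs = integer(0), median_r = numeric(0),
                      p = numeric(0), q = numeric(0), validated = logical(0)))
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  tab$validated <- tab$q < fdr
  tab
}
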