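#' Non-silent variant classification whitelist
#'
#' The somatic variant classes counted as non-silent mutation events.
#'
#' @return character vector of MAF `Variant_Classification` values.
#' @export
maf_nonsilent_classes <- function() {
  c("Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "RNA",
    "Splice_Region", "Splice_Site", "Translation_Start_Site")
}

#' Read a MAF-lite mutation table into a cohort object
#'
#' Keeps rows whose `Variant_Classification` is in the whitelist and builds
#' a boolean gene-by-sample indicator (>= 1 non-silent event).
#'
#' @param path MAF-lite TSV with columns `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification`.
#' @param allowed_classes whitelist (default [maf_nonsilent_classes()]).
#' @param expected optional named numeric of expected per-gene counts for
#'   the pan cohort (genes missing from it are treated as 0 with a warning
#'   at use time).
#' @param cohort_table optional data.frame (sample, cohort); default one
#'   cohort "all".
#' @return a `mutation_cohort`.
#' @export
read_maf_lite <- function(path, allowed_classes = maf_nonsilent_classes(),
                          expected = NULL, cohort_table = NULL) {
  maf <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  if (!all(need %in% names(maf)))
    stop("MAF-lite requires columns: ", paste(need, collapse = ", "))
  n_drop <- sum(!maf$Variant_Classification %in% allowed_classes)
  if (n_drop > 0)
    message(sprintf("dropped %d row(s) with disallowed variant classes", n_drop))
  maf <- maf[maf$Variant_Classification %in% allowed_classes, , drop = FALSE]
  samples <- sort(unique(c(maf$Tumor_Sample_Barcode,
                           cohort_table$sample %||% character(0))))
  genes <- sort(unique(maf$Hugo_Symbol))
  indicator <- matrix(FALSE, length(genes), length(samples),
                      dimnames = list(genes, samples))
  indicator[cbind(match(maf$Hugo_Symbol, genes),
                  match(maf$Tumor_Sample_Barcode, samples))] <- TRUE
  if (is.null(cohort_table))
    cohort_table <- data.frame(sample = samples, cohort = "all",
                               stringsAsFactors = FALSE)
  structure(list(samples = cohort_table, indicator = indicator,
                 expected = expected, maf = maf,
                 allowed_classes = allowed_classes),
            class = "mutation_cohort")
}

#' Corrected per-gene mutation load
#'
#' \eqn{M_g = \log_2(\max(N_{g,obs} - N_{g,exp}, 0) + 1)} where the
#' observed count is the number of patients in the target cohort carrying
#' a non-silent mutation in g, and the expected count is the pan-cohort
#' expectation scaled by the cohort's patient proportion when a single
#' cohort is targeted.
#'
#' @param cohort a `mutation_cohort`.
#' @param target_cohort cohort label, or "pan" for the full cohort.
#' @param genes optional gene universe (defaults to genes in the
#'   indicator); genes without expected counts get expectation 0 with a
#'   warning.
#' @return named numeric vector of M values.
#' @export
corrected_load <- function(cohort, target_cohort = "pan", genes = NULL) {
  stopifnot(inherits(cohort, "mutation_cohort"))
  genes <- genes %||% rownames(cohort$indicator)
  if (target_cohort == "pan") {
    samp <- cohort$samples$sample
    scale <- 1
  } else {
    samp <- cohort$samples$sample[cohort$samples$cohort == target_cohort]
    if (length(samp) == 0L) stop("empty cohort: ", target_cohort)
    scale <- length(samp) / nrow(cohort$samples)
  }
  ind <- cohort$indicator[, intersect(samp, colnames(cohort$indicator)),
                          drop = FALSE]
  n_obs <- setNames(rep(0, length(genes)), genes)
  present <- intersect(genes, rownames(ind))
  n_obs[present] <- rowSums(ind[present, , drop = FALSE])
  n_exp <- setNames(rep(0, length(genes)), genes)
  if (!is.null(cohort$expected)) {
    known <- intersect(genes, names(cohort$expected))
    if (length(known) < length(genes))
      warning(sprintf("%d gene(s) without expected counts treated as 0",
                      length(genes) - length(known)))
    n_exp[known] <- cohort$expected[known] * scale
  } else {
    warning("no expected counts; using 0 for all genes")
  }
  log2(pmax(n_obs - n_exp, 0) + 1)
}

# largest lambda in `lambda_grid` (descending) at which each column of x
# has a non-zero lasso coefficient; 0 if never selected
.first_entry_lambda <- function(x, y, lambda_grid) {
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lambda_grid, standardize = FALSE,
                        intercept = FALSE)
  beta <- fit$beta  # p x n_lambda sparse
  score <- numeric(ncol(x))
  # near-zero coefficients at the boundary penalty are numerical noise
  nz <- Matrix::which(abs(beta) > 1e-7, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    first <- tapply(nz[, 2], nz[, 1], min)
    score[as.integer(names(first))] <- fit$lambda[first]
  }
  score
}

#' Lasso selection-pressure scores for assemblies with permutation p-values
#'
#' Regresses the corrected mutation load M on a sparse design with one
#' indicator column per assembly plus one singleton column per gene (so
#' single-gene signal is not credited to assemblies), solved along a
#' descending lasso path. An assembly's selection score is the largest
#' penalty at which its coefficient becomes non-zero. Empirical p-values
#' compare each assembly's observed score with its scores under
#' permutations of the gene labels of M, followed by BH correction.
#'
#' @param M named numeric vector of per-gene loads ([corrected_load()]).
#' @param map a `cell_map`.
#' @param n_perm number of permutations (>= 100).
#' @param lambda_grid optional descending penalty grid; default 50
#'   log-spaced values from the observed first-entry penalty down to 1e-3
#'   of it.
#' @param seed integer seed.
#' @param fdr_max selection threshold on BH-adjusted p.
#' @param pooled compare against the pooled permuted score distribution
#'   instead of per-assembly.
#' @return a `selection_result`: data.frame (assembly, score, p, q,
#'   selected) plus settings.
#' @export
selection_pressure <- function(M, map, n_perm = 10000, lambda_grid = NULL,
                               seed = 1L, fdr_max = 0.4, pooled = FALSE) {
  stopifnot(inherits(map, "cell_map"))
  if (n_perm < 100) stop("permutation budget below 100 is refused")
  ids <- setdiff(names(map$assemblies), map$root)
  ids <- ids[lengths(map$assemblies[ids]) >= 2]
  if (length(ids) == 0L) stop("no assemblies with >= 2 proteins")
  genes <- names(M)
  gi <- setNames(seq_along(genes), genes)

  ii <- integer(0); jj <- integer(0)
  for (k in seq_along(ids)) {
    m <- intersect(map$assemblies[[ids[k]]], genes)
    ii <- c(ii, gi[m]); jj <- c(jj, rep(k, length(m)))
  }
  n_a <- length(ids)
  x <- Matrix::sparseMatrix(
    i = c(ii, seq_along(genes)),
    j = c(jj, n_a + seq_along(genes)),
    x = 1, dims = c(length(genes), n_a + length(genes)))

  if (all(M == 0)) {
    tab <- data.frame(assembly = ids, score = 0, p = 1, q = 1,
                      selected = FALSE, stringsAsFactors = FALSE)
    return(structure(list(table = tab, n_perm = n_perm, seed = seed,
                          lambda_grid = lambda_grid),
                     class = "selection_result"))
  }

  if (is.null(lambda_grid)) {
    lam_max <- max(abs(Matrix::crossprod(x, M))) / length(genes)
    lambda_grid <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = 50))
  }

  obs <- .first_entry_lambda(x, M, lambda_grid)[seq_len(n_a)]
  perm_ge <- numeric(n_a)
  pooled_scores <- numeric(0)
  withr::with_seed(derive_seed(seed, 1103L), {
    for (b in seq_len(n_perm)) {
      sc <- .first_entry_lambda(x, sample(M), lambda_grid)[seq_len(n_a)]
      if (pooled) pooled_scores <- c(pooled_scores, sc)
      else perm_ge <- perm_ge + (sc >= obs)
    }
  })
  p <- if (pooled) {
    vapply(obs, function(o) (1 + sum(pooled_scores >= o)) /
             (length(pooled_scores) + 1), 1)
  } else {
    (1 + perm_ge) / (n_perm + 1)
  }
  q <- bh_adjust(p)
  tab <- data.frame(assembly = ids, score = obs, p = p, q = q,
                    selected = q <= fdr_max, stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 lambda_grid = lambda_grid, fdr_max = fdr_max),
            class = "selection_result")
}

#' Assembly-level mutation frequencies per cohort
#'
#' Frequency = distinct patients in the cohort carrying >= 1 mutated
#' assembly member / cohort size. Cohorts smaller than `min_cohort_size`
#' are excluded, as are assemblies with more than `max_mutated_proteins`
#' mutated members.
#'
#' @param cohort a `mutation_cohort`.
#' @param map a `cell_map`.
#' @param min_cohort_size minimum patients per cohort.
#' @param max_mutated_proteins cap on mutated members per assembly.
#' @return data.frame: assembly, cohort, n_patients, n_mutated_patients,
#'   frequency.
#' @export
assembly_mutation_frequency <- function(cohort, map, min_cohort_size = 15,
                                        max_mutated_proteins = 50) {
  stopifnot(inherits(cohort, "mutation_cohort"), inherits(map, "cell_map"))
  ind <- cohort$indicator
  ids <- setdiff(names(map$assemblies), map$root)
  cohorts <- split(cohort$samples$sample, cohort$samples$cohort)
  cohorts <- cohorts[lengths(cohorts) >= min_cohort_size]
  rows <- list()
  for (id in ids) {
    members <- intersect(map$assemblies[[id]], rownames(ind))
    if (length(members) == 0L) next
    mut_members <- members[rowSums(ind[members, , drop = FALSE]) > 0]
    if (length(mut_members) > max_mutated_proteins) next
    for (cn in names(cohorts)) {
      samp <- intersect(cohorts[[cn]], colnames(ind))
      hit <- colSums(ind[members, samp, drop = FALSE]) > 0
      rows[[length(rows) + 1L]] <- data.frame(
        assembly = id, cohort = cn, n_patients = length(samp),
        n_mutated_patients = sum(hit),
        frequency = sum(hit) / length(samp), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(assembly = character(0), cohort = character(0),
                      n_patients = integer(0), n_mutated_patients = integer(0),
                      frequency = numeric(0)))
  do.call(rbind, rows)
}

#' Putative driver proteins from selected assemblies
#'
#' Proteins belonging to a selected (recurrently mutated) assembly and
#' mutated in at least `min_patients` patients.
#'
#' @param selection a `selection_result`.
#' @param cohort a `mutation_cohort`.
#' @param map the `cell_map` used for selection.
#' @param min_patients minimum patients mutated (default 2, i.e. "more
#'   than one").
#' @return character vector of proteins (deduplicated, sorted).
#' @export
putative_drivers <- function(selection, cohort, map, min_patients = 2) {
  stopifnot(inherits(selection, "selection_result"),
            inherits(cohort, "mutation_cohort"))
  sel_ids <- selection$table$assembly[selection$table$selected]
  if (length(sel_ids) == 0L) return(character(0))
  members <- unique(unlist(map$assemblies[sel_ids]))
  members <- intersect(members, rownames(cohort$indicator))
  counts <- rowSums(cohort$indicator[members, , drop = FALSE])
  sort(names(counts)[counts >= min_patients])
}

#' KDE-area FDR curve for driver validation against screen counts
#'
#' Gaussian kernel densities are fitted to the screen counts of putative
#' drivers (positives) and all other map genes (background). For each
#' integer threshold x, AreaFP and AreaTP are the trapezoidal tail areas
#' (>= x) of the background and positive densities, and
#' FDR(x) = AreaFP / (AreaFP + AreaTP). The chosen threshold is the
#' smallest x with FDR at or below `fdr_target`.
#'
#' @param positive_counts numeric screen counts for putative drivers.
#' @param background_counts screen counts for all other genes.
#' @param thresholds integer candidate thresholds (default 0..max count).
#' @param fdr_target target FDR (default 0.30).
#' @param bw bandwidth rule passed to [stats::density()] (default "nrd",
#'   Scott's rule).
#' @param weighted weight the two areas by class sizes instead of using
#'   unit-mass densities.
#' @return list with `curve` (threshold, area_fp, area_tp, fdr) and
#'   `threshold` (NA if never below target).
#' @export
kde_driver_fdr <- function(positive_counts, background_counts,
                           thresholds = NULL, fdr_target = 0.30, bw = "nrd",
                           weighted = FALSE) {
  stopifnot(length(positive_counts) > 0, length(background_counts) > 0)
  thresholds <- thresholds %||%
    seq(0L, ceiling(max(c(positive_counts, background_counts))))
  safe_density <- function(v) {
    if (length(unique(v)) < 2) {
      message("degenerate constant counts; falling back to bw = 0.5")
      density(v, bw = 0.5, n = 1024, from = min(thresholds) - 3,
              to = max(thresholds) + 3)
    } else {
      density(v, bw = bw, n = 1024, from = min(thresholds) - 3,
              to = max(thresholds) + 3)
    }
  }
  dp <- safe_density(positive_counts)
  db <- safe_density(background_counts)
  wp <- if (weighted) length(positive_counts) else 1
  wb <- if (weighted) length(background_counts) else 1
  tail_area <- function(d, x0, w) {
    keep <- d$x >= x0
    if (sum(keep) < 2) return(0)
    w * pracma::trapz(d$x[keep], d$y[keep])
  }
  curve <- do.call(rbind, lapply(thresholds, function(x0) {
    afp <- tail_area(db, x0, wb)
    atp <- tail_area(dp, x0, wp)
    data.frame(threshold = x0, area_fp = afp, area_tp = atp,
               fdr = if (afp + atp > 0) afp / (afp + atp) else NA_real_)
  }))
  ok <- which(!is.na(curve$fdr) & curve$fdr <= fdr_target)
  list(curve = curve,
       threshold = if (length(ok) > 0) curve$threshold[min(ok)] else NA_integer_)
}
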