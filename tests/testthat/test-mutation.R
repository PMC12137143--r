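write_maf <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  data.table::fwrite(rows, f, sep = "\t")
  f
}

test_that("MAF-lite reading applies the non-silent whitelist", {
  maf <- data.frame(
    Hugo_Symbol = c("G1", "G2", "G2", "G3", "G3"),
    Tumor_Sample_Barcode = c("S1", "S1", "S1", "S2", "S2"),
    Variant_Classification = c("Missense_Mutation", "Silent", "Silent",
                               "Splice_Site", "Splice_Site"))
  f <- write_maf(maf)
  suppressMessages(cohort <- read_maf_lite(f))
  expect_true(cohort$indicator["G1", "S1"])
  expect_false("G2" %in% rownames(cohort$indicator))   # only Silent rows
  expect_true(cohort$indicator["G3", "S2"])            # duplicates idempotent
  expect_length(maf_nonsilent_classes(), 11L)
  expect_true(all(c("RNA", "Splice_Region", "Translation_Start_Site") %in%
                    maf_nonsilent_classes()))
  f2 <- write_maf(data.frame(gene = "G1", sample = "S1"))
  expect_error(read_maf_lite(f2), "requires columns")
})

test_that("corrected load follows the log2 clamp formula and cohort scaling", {
  # direct formula evaluations
  genes <- c("G1", "G2")
  samples <- sprintf("S%03d", 1:772)
  ind <- matrix(FALSE, 2, 772, dimnames = list(genes, samples))
  ind["G1", 1:5] <- TRUE          # N_obs = 5
  ind["G2", 1] <- TRUE            # N_obs = 1 <= N_exp
  cohort <- structure(list(
    samples = data.frame(sample = samples,
                         cohort = rep(c("WT", "other"), c(44, 728))),
    indicator = ind, expected = c(G1 = 1, G2 = 2),
    maf = NULL, allowed_classes = maf_nonsilent_classes()),
    class = "mutation_cohort")
  M <- corrected_load(cohort)
  expect_equal(unname(M["G1"]), log2(5), tolerance = 1e-12)
  expect_equal(unname(M["G2"]), 0)
  # monotonicity in N_obs for fixed N_exp
  ind2 <- ind; ind2["G2", 1:20] <- TRUE
  cohort2 <- cohort; cohort2$indicator <- ind2
  expect_gt(corrected_load(cohort2)["G2"], M["G2"])
  # cohort scaling: 44 of 772 patients is 5.7%; N_exp,pan = 2 -> 0.114
  M_wt <- corrected_load(cohort, target_cohort = "WT")
  expect_equal(44 / 772 * 2, 0.1139896, tolerance = 1e-6)
  # scaled expectation enters the formula: G1 has 5 WT patients mutated
  expect_equal(unname(M_wt["G1"]), log2(max(5 - 44 / 772 * 1, 0) + 1),
               tolerance = 1e-12)
})

test_that("first-entry lambda matches the coordinate-descent oracle", {
  withr::with_seed(9, {
    for (rep in 1:4) {
      n <- 15; p <- 5
      X <- matrix(rbinom(n * p, 1, 0.4), n, p)
      X <- X[, colSums(X) > 0, drop = FALSE]
      y <- as.numeric(X[, 1] * 2 + rnorm(n, 0, 0.3))
      lam_max <- max(abs(crossprod(X, y))) / n
      grid <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = 30))
      impl <- cellmapr:::.first_entry_lambda(
        Matrix::Matrix(X, sparse = TRUE), y, grid)
      orac <- oracle_lasso_first_entry(X, y, grid)
      expect_equal(impl, orac, tolerance = 1e-6)
    }
  })
})

test_that("selection pressure scores, null behaviour and p-value validity", {
  map <- generate_planted_hierarchy(60, 2, c(6), seed = 10)
  leaves <- truth_leaves(map)
  cm <- build_dag(lapply(leaves, function(id)
    list(members = map$assemblies[[id]], persistence = 1)), map$proteins)

  # all-zero load: every score 0, p = 1
  M0 <- setNames(rep(0, 60), map$proteins)
  s0 <- selection_pressure(M0, cm, n_perm = 100, seed = 1)
  expect_true(all(s0$table$score == 0))
  expect_true(all(s0$table$p == 1))
  expect_false(any(s0$table$selected))

  # the assembly holding all the signal has the maximal score
  M1 <- M0
  hot <- names(cm$assemblies)[2]
  M1[cm$assemblies[[hot]]] <- 2
  s1 <- selection_pressure(M1, cm, n_perm = 100, seed = 1)
  expect_equal(s1$table$assembly[which.max(s1$table$score)], hot)

  # permutation p-values are valid under a structureless load
  withr::with_seed(11, Mr <- setNames(abs(rnorm(60)), map$proteins))
  sr <- selection_pressure(Mr, cm, n_perm = 200, seed = 2)
  expect_true(all(sr$table$p > 0 & sr$table$p <= 1))
  expect_lte(mean(sr$table$p < 0.2), 0.5)   # not anti-conservative wholesale
  expect_error(selection_pressure(Mr, cm, n_perm = 50, seed = 1), "refused")
})

test_that("assembly mutation frequencies apply the distinct-patient and size rules", {
  map <- generate_planted_hierarchy(40, 2, c(4), seed = 12)
  leaves <- truth_leaves(map)
  cm <- build_dag(lapply(leaves, function(id)
    list(members = map$assemblies[[id]], persistence = 1)), map$proteins)
  genes <- map$proteins
  samples <- sprintf("S%02d", 1:40)
  ind <- matrix(FALSE, 40, 40, dimnames = list(genes, samples))
  mem <- cm$assemblies[[setdiff(names(cm$assemblies), "root")[1]]]
  ind[mem[1], "S01"] <- TRUE
  ind[mem[2], "S01"] <- TRUE     # same patient, two members: counted once
  ind[mem[1], "S02"] <- TRUE
  cohort <- structure(list(
    samples = data.frame(sample = samples,
                         cohort = rep(c("big", "small"), c(30, 10))),
    indicator = ind, expected = NULL, maf = NULL,
    allowed_classes = maf_nonsilent_classes()), class = "mutation_cohort")
  fr <- assembly_mutation_frequency(cohort, cm)
  expect_false(any(fr$cohort == "small"))             # < 15 patients excluded
  row <- fr[fr$n_mutated_patients > 0, ]
  expect_equal(row$n_mutated_patients, 2L)            # S01 counted once
  expect_equal(row$frequency, 2 / 30)
  # assemblies beyond the mutated-member cap are excluded
  ind2 <- ind; ind2[, "S03"] <- TRUE
  cohort2 <- cohort; cohort2$indicator <- ind2
  fr2 <- assembly_mutation_frequency(cohort2, cm, max_mutated_proteins = 5)
  expect_equal(nrow(fr2), 0L)
})

test_that("putative drivers require selection and recurrence", {
  map <- generate_planted_hierarchy(30, 2, c(3), seed = 13)
  leaves <- truth_leaves(map)
  cm <- build_dag(lapply(leaves, function(id)
    list(members = map$assemblies[[id]], persistence = 1)), map$proteins)
  ids <- setdiff(names(cm$assemblies), "root")
  sel <- structure(list(table = data.frame(
    assembly = ids, score = 1, p = 0.01, q = 0.01,
    selected = c(TRUE, FALSE, FALSE))), class = "selection_result")
  sel_members <- cm$assemblies[[ids[1]]]
  other_members <- cm$assemblies[[ids[2]]]
  samples <- sprintf("S%02d", 1:10)
  ind <- matrix(FALSE, 30, 10, dimnames = list(map$proteins, samples))
  ind[sel_members[1], 1:3] <- TRUE     # recurrent, in selected assembly
  ind[sel_members[2], 1] <- TRUE       # single patient -> excluded
  ind[other_members[1], 1:5] <- TRUE   # recurrent but unselected assembly
  cohort <- structure(list(samples = data.frame(sample = samples, cohort = "all"),
                           indicator = ind, expected = NULL, maf = NULL,
                           allowed_classes = maf_nonsilent_classes()),
                      class = "mutation_cohort")
  drivers <- putative_drivers(sel, cohort, cm)
  expect_identical(drivers, sel_members[1])
})

test_that("KDE-area FDR reflects separation, symmetry and dominance", {
  # identical distributions: FDR = 0.5 wherever both tails have mass
  same <- c(1, 2, 3, 4, 5, 6)
  res <- kde_driver_fdr(same, same, thresholds = 0:4)
  expect_true(all(abs(res$curve$fdr - 0.5) < 1e-9))

  # complete separation with narrow bandwidth: FDR near 0 above the gap
  res2 <- kde_driver_fdr(rep(10:12, 5), rep(0:1, 5), thresholds = 0:12)
  fdr5 <- res2$curve$fdr[res2$curve$threshold == 5]
  expect_lt(fdr5, 0.05)
  expect_equal(res2$threshold, min(res2$curve$threshold[
    !is.na(res2$curve$fdr) & res2$curve$fdr <= 0.30]))

  # stochastic dominance -> non-increasing FDR in the threshold
  withr::with_seed(14, {
    pos <- rpois(200, 6); bg <- rpois(400, 2)
  })
  res3 <- kde_driver_fdr(pos, bg, thresholds = 0:10)
  expect_true(all(diff(res3$curve$fdr[!is.na(res3$curve$fdr)]) < 1e-9))
})
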