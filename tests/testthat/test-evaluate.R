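test_that("Cliff's delta matches exhaustive enumeration and is antisymmetric", {
  expect_equal(cliffs_delta(c(3, 4), c(1, 2)), 1)
  withr::with_seed(1, {
    for (rep in 1:5) {
      a <- sample(0:10, sample(3:20, 1), replace = TRUE)
      b <- sample(0:10, sample(3:20, 1), replace = TRUE)
      expect_equal(cliffs_delta(a, b), oracle_cliffs(a, b), tolerance = 1e-12)
      expect_equal(cliffs_delta(a, b), -cliffs_delta(b, a), tolerance = 1e-12)
      expect_gte(cliffs_delta(a, b), -1); expect_lte(cliffs_delta(a, b), 1)
    }
  })
})

sim_with_block <- function(n = 20, block = 1:5, hi = 0.9, lo = 0) {
  s <- matrix(lo, n, n, dimnames = list(sprintf("P%02d", 1:n),
                                        sprintf("P%02d", 1:n)))
  s[block, block] <- hi
  diag(s) <- 1
  s
}

test_that("pairset enrichment separates planted positives from background", {
  s <- sim_with_block()
  pos <- t(combn(rownames(s)[1:5], 2))
  res <- pairset_enrichment(s, pos, n_boot = 50, pairs_per_sample = 100, seed = 1)
  expect_equal(res$delta_mean, 1)          # complete separation every bootstrap
  expect_equal(res$delta_sd, 0)
  # positives drawn from the background distribution: mean delta ~ 0
  withr::with_seed(2, {
    sr <- matrix(0, 20, 20, dimnames = dimnames(s))
    sr[upper.tri(sr)] <- rnorm(190)
    sr <- sr + t(sr); diag(sr) <- 1
  })
  res0 <- pairset_enrichment(sr, pos, n_boot = 200, pairs_per_sample = 200,
                             seed = 3)
  expect_lt(abs(res0$delta_mean), 3 * res0$delta_sd)
})

test_that("complex edge enrichment computes exact binomial tails", {
  nodes <- sprintf("N%02d", 1:10)
  # network of 9 edges: the 3 edges of a triangle plus 6 others
  tri <- c("N01", "N02", "N03")
  edges <- data.frame(
    a = c("N01", "N01", "N02", "N04", "N05", "N06", "N07", "N08", "N09"),
    b = c("N02", "N03", "N03", "N05", "N06", "N07", "N08", "N09", "N10"),
    weight = 1)
  net <- structure(list(nodes = nodes, edges = edges,
                        is_bait = setNames(rep(TRUE, 10), nodes)),
                   class = "interaction_network")
  density <- 9 / choose(10, 2)
  catalog <- structure(list(name = "toy", sets = list(
    triangle = tri,                      # all 3 internal edges present
    empty = c("N04", "N07", "N10"),      # 0 internal edges
    pair = c("N01", "N02"))),            # below min_size
    class = "reference_catalog")
  res <- complex_edge_enrichment(net, catalog, fdr = 0.05)
  expect_equal(nrow(res$table), 2L)      # size-2 complex excluded
  p_tri <- res$table$p[res$table$complex == "triangle"]
  expect_equal(p_tri, density^3, tolerance = 1e-12)
  expect_equal(p_tri, oracle_binom_tail(3, 3, density), tolerance = 1e-12)
  expect_equal(res$table$p[res$table$complex == "empty"], 1)
})

test_that("assembly matching combines Jaccard and hypergeometric thresholds", {
  univ <- sprintf("P%02d", 1:30)
  asm <- lapply(list(univ[1:3], univ[4:9]),
                function(s) list(members = s, persistence = 1))
  map <- build_dag(asm, univ)
  # identical assembly present
  res <- match_assembly(univ[1:3], map)
  expect_true(res$matched)
  expect_equal(unname(map$assemblies[[res$best_match]]), univ[1:3])
  # exact-enumeration check of the hypergeometric p inside the matcher:
  # overlap 3 of a 3-set with a 3-set in a 10-protein universe
  expect_equal(cellmapr:::hyper_test(3, 3, 3, 10), 1 / choose(10, 3),
               tolerance = 1e-12)
  expect_equal(oracle_hypergeom(3, 3, 3, 10), 1 / choose(10, 3),
               tolerance = 1e-12)
  # low Jaccard is unmatched regardless of p
  res2 <- match_assembly(c(univ[1:2], univ[20:27]), map, jaccard_min = 0.40)
  expect_false(res2$matched)
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  p <- c(0.01, 0.04, 0.03, 0.005, 0.55)
  # sorted: .005 .01 .03 .04 .55 -> p*(5/rank): .025 .025 .05 .05 .55
  expect_equal(cellmapr:::bh_adjust(p), c(0.025, 0.05, 0.05, 0.025, 0.55))
})

test_that("jackknife robustness and modality dependence behave on planted data", {
  inp <- tiny_pipeline_inputs()
  suppressMessages(al <- align_modalities(inp$fm_x, inp$fm_y))
  cfg <- tiny_config()
  suppressMessages(ref <- cellmap_pipeline(al$x, al$y, cfg, seed = 5))
  rep_count <- 2
  rob <- suppressMessages(
    jackknife_robustness(al$x, al$y, ref$map, cfg, n_reps = rep_count,
                         drop_fraction = 0.10, seed = 6))
  expect_true(all(rob$table$robustness %in% c(0, 0.5, 1)))
  # the planted leaves are strongly separated: their map assemblies persist
  truth <- inp$bundle$truth
  leaf_ids <- vapply(truth$assemblies[truth_leaves(truth)], function(m) {
    ids <- setdiff(names(ref$map$assemblies), "root")
    js <- vapply(ids, function(id)
      length(intersect(m, ref$map$assemblies[[id]])) /
        length(union(m, ref$map$assemblies[[id]])), 1)
    ids[which.max(js)]
  }, "")
  leaf_rob <- rob$table$robustness[match(leaf_ids, rob$table$assembly_id)]
  expect_true(all(leaf_rob >= 0.5))
  expect_gte(mean(leaf_rob), 0.75)

  # randomizing the image modality: structure lives in both, so leaves
  # should survive on the intact interaction modality
  roby <- suppressMessages(
    modality_randomization(al$x, al$y, ref$map, which = "y", cfg,
                           n_reps = rep_count, drop_fraction = 0.10, seed = 7))
  leafy <- roby$table$robustness[match(leaf_ids, roby$table$assembly_id)]
  # when x carries no structure either, randomizing y collapses recovery
  xnoise <- withr::with_seed(13, feature_matrix(
    matrix(rnorm(length(al$x$protein_ids) * 16), ncol = 16,
           dimnames = list(al$x$protein_ids, NULL)), "noise"))
  robxy <- suppressMessages(tryCatch(
    modality_randomization(xnoise, al$y, ref$map, which = "y", cfg,
                           n_reps = rep_count, drop_fraction = 0.10, seed = 8),
    error = function(e) NULL))
  collapsed <- if (is.null(robxy)) 0 else
    mean(robxy$table$robustness[match(leaf_ids, robxy$table$assembly_id)])
  expect_gte(mean(leafy), collapsed)
  # replacement matrix contract: standard normal columns
  rnd <- withr::with_seed(cellmapr:::derive_seed(7, 809L), {
    matrix(rnorm(length(al$y$protein_ids) * al$y$d), length(al$y$protein_ids))
  })
  expect_lt(abs(mean(rnd)), 0.02)
  expect_lt(abs(sd(rnd) - 1), 0.02)
})

test_that("recovery rises as planted feature noise falls", {
  # decreasing image noise = increasing planted signal; mean best Jaccard
  # of the leaves against the inferred map must rise accordingly
  noise <- c(6, 2, 0.5)
  rec <- vapply(noise, function(ns) {
    truth <- generate_planted_hierarchy(48, 2, c(4), seed = 3)
    net <- simulate_apms(truth, p_in = 0.5, p_out = 0.05, seed = 3)
    fmx <- embed_network(net, dim = 24, epochs = 2, seed = 3)
    fmy <- simulate_image_features(truth, dim = 24, noise_sd = ns, seed = 3)
    suppressMessages(res <- cellmap_pipeline(fmx, fmy, tiny_config(seed = 3),
                                             seed = 3))
    mean(leaf_recovery(truth, res$map))
  }, 1)
  expect_gte(rec[2], rec[1])
  expect_gte(rec[3], rec[1] + 0.1)
})

test_that("bait-degree randomization preserves bait interaction counts", {
  b <- make_synthetic_bundle(40, 2, c(4), seed = 9)
  net <- b$network
  rnd <- randomize_bait_degrees(net, seed = 1)
  # interactions per bait are preserved up to collision-deduplication, so
  # the total cannot exceed the bait-incident edge count of the original
  baits <- names(net$is_bait)[net$is_bait]
  per_bait <- vapply(baits, function(v)
    sum(net$edges$a == v | net$edges$b == v), 1)
  expect_lte(nrow(rnd$edges), sum(per_bait))
  expect_gte(nrow(rnd$edges), round(0.5 * sum(per_bait)))
  expect_true(all(c(rnd$edges$a, rnd$edges$b) %in% net$nodes))
  expect_identical(randomize_bait_degrees(net, seed = 4),
                   randomize_bait_degrees(net, seed = 4))
})
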