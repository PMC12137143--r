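test_that("planted hierarchy is balanced, complete and deterministic", {
  # degenerate: root only
  m1 <- generate_planted_hierarchy(12, 1, integer(0), seed = 1)
  expect_length(m1$assemblies, 1L)
  expect_setequal(m1$assemblies[[m1$root]], m1$proteins)

  # 1 root + 3 leaves of 4
  m2 <- generate_planted_hierarchy(12, 2, c(3), seed = 1)
  expect_length(m2$assemblies, 4L)
  leaves <- truth_leaves(m2)
  expect_length(leaves, 3L)
  expect_true(all(lengths(m2$assemblies[leaves]) == 4L))

  # 3 levels: 1 + 4 + 20 assemblies; every protein in exactly one leaf
  m3 <- generate_planted_hierarchy(300, 3, c(4, 5), seed = 1)
  expect_length(m3$assemblies, 25L)
  leaf_members <- unlist(m3$assemblies[truth_leaves(m3)])
  expect_equal(sort(unname(leaf_members)), sort(m3$proteins))
  expect_equal(anyDuplicated(leaf_members), 0L)
  # children are subsets of parents; unique root covers the universe
  for (i in seq_len(nrow(m3$parent_edges))) {
    expect_true(all(m3$assemblies[[m3$parent_edges$child[i]]] %in%
                      m3$assemblies[[m3$parent_edges$parent[i]]]))
  }
  # leaf sizes differ by at most one
  expect_lte(diff(range(lengths(m3$assemblies[truth_leaves(m3)]))), 1L)

  expect_identical(generate_planted_hierarchy(50, 2, c(5), seed = 7),
                   generate_planted_hierarchy(50, 2, c(5), seed = 7))
  expect_error(generate_planted_hierarchy(10, 2, c(11), seed = 1), "exceeds")
  expect_error(generate_planted_hierarchy(10, 2, c(0), seed = 1), "positive")
})

test_that("overlap parameter plants multi-leaf membership", {
  m <- generate_planted_hierarchy(60, 2, c(4), seed = 3, overlap = 0.1)
  leaf_members <- unlist(m$assemblies[truth_leaves(m)])
  expect_gt(sum(duplicated(leaf_members)), 0L)
})

test_that("simulated network has planted leaf structure", {
  m <- generate_planted_hierarchy(40, 2, c(4), seed = 1)
  # extreme parameters: components are exactly the leaves
  net <- simulate_apms(m, p_in = 1, p_out = 0, seed = 1)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = m$proteins)
  comp <- igraph::components(g)$membership
  for (lf in truth_leaves(m))
    expect_length(unique(comp[m$assemblies[[lf]]]), 1L)
  expect_equal(igraph::components(g)$no, 4L)

  # binomial expectation on within-leaf edges: 20 leaves of 15, p_in = 0.8
  m2 <- generate_planted_hierarchy(300, 2, c(20), seed = 2)
  net2 <- simulate_apms(m2, p_in = 0.8, p_out = 0.01, seed = 2)
  within <- sum(vapply(truth_leaves(m2), function(lf) {
    mem <- m2$assemblies[[lf]]
    sum(net2$edges$a %in% mem & net2$edges$b %in% mem)
  }, 1))
  expected <- 20 * choose(15, 2) * 0.8           # 1680
  sd3 <- 3 * sqrt(20 * choose(15, 2) * 0.8 * 0.2)
  expect_lt(abs(within - expected), sd3)

  expect_identical(simulate_apms(m, seed = 5), simulate_apms(m, seed = 5))
  expect_error(simulate_apms(m, p_in = 0.1, p_out = 0.5), "p_out")
})

test_that("image features carry hierarchical cosine structure", {
  m <- generate_planted_hierarchy(30, 2, c(3), seed = 1)
  # noiseless limit: leaf-mates identical
  f0 <- simulate_image_features(m, dim = 16, noise_sd = 0, seed = 1)
  lf <- truth_leaves(m)[1]
  mem <- m$assemblies[[lf]]
  expect_equal(max(dist(f0$values[mem, ])), 0)

  fm <- simulate_image_features(m, dim = 64, seed = 1)
  s <- cosine_similarity_matrix(fm$values)
  same <- matrix(FALSE, 30, 30, dimnames = dimnames(s))
  for (l in truth_leaves(m)) same[m$assemblies[[l]], m$assemblies[[l]]] <- TRUE
  ut <- upper.tri(s)
  expect_gt(mean(s[ut & same]), mean(s[ut & !same]))

  big <- simulate_image_features(generate_planted_hierarchy(300, 3, c(4, 5), seed = 1),
                                 dim = 1024, seed = 1)
  expect_equal(dim(big$values), c(300L, 1024L))
  expect_true(all(is.finite(big$values)))
  expect_error(simulate_image_features(m, noise_sd = -1), "noise_sd")
})

test_that("SEC profiles co-elute within leaves", {
  m <- generate_planted_hierarchy(30, 2, c(3), seed = 1)
  s0 <- simulate_sec(m, noise_sd = 0, jitter = 0, seed = 1)
  mem <- m$assemblies[[truth_leaves(m)[1]]]
  cc <- cor(t(s0$replicates[[1]][mem, ]))
  expect_equal(min(cc), 1, tolerance = 1e-12)

  s1 <- simulate_sec(m, n_fractions = 40, n_reps = 3, seed = 1)
  expect_length(s1$replicates, 3L)
  expect_equal(dim(s1$replicates[[2]]), c(30L, 40L))
  expect_true(all(s1$replicates[[1]] >= 0))
  co <- coelution_similarity(s1)
  same <- matrix(FALSE, 30, 30, dimnames = dimnames(co$sims))
  for (l in truth_leaves(m)) same[m$assemblies[[l]], m$assemblies[[l]]] <- TRUE
  ut <- upper.tri(co$sims)
  expect_gt(mean(co$sims[ut & same]), mean(co$sims[ut & !same]))
  expect_error(simulate_sec(m, peak_sd = 0), "peak_sd")
})

test_that("mutation simulator plants the requested selection signal", {
  m <- generate_planted_hierarchy(200, 2, c(20), seed = 1)
  sel <- truth_leaves(m)[1:3]
  mut <- simulate_mutations(m, n_patients = 200, base_rate = 0.005,
                            selected = sel, effect = 8, seed = 1)
  sel_genes <- unique(unlist(m$assemblies[sel]))
  bg_genes <- setdiff(m$proteins, sel_genes)
  rate_sel <- mean(rowSums(mut$indicator[sel_genes, ])) / 200
  rate_bg <- mean(rowSums(mut$indicator[bg_genes, ])) / 200
  expect_gt(rate_sel / rate_bg, 4)     # ~8x planted, loose stochastic bound
  expect_lt(rate_sel / rate_bg, 16)
  expect_equal(unname(mut$expected[1]), 200 * 0.005)
  expect_identical(simulate_mutations(m, selected = sel, seed = 9)$maf,
                   simulate_mutations(m, selected = sel, seed = 9)$maf)
  expect_error(simulate_mutations(m, base_rate = 0.2, selected = sel,
                                  effect = 8, seed = 1), "exceeds 1")
})

test_that("corrupted catalogs have the constructed Jaccard overlap", {
  m <- generate_planted_hierarchy(32, 2, c(2), seed = 1)   # 2 leaves of 16
  cat0 <- corrupt_catalog(m, 0, 0, seed = 1)
  lf <- truth_leaves(m)
  for (l in lf)
    expect_setequal(cat0$sets[[paste0("ref_", l)]], m$assemblies[[l]])

  cat5 <- corrupt_catalog(m, drop_frac = 0.5, add_frac = 0, seed = 1)
  j <- length(intersect(cat5$sets[[paste0("ref_", lf[1])]], m$assemblies[[lf[1]]])) /
    length(union(cat5$sets[[paste0("ref_", lf[1])]], m$assemblies[[lf[1]]]))
  expect_equal(j, 0.5)

  cat9 <- corrupt_catalog(m, drop_frac = 0.9, add_frac = 2.0, seed = 1)
  j9 <- vapply(lf, function(l) {
    s <- cat9$sets[[paste0("ref_", l)]]
    length(intersect(s, m$assemblies[[l]])) / length(union(s, m$assemblies[[l]]))
  }, 1)
  expect_true(all(j9 < 0.2))
})

test_that("bundle components share one universe and regenerate identically", {
  b <- make_synthetic_bundle(60, 2, c(4), seed = 5)
  expect_setequal(b$image_features$protein_ids, b$truth$proteins)
  expect_setequal(b$sec$proteins, b$truth$proteins)
  expect_setequal(rownames(b$mutations$indicator), b$truth$proteins)
  expect_true(all(unlist(b$catalogs[[1]]$sets) %in% b$truth$proteins))
  expect_true(all(c(b$network$edges$a, b$network$edges$b) %in% b$truth$proteins))
  b2 <- make_synthetic_bundle(60, 2, c(4), seed = 5)
  expect_identical(b$network$edges, b2$network$edges)
  expect_identical(b$image_features$values, b2$image_features$values)
  expect_identical(b$sec$replicates, b2$sec$replicates)
})
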