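test_that("UPGMA clustering reproduces the known membrane grouping", {
  m <- dprime_matrix(pampa_nine())
  h <- hierarchical_cluster(m)
  # first (lowest) merge joins the two skin membranes, at D' < 1
  expect_equal(sort(-h$merge[1, ]), c(1, 2))
  expect_lt(h$height[1], 1)
  expect_equal(h$height[1], m["1", "2"])
  # second cluster: the two alkane-coated intestinal membranes (4, 5)
  expect_equal(sort(-h$merge[2, ]), c(4, 5))
  # leaves are exactly the input ids
  expect_setequal(h$labels, rownames(m))
})

test_that("UPGMA heights are monotone and the tree round-trips to Newick", {
  sys <- random_systems(10, seed = 3)
  m <- dprime_matrix(sys)
  h <- hierarchical_cluster(m, linkage = "upgma")
  expect_true(all(diff(h$height) >= -1e-12))
  nwk <- dendrogram_newick(h)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, sys$system_id)
  expect_true(ape::is.ultrametric(tree, tol = 1e-6))

  # two-leaf input merges once at the pairwise distance
  h2 <- hierarchical_cluster(dprime_matrix(sys[1:2, ]))
  expect_equal(h2$height, m["sys1", "sys2"])
  expect_error(hierarchical_cluster(dprime_matrix(sys)[1, 1, drop = FALSE]),
               "at least 2")
})

test_that("covariance PCA of the nine membranes matches its eigenstructure", {
  nine <- pampa_nine()
  p <- pca_coefficients(nine, k = 2)
  # two components carry (essentially all) the variance
  expect_gte(sum(p$explained_variance_fraction), 0.94)
  # independent route: prcomp on the same rows
  pr <- prcomp(as.matrix(nine[, c("e", "s", "a", "b", "v")]),
               center = TRUE, scale. = FALSE)
  expect_equal(abs(unname(p$loadings)), abs(unname(pr$rotation[, 1:2])),
               tolerance = 1e-9)
  expect_equal(p$eigenvalues, unname(pr$sdev^2), tolerance = 1e-9)
  # loadings are orthonormal
  expect_equal(crossprod(p$loadings), diag(2), ignore_attr = TRUE,
               tolerance = 1e-12)
  # sign convention: the largest-|loading| entry of each PC is positive
  for (j in 1:2) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("PCA satisfies its structural invariants", {
  sys <- random_systems(9, seed = 5)
  p5 <- pca_coefficients(sys, k = 5)
  expect_equal(sum(p5$explained_variance_fraction), 1)
  expect_true(all(diff(p5$explained_variance_fraction) <= 1e-12))
  # exact reconstruction from all five components
  X <- as.matrix(sys[, c("e", "s", "a", "b", "v")])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(unname(p5$scores %*% t(p5$loadings)), unname(Xc),
               tolerance = 1e-9, ignore_attr = TRUE)
  # loadings invariant (up to sign) under row permutation
  perm <- sys[sample(nrow(sys)), ]
  pp <- pca_coefficients(perm, k = 2)
  expect_equal(abs(unname(pp$loadings)),
               abs(unname(pca_coefficients(sys, k = 2)$loadings)),
               tolerance = 1e-9)

  # data varying along one coordinate collapses to that axis
  flat <- sys; flat[, c("s", "a", "b", "v")] <-
    matrix(rep(c(-1, -2, -3, 2), each = nrow(sys)), nrow = nrow(sys))
  p1 <- pca_coefficients(flat, k = 1)
  expect_equal(unname(p1$loadings[, 1]), c(1, 0, 0, 0, 0), tolerance = 1e-9)
  expect_equal(p1$explained_variance_fraction, 1)
  expect_error(pca_coefficients(sys[1:2, ]), "at least 3")
})

test_that("biological comparison flags exactly the emulating pairs", {
  pam <- pampa_nine(); pam <- pam[pam$system_id != "9", ]
  bio <- bio_five()
  tab <- compare_to_biological(pam, bio, threshold = 1.0)
  flagged <- tab[tab$emulates, c("biological", "pampa")]
  got <- paste(flagged$biological, flagged$pampa)
  expect_setequal(got, c("10 1", "10 2", "11 2", "14 1", "14 2"))
  # one code path with dprime_matrix
  m <- dprime_matrix(pampa_systems())
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$dprime[i], m[tab$biological[i], tab$pampa[i]])
  }
  # degenerate thresholds
  expect_false(any(compare_to_biological(pam, bio, threshold = 0)$emulates))
  expect_true(all(compare_to_biological(pam, bio, threshold = Inf)$emulates))
  expect_error(compare_to_biological(pam[0, ], bio), "non-empty")
})

test_that("radial plot data is an ordered pass-through of the coefficients", {
  nine <- pampa_nine()
  rd <- radial_plot_data(nine)
  expect_equal(nrow(rd), 9 * 5)
  expect_equal(levels(rd$axis), c("e", "s", "a", "b", "v"))
  # identity pass-through
  for (id in nine$system_id) {
    expect_equal(rd$value[rd$system_id == id],
                 as.numeric(nine[nine$system_id == id,
                                 c("e", "s", "a", "b", "v")]))
  }
  # stable axis order across calls
  expect_identical(rd$axis, radial_plot_data(nine)$axis)
  # the hexadecane P16 membrane has the smallest |v|
  v_by_sys <- rd$value[rd$axis == "v"]
  expect_equal(nine$system_id[which.min(abs(v_by_sys))], "9")
})
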