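test_that("newick parsing, validation and round-trip identity", {
  tr <- read_species_tree("(A:1,B:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))

  tr6 <- example_species_tree()
  expect_equal(ape::Ntip(tr6), 6L)
  expect_equal(max(ape::node.depth.edgelength(tr6)), 15)
  expect_true(attr(validate_species_tree(tr6), "ultrametric"))

  # write-read round trip preserves splits and lengths
  txt <- write_species_tree(tr6)
  tr6b <- read_species_tree(txt)
  expect_equal(ape::dist.topo(ape::unroot(tr6), ape::unroot(tr6b)), 0,
               ignore_attr = TRUE)
  d1 <- ape::cophenetic.phylo(tr6); d2 <- ape::cophenetic.phylo(tr6b)
  expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-10)

  expect_error(read_species_tree("(A:1,B:1"), "malformed")
  expect_error(read_species_tree("(A,B);"), "length")
  expect_error(read_species_tree("(A:1,A:1);"), "unique")
  expect_error(read_species_tree("(A:1,B:0);"), "> 0")
})

test_that("BM covariance matches hand computation and edge-walk simulation", {
  # two tips, no shared path
  t2 <- read_species_tree("(A:2,B:2);")
  expect_equal(bm_covariance(t2, 1),
               matrix(c(2, 0, 0, 2), 2, dimnames = list(c("A", "B"), c("A", "B"))))

  # hand-computed 3-tip case: Cov(A,B) = 1 (shared path), Var(A) = 2
  t3 <- read_species_tree("((A:1,B:1):1,C:2);")
  V <- bm_covariance(t3, 1)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["C", "C"], 2)
  expect_equal(V["A", "C"], 0)
  expect_equal(V, t(V))

  expect_error(bm_covariance(t3, 0), "positive")

  # brute-force oracle: empirical covariance of edge-walk simulated draws
  set.seed(42)
  draws <- sim_tips_bm_oracle(t3, 1e5, sigma2 = 1.5)
  emp <- cov(draws)
  expect_equal(emp, bm_covariance(t3, 1.5)[colnames(emp), colnames(emp)],
               tolerance = 0.03)
})

test_that("OU covariance: zero-distance variance, decay, simulation oracle", {
  tr <- example_species_tree()
  p <- ou_params(alpha = 0.3, sigma2 = 1.2)
  V <- ou_covariance(tr, p)
  expect_equal(unname(diag(V)), rep(p$sigma2 / (2 * p$alpha), 6))
  expect_equal(V, t(V))
  # monotone decay in patristic distance
  d <- ape::cophenetic.phylo(tr)[rownames(V), colnames(V)]
  ut <- upper.tri(V)
  expect_true(all(diff(V[ut][order(d[ut])]) <= 1e-12))
  expect_error(ou_covariance(tr, ou_params(0, 1)), "alpha")

  # stationary-OU edge-walk oracle
  t3 <- read_species_tree("((A:1,B:1):1,C:2);")
  set.seed(7)
  draws <- sim_tips_ou_oracle(t3, 1e5, alpha = 0.5, sigma2 = 1, theta = 2)
  emp <- cov(draws)
  Vou <- ou_covariance(t3, ou_params(0.5, 1))[colnames(emp), colnames(emp)]
  expect_equal(emp, Vou, tolerance = 0.04)
  expect_equal(unname(colMeans(draws)), rep(2, 3), tolerance = 0.02)
})

test_that("covariance builders give Cholesky-safe symmetric matrices", {
  tr <- example_species_tree()
  for (V in list(bm_covariance(tr, 0.7),
                 ou_covariance(tr, ou_params(2, 1)),
                 ou_covariance(tr, ou_params(0.05, 0.3), stationary = FALSE))) {
    expect_equal(V, t(V))
    expect_no_error(chol(V + diag(1e-10, nrow(V))))
  }
})

test_that("replicate covariance adds sigma2_e on the diagonal only", {
  tr <- example_species_tree()
  V <- ou_covariance(tr, ou_params(0.5, 1))
  sp <- rep(tr$tip.label, each = 3)
  R0 <- replicate_covariance(V, sp, 0)
  R1 <- replicate_covariance(V, sp, 0.25)
  expect_equal(unname(diag(R1) - diag(R0)), rep(0.25, length(sp)))
  off <- R1 - R0; diag(off) <- 0
  expect_equal(max(abs(off)), 0)
  expect_error(replicate_covariance(V, c("nope"), 0), "unknown species")
})

test_that("regimes validate shift structure and propagate optima", {
  tr <- example_species_tree()
  r0 <- regime_from_shifts(tr)
  expect_length(r0$shift_edges, 0)
  expect_equal(unique(r0$edge_optimum), 1L)

  # single shift: subtree inherits the new optimum
  e_mel <- which(edge_labels(tr) == "Dmel")
  r1 <- regime_from_shifts(tr, e_mel, optima = c(4, 8))
  expect_equal(r1$shift_edges, e_mel)
  expect_equal(sum(r1$edge_optimum == 2L), 1L)

  # shift on an internal edge covers all descendant edges
  e_n10 <- which(edge_labels(tr) == "n10")
  r2 <- regime_from_shifts(tr, e_n10, optima = c(4, 8))
  covered <- edge_labels(tr)[r2$edge_optimum == 2L]
  expect_setequal(covered, c("n10", "Dsim", "Dsec"))

  # both children of the root shifted: ancestral optimum kept as parameter
  root_children <- which(exprevol:::parent_edge_index(tr) == 0L)
  r3 <- regime_from_shifts(tr, root_children)
  expect_length(r3$shift_edges, 2L)
  expect_equal(max(r3$edge_optimum), 3L)

  expect_error(regime(tr, rep(2L, nrow(tr$edge))), "invariant")
})

test_that("OU tip means follow exact conditional propagation", {
  tr <- example_species_tree()
  e_mel <- which(edge_labels(tr) == "Dmel")
  r <- regime_from_shifts(tr, e_mel, optima = c(4, 8))
  for (a in c(0.2, 1, 5)) {
    mu <- ou_tip_means(r, a)
    # non-shifted tips stay at the ancestral optimum
    expect_equal(unname(mu[c("Dsim", "Dsec", "Dsan", "Dere", "Dsuz")]),
                 rep(4, 5), tolerance = 1e-10)
    # shifted tip approaches the new optimum with weight 1 - exp(-a * t)
    expect_equal(unname(mu["Dmel"]), 4 + (1 - exp(-a * 3)) * 4,
                 tolerance = 1e-10)
  }
  # design rows are convex weights
  w <- exprevol:::oum_design(tr, r, 0.7)
  expect_equal(unname(rowSums(w)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(w >= -1e-12))
})

test_that("edge visibility quantifies shift reversion before the tips", {
  tr <- example_species_tree()
  vis <- edge_visibility(tr, 1)
  # terminal edges several half-lives long are fully visible
  expect_gt(vis[["Dsuz"]], 0.99)
  expect_gt(vis[["Dmel"]], 0.9)
  # deep internal edges ending ~10 My before the tips are invisible
  expect_lt(vis[["n8"]], 1e-3)
  expect_lt(vis[["n9"]], 0.06)
  # weaker selection raises deep-edge visibility
  expect_gt(edge_visibility(tr, 0.05)[["n8"]], vis[["n8"]])
})
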