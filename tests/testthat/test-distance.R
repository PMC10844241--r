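tr <- example_species_tree()

test_that("sOU distance is a valid dissimilarity with the right zeros", {
  set.seed(11)
  base <- rexp(200, 1 / 20)
  m <- sapply(1:3, function(i) base * exp(rnorm(200, 0, 0.3)))
  dimnames(m) <- list(paste0("g", 1:200), c("A", "B", "C"))
  # identical expression vectors are at distance zero
  m[, "B"] <- m[, "A"]
  D <- sou_distance(m)
  expect_equal(D["A", "B"], 0)
  expect_true(all(D >= 0))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))

  # label permutation permutes rows and columns identically
  D2 <- sou_distance(m[, c("C", "A", "B")])
  expect_equal(D2[c("A", "B", "C"), c("A", "B", "C")], D)

  # distance is invariant to a global expression rescaling only through
  # correlation of logs; a constant multiple changes little but symmetry
  # and the gene filter must hold
  expect_error(sou_distance(m[1:10, ]), "fewer than")
})

test_that("sOU distance grows monotonically with divergence time", {
  sm <- simulate_species_means(tr, 5000, seed = 3)
  D <- sou_distance(sm)
  dt <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  ut <- upper.tri(D)
  # tied patristic distances (6 pairs at 20 My, 5 at 30 My on this tree)
  # cap the attainable Spearman below 1 even under perfect monotonicity;
  # the cap is the correlation of a perfectly ordered vector with the
  # tied times
  dtv <- dt[ut]
  cap <- cor(rank(dtv)[order(dtv)], seq_along(dtv))
  expect_gt(cor(D[ut], dtv, method = "spearman"), cap - 0.01)
  # strict monotonicity of mean distance across divergence-time groups
  grp <- tapply(D[ut], dt[ut], mean)
  expect_true(all(diff(grp[order(as.numeric(names(grp)))]) > 0))
})

test_that("NJ recovers additive matrices exactly and roots on the outgroup", {
  # hand-constructed additive 4-taxon matrix: ((A:1,B:2):1,(C:3,D:1));
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  Dadd <- ape::cophenetic.phylo(ref)
  nj <- ape::nj(as.dist(Dadd))
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  d_rec <- ape::cophenetic.phylo(nj)[rownames(Dadd), colnames(Dadd)]
  expect_equal(d_rec, Dadd, tolerance = 1e-10)

  # panels simulated on the species tree: topology recovered, high supports
  sm <- simulate_species_means(tr, 5000, seed = 3)
  njt <- nj_tree(sm, outgroup = "Dsuz", n_bootstrap = 100, seed = 5)
  expect_equal(ape::dist.topo(ape::unroot(njt), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  sup <- suppressWarnings(as.numeric(njt$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))

  # duplicated taxon (distance ~0 to its twin) becomes its sibling
  sm_twin <- cbind(sm, Dtwin = sm[, "Dmel"] * (1 + rnorm(nrow(sm), 0, 1e-4)))
  njt2 <- nj_tree(sm_twin, outgroup = "Dsuz", n_bootstrap = 0)
  pair <- ape::getMRCA(njt2, c("Dmel", "Dtwin"))
  expect_equal(length(ape::extract.clade(njt2, pair)$tip.label), 2L)

  expect_error(nj_tree(sm, outgroup = "nope"), "not among")
})

test_that("relative-rate Z is zero under symmetry and antisymmetric", {
  set.seed(13)
  m <- matrix(rexp(300 * 3, 1 / 30), 300, 3,
              dimnames = list(paste0("g", 1:300), c("A", "B", "O")))
  # identical ingroup matrices: Z exactly 0
  m[, "B"] <- m[, "A"]
  expect_equal(relative_rate(m, "A", "B", "O")$Z, 0)

  sm <- simulate_species_means(tr, 800, seed = 17)
  z_ab <- relative_rate(sm, "Dmel", "Dsan", "Dsuz", seed = 9)$Z
  z_ba <- relative_rate(sm, "Dsan", "Dmel", "Dsuz", seed = 9)$Z
  expect_equal(z_ab, -z_ba, tolerance = 1e-10)

  # scale invariance: multiplying all TPM by a constant barely moves Z
  z_sc <- relative_rate(sm * 2, "Dmel", "Dsan", "Dsuz", seed = 9)$Z
  expect_equal(z_ab, z_sc, tolerance = 0.3)

  expect_error(relative_rate(sm, "Dmel", "Dmel", "Dsuz"), "distinct")
  expect_error(relative_rate(sm[1:10, ], "Dmel", "Dsan", "Dsuz"),
               "fewer than")
})

test_that("subsampled rate test flags the accelerated lineage only", {
  sm <- simulate_species_means(tr, 2000, rate_scale = c(Dmel = 3), seed = 8)
  pairs <- list(c("Dmel", "Dsan"), c("Dmel", "Dere"), c("Dsim", "Dere"),
                c("Dsec", "Dsan"), c("Dsim", "Dsec"))
  st <- subsampled_rate_test(sm, pairs, "Dsuz", n_genes = 500, n_reps = 100,
                             n_boot = 50, seed = 2)
  verdicts <- vapply(st$results, `[[`, character(1), "verdict")
  expect_equal(unname(verdicts[c("Dmel_Dsan", "Dmel_Dere")]),
               c("elevated_A", "elevated_A"))
  expect_equal(unname(verdicts[c("Dsim_Dere", "Dsec_Dsan", "Dsim_Dsec")]),
               rep("ns", 3))
  # determinism under a fixed seed
  st2 <- subsampled_rate_test(sm, pairs, "Dsuz", n_genes = 500, n_reps = 100,
                              n_boot = 50, seed = 2)
  expect_identical(st$results$Dmel_Dsan$Z, st2$results$Dmel_Dsan$Z)
  expect_identical(vapply(st2$results, `[[`, character(1), "verdict"),
                   verdicts)

  # degenerate case: every pair significant leaves no null bound
  sm_all <- simulate_species_means(
    tr, 1200, rate_scale = c(Dmel = 9, Dsim = 9, Dsec = 9), seed = 10)
  expect_error(
    subsampled_rate_test(sm_all,
                         list(c("Dmel", "Dsan"), c("Dsim", "Dere"),
                              c("Dsec", "Dere")),
                         "Dsuz", n_genes = 300, n_reps = 20, n_boot = 50,
                         seed = 3),
    "bounds")
})
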