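test_that("panel simulation is a pure function of spec and seed", {
  spec <- sim_spec(n_genes = 20, tissues = c("antenna", "larva"),
                   sexed_tissues = "antenna",
                   changers = list(n = 5, delta = 4, tissues_per = 2,
                                   coincidental_fraction = 0.5),
                   seed = 99)
  p1 <- simulate_panel(spec)
  p2 <- simulate_panel(spec)
  expect_identical(p1$tpm, p2$tpm)
  expect_identical(p1$truth, p2$truth)
  # a different seed changes the draw
  p3 <- simulate_panel(sim_spec(n_genes = 20, tissues = c("antenna", "larva"),
                                sexed_tissues = "antenna", seed = 100))
  expect_false(identical(p1$tpm[, 1], p3$tpm[, 1]))
  # generators do not perturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_panel(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero-variance spec collapses to the root state", {
  spec <- sim_spec(n_genes = 5, tissues = "larva",
                   sexed_tissues = character(0),
                   params = ou_params(alpha = 0.5, sigma2 = 1e-12,
                                      sigma2_e = 0),
                   root_mean = 4, seed = 1)
  p <- simulate_panel(spec)
  expect_equal(unname(as.numeric(p$tpm)), rep(2^4 - 1, length(p$tpm)),
               tolerance = 1e-4)
})

test_that("panel metadata mirrors the study design", {
  spec <- sim_spec(n_genes = 10, seed = 2)
  p <- simulate_panel(spec)
  # 3 sexed tissues x 2 sexes x 3 reps + 2 unsexed x 3 reps = 24 per species
  expect_equal(ncol(p$tpm), 6 * (3 * 2 * 3 + 2 * 3))
  expect_setequal(unique(p$meta$tissue), spec$tissues)
  expect_setequal(unique(p$meta$sex[p$meta$tissue == "antenna"]),
                  c("female", "male"))
  expect_equal(unique(p$meta$sex[p$meta$tissue == "larva"]), "mixed")
})

test_that("simulated species means reproduce the requested kernel", {
  tr <- example_species_tree()
  p <- ou_params(alpha = 0.5, sigma2 = 1, sigma2_e = 0)
  spec <- sim_spec(tree = tr, n_genes = 1e4, tissues = "larva",
                   sexed_tissues = character(0), n_replicates = 2,
                   params = p, root_mean = 6, seed = 31)
  pan <- simulate_panel(spec)
  # recover the log-scale species means from replicate-free expectations
  lg <- log2(species_mean_tpm(pan, "larva") + 1)
  emp <- cov(lg)
  V <- ou_covariance(tr, p)[colnames(emp), colnames(emp)]
  expect_equal(emp, V, tolerance = 0.06)
})

test_that("planted truth table describes coincidental structure", {
  spec_c1 <- sim_spec(n_genes = 40, changers = list(
    n = 20, delta = 4, tissues_per = 3, coincidental_fraction = 1), seed = 5)
  tr1 <- simulate_panel(spec_c1)$truth
  per_gene_edges <- tapply(tr1$edge, tr1$gene, function(e) length(unique(e)))
  expect_true(all(per_gene_edges == 1))

  spec_c0 <- sim_spec(n_genes = 40, changers = list(
    n = 20, delta = 4, tissues_per = 3, coincidental_fraction = 0), seed = 5)
  tr0 <- simulate_panel(spec_c0)$truth
  per_gene_edges0 <- tapply(tr0$edge, tr0$gene, function(e) length(unique(e)))
  expect_gt(mean(per_gene_edges0 > 1), 0.5)
})

test_that("count sampling matches NB moments and library scaling", {
  tpm <- matrix(50, 400, 4, dimnames = list(paste0("g", 1:400), paste0("s", 1:4)))
  # dispersion -> 0 limit: Poisson-like variance
  cp <- panel_to_counts(tpm, nb_dispersion = 0, seed = 3)
  expect_equal(var(as.numeric(cp)) / mean(cp), 1, tolerance = 0.1)
  # NB: var = mu + disp mu^2
  cn <- panel_to_counts(tpm, nb_dispersion = 0.2, seed = 3)
  expect_equal(mean(cn), 50, tolerance = 3 * sqrt(50 * (1 + 0.2 * 50) / 1600))
  expect_equal(var(as.numeric(cn)), 50 + 0.2 * 2500, tolerance = 60)
  # library size doubling doubles the mean
  c2 <- panel_to_counts(tpm, nb_dispersion = 0.1,
                        library_sizes = rep(2e6, 4), seed = 3)
  expect_equal(mean(c2) / mean(panel_to_counts(tpm, 0.1, seed = 3)), 2,
               tolerance = 0.05)
  expect_error(panel_to_counts(tpm, nb_dispersion = -1), "dispersion")
})

test_that("atlas pair simulation respects sharing structure", {
  # full sharing with identical profiles: truth map is the identity
  pr <- simulate_atlas_pair(n_clusters = 4, n_genes = 150,
                            n_shared_clusters = 4, planted_cor = 1, seed = 8)
  expect_equal(pr$truth$cluster_a, paste0("A", 1:4))
  expect_equal(pr$truth$cluster_b, paste0("B", 1:4))
  for (i in 1:4) expect_setequal(pr$markers_a[[i]], pr$markers_b[[i]])

  # no sharing: disjoint marker universes
  pr0 <- simulate_atlas_pair(n_clusters = 3, n_genes = 200,
                             n_shared_clusters = 0, seed = 9)
  expect_equal(nrow(pr0$truth), 0)
  expect_length(intersect(unlist(pr0$markers_a), unlist(pr0$markers_b)), 0)

  expect_error(simulate_atlas_pair(n_clusters = 10, n_genes = 50,
                                   n_shared_clusters = 0),
               "exceed")
  expect_error(simulate_atlas_pair(n_clusters = 2, n_shared_clusters = 3),
               "n_shared_clusters")
})

test_that("alignment simulation plants exactly the requested gaps", {
  sp <- c("s1", "s2", "s3")
  # no gaps: one contiguous conserved block over everything
  a0 <- simulate_alignment(sp, 500, seed = 1)
  expect_true(all(!grepl("-", a0$seqs, fixed = TRUE)))

  a1 <- simulate_alignment(sp, 500,
          gaps = data.frame(species = "s2", start = 101, length = 200),
          seed = 1)
  runs <- gregexpr("-+", a1$seqs[["s2"]])[[1]]
  expect_equal(as.integer(runs), 101)
  expect_equal(attr(runs, "match.length"), 200)
  expect_false(grepl("-", a1$seqs[["s1"]], fixed = TRUE))

  # FASTA round trip
  f <- tempfile(fileext = ".fa")
  write_alignment_fasta(a1, f)
  back <- read_alignment_fasta(f)
  expect_identical(unname(back[sp]), unname(a1$seqs[sp]))

  expect_error(simulate_alignment(sp, 100,
    gaps = data.frame(species = "s1", start = 90, length = 20)), "bounds")
  expect_error(simulate_alignment(sp, 100,
    gaps = data.frame(species = c("s1", "s1"), start = c(10, 15),
                      length = c(10, 10))), "overlapping")
})

test_that("alignment anchors increase strictly over non-gap columns", {
  a <- simulate_alignment(c("x", "y"), 300,
        gaps = data.frame(species = "x", start = c(50, 200),
                          length = c(30, 40)),
        genomic_start = c(100, 900), seed = 2)
  m <- exprevol:::aln_matrix(a)
  nongap <- m["x", ] != "-"
  pos <- a$genomic_start[["x"]] + cumsum(nongap) - 1
  expect_true(all(diff(pos[nongap]) > 0))
})
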