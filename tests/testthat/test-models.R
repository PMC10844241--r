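tr <- example_species_tree()

test_that("BM fitting recovers sigma2 and respects scale equivariance", {
  set.seed(21)
  n_genes <- 300
  draws <- sim_tips_bm_oracle(tr, n_genes, sigma2 = 1, root = 4)
  s2 <- vapply(seq_len(n_genes), function(g) {
    traits <- sapply(1:3, function(r) draws[g, ] + rnorm(6, 0, sqrt(0.05)))
    rownames(traits) <- colnames(draws)
    fit_bm(traits, tr)$sigma2
  }, numeric(1))
  # REML is mean-unbiased; the per-gene sampling distribution is
  # chi-squared-like with n_species - 1 = 5 dof, so the median sits near
  # qchisq(.5, 5)/5 = 0.871 (frozen oracle value)
  expect_equal(mean(s2), 1, tolerance = 0.1)
  expect_equal(median(s2), qchisq(0.5, 5) / 5, tolerance = 0.08)

  # doubling all branch lengths halves the sigma2 estimate
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  traits <- sapply(1:3, function(r) draws[5, ] + rnorm(6, 0, 0.2))
  rownames(traits) <- colnames(draws)
  f1 <- fit_bm(traits, tr); f2 <- fit_bm(traits, tr2)
  expect_equal(f2$sigma2, f1$sigma2 / 2, tolerance = 1e-4)
  expect_equal(f2$logL, f1$logL, tolerance = 1e-4)

  # all-identical observations flag as degenerate
  flat <- matrix(3, 6, 3, dimnames = list(tr$tip.label, NULL))
  expect_true(fit_bm(flat, tr)$degenerate)
})

test_that("OU fitting recovers alpha and planted optima", {
  set.seed(22)
  n_genes <- 120
  a_true <- 0.5
  draws <- sim_tips_ou_oracle(tr, n_genes, alpha = a_true, sigma2 = 1,
                              theta = 4)
  alphas <- vapply(seq_len(n_genes), function(g) {
    traits <- sapply(1:3, function(r) draws[g, ] + rnorm(6, 0, sqrt(0.05)))
    rownames(traits) <- colnames(draws)
    fit_ou(traits, tr)$alpha
  }, numeric(1))
  med <- median(alphas)
  expect_gt(med, a_true / 2)
  expect_lt(med, a_true * 2)

  # strong planted shift: optimum estimates behave like the analytic GLS
  # oracle. With alpha known, theta_2 is identified through the shifted
  # tip only: SE = sqrt(tip variance + replicate SE^2) / visibility, so
  # median |error| = 0.675 * SE (half-normal median, frozen oracle value).
  e_mel <- which(edge_labels(tr) == "Dmel")
  reg <- regime_from_shifts(tr, e_mel, optima = c(4, 4 + 4 * sqrt(0.5)))
  mu <- ou_tip_means(reg, 1)
  V <- ou_covariance(tr, ou_params(1, 1))
  L <- chol(V)
  err <- replicate(80, {
    means <- mu + drop(t(L) %*% rnorm(6))
    traits <- sapply(1:3, function(r) means + rnorm(6, 0, sqrt(0.05)))
    rownames(traits) <- tr$tip.label
    th <- fit_ou(traits, tr, regime_from_shifts(tr, e_mel), alpha = 1)$theta
    th - reg$optima
  })
  w <- 1 - exp(-1 * 3)                       # shift visibility on Dmel
  se2 <- sqrt(0.5 + 0.05 / 3) / w            # analytic SE of theta_2
  expect_lt(abs(mean(err[2, ])), 3 * se2 / sqrt(80))   # unbiased
  expect_equal(median(abs(err[2, ])), 0.675 * se2, tolerance = 0.35)
  expect_lt(median(abs(err[1, ])), 0.5)      # ancestral optimum: 5 tips
})

test_that("OU likelihood converges to BM as alpha -> 0 (fixed-root form)", {
  set.seed(23)
  y <- matrix(rnorm(18, 4, 1), 6, 3, dimnames = list(tr$tip.label, NULL))
  bm <- fit_bm(y, tr)
  ou <- fit_ou(y, tr, alpha = 1e-6, gamma = bm$gamma, stationary = FALSE)
  expect_equal(ou$logL, bm$logL, tolerance = 1e-3)
})

test_that("shift configuration enumeration is exhaustive and valid", {
  cfgs <- enumerate_shift_configs(tr, max_shifts = 3)
  # 1 + C(10,1) + C(10,2) + C(10,3) on the 10-edge, 6-taxon tree
  expect_length(cfgs, 176L)
  expect_length(enumerate_shift_configs(tr, 0), 1L)
  ns <- vapply(cfgs, function(r) length(r$shift_edges), integer(1))
  expect_equal(unname(table(ns)), c(1L, 10L, 45L, 120L), ignore_attr = TRUE)
  # each regime satisfies its invariants (constructor validates)
  for (r in cfgs[seq(1, 176, by = 25)]) {
    expect_s3_class(r, "regime")
    expect_equal(max(r$edge_optimum), length(r$shift_edges) + 1L)
  }
  expect_warning(enumerate_shift_configs(tr, 99), "capped")
})

test_that("model selection is parsimonious without signal", {
  # identical replicate sets with tiny noise: OU1 or BM, never OUM
  for (s in 1:5) {
    traits <- toy_traits(tr, rep(5, 6), sd_rep = 0.01, seed = s)
    f <- select_model(traits, tr)
    expect_true(f$selected %in% c("BM", "OU1"))
    expect_length(f$shift_edges, 0)
  }
})

test_that("selected pBIC is minimal and OUM logL dominates nested OU1", {
  set.seed(24)
  means <- 4 + drop(t(chol(ou_covariance(tr, ou_params(0.5, 1)))) %*% rnorm(6))
  traits <- sapply(1:3, function(r) means + rnorm(6, 0, 0.2))
  rownames(traits) <- tr$tip.label
  f <- select_model(traits, tr)
  sel <- f$scores$pBIC[f$scores$model == f$selected &
                         f$scores$n_shifts == f$n_shifts]
  expect_true(all(min(sel) <= f$scores$pBIC + 1e-9))
  # nested richer regimes never lose likelihood at the optimum
  ou1 <- f$scores$logL[f$scores$model == "OU1"]
  expect_true(all(f$scores$logL[f$scores$model == "OUM"] >= ou1 - 1e-4))
})

test_that("planted shifts are found on the planted edge with direction", {
  spec <- sim_spec(n_genes = 40, tissues = "antenna",
                   sexed_tissues = character(0),
                   params = ou_params(alpha = 1, sigma2 = 1, sigma2_e = 0.05),
                   changers = list(n = 20, delta = 5, tissues_per = 1,
                                   coincidental_fraction = 0,
                                   min_visibility = 0.7),
                   seed = 77)
  pan <- simulate_panel(spec)
  fits <- fit_gene_models(panel_traits(pan, "antenna"), tr,
                          tissue = "antenna")
  ev <- change_events(fits)
  hit <- merge(pan$truth, ev, by = c("gene", "tissue", "edge"))
  expect_gt(nrow(hit), 10)
  expect_true(all(hit$direction.x == hit$direction.y))
  # background genes stay shift-free in the large majority
  bg <- setdiff(names(fits), pan$truth$gene)
  bg_events <- sum(vapply(fits[bg], function(f) length(f$shift_edges),
                          integer(1)))
  expect_lt(bg_events / length(bg), 0.25)
})

test_that("branch classification aggregates fits into the three classes", {
  mk_fit <- function(model, shift_edges = integer(0)) {
    elab <- edge_labels(tr)
    bc <- setNames(rep(switch(model, BM = "neutral", "constrained"),
                       length(elab)), elab)
    bc[shift_edges] <- "divergent"
    structure(list(gene = "g", tissue = "t", degenerate = FALSE,
                   selected = model, shift_edges = shift_edges,
                   shift_edge_labels = elab[shift_edges],
                   directions = rep("up", length(shift_edges)),
                   branch_class = bc),
              class = "gene_fit")
  }
  # all OU1: 100% constrained
  cl <- classify_branches(replicate(10, mk_fit("OU1"), simplify = FALSE))
  expect_equal(unname(cl$fractions["constrained"]), 1)
  # one OUM gene with one shift among 9 OU1 genes on 10 edges: 1/100 divergent
  fits <- c(replicate(9, mk_fit("OU1"), simplify = FALSE),
            list(mk_fit("OUM", 3L)))
  cl2 <- classify_branches(fits)
  expect_equal(unname(cl2$fractions["divergent"]), 1 / 100)
  expect_equal(sum(cl2$fractions), 1)
  # BM and OU1 genes yield no events
  expect_equal(nrow(change_events(list(mk_fit("BM"), mk_fit("OU1")))), 0L)
})
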