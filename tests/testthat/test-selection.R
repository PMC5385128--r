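test_that("chi-squared tail probabilities match published-style rounding and the integration oracle", {
  # LRT -> p pairs as printed in clade-model comparisons of this kind
  printed <- list(c(5.3, 0.02), c(4.7, 0.03), c(4.1, 0.04), c(2.8, 0.09),
                  c(1.6, 0.2), c(0.7, 0.4))
  for (pp in printed) {
    expect_equal(signif(chisq_pvalue(pp[1], 1), 1), pp[2])
  }
  expect_equal(round(chisq_pvalue(5.3, 1), 2), 0.02)
  expect_equal(round(chisq_pvalue(3.841, 1), 2), 0.05)
  expect_equal(chisq_pvalue(0, 1), 1)
  # numerical-integration oracle over [0, 50]
  for (q in c(0.01, 0.5, 1, 3.841, 10, 25, 50)) {
    expect_equal(chisq_pvalue(q, 1), oracle_chisq_tail(q, 1), tolerance = 1e-10)
  }
  # strictly decreasing in the statistic
  qs <- seq(0, 50, length.out = 101)
  expect_true(all(diff(chisq_pvalue(qs, 1)) < 0))
  # clamping of optimizer noise vs true errors
  expect_equal(chisq_pvalue(-1e-8, 1), 1)
  expect_error(chisq_pvalue(-0.5, 1), "negative LRT")
  expect_error(chisq_pvalue(1, 0), "df")
})

test_that("free-ratio rates satisfy the dN/dS decomposition identities", {
  tr <- read_labeled_tree("(((A:0.15,B:0.15):0.08,C:0.2):0.05,(D:0.15,E:0.15):0.08,F:0.25);")
  sim <- simulate_alignment(sim_spec(tr, "M0", list(kappa = 2, omega = 1),
                                     400, seed = 11))
  br <- free_ratio(sim$alignment, tr, control = list(factr = 1e9))
  expect_true(attr(br, "converged"))
  # omega_b = dN/dS identically wherever dS > 0
  ok <- br$dS > 0
  expect_true(all(ok))
  expect_lt(max(abs(br$omega[ok] - br$dN[ok] / br$dS[ok])), 1e-10)
  # neutral simulation: per-branch omega estimates scatter around 1
  expect_gte(median(br$omega), 0.6)
  expect_lte(median(br$omega), 1.5)
})

test_that("identical sequences yield zero substitution estimates on every branch", {
  tr <- read_labeled_tree("((A:0.1,B:0.1):0.05,C:0.1,D:0.1);")
  aln <- codon_alignment(matrix(rep(c("ATG", "CCA", "AAG", "GGT"), each = 4), 4, 4,
                                dimnames = list(c("A", "B", "C", "D"), NULL)))
  br <- free_ratio(aln, tr, freq = "equal")
  expect_lt(max(br$dN), 1e-6)
  expect_lt(max(br$dS), 1e-6)
})

test_that("the branch-site test detects strong foreground selection", {
  tr <- read_labeled_tree(codonsel:::study_tree_newick())
  hits <- 0L
  for (r in 1:4) {
    sim <- simulate_alignment(sim_spec(tr, "bsA",
      list(kappa = 2, omega0 = 0.05, p0 = 0.8, p1 = 0.1, omega2 = 5),
      600, seed = 1000 + r))
    bs <- branch_site_test(sim$alignment, tr, restarts = 0, seed = r,
                           control = list(factr = 1e9))
    expect_gte(bs$lnL_alt, bs$lnL_null - 1e-6)  # nesting on every input
    expect_gte(bs$alt$theta$omega2, 1)          # alternative box constraint
    hits <- hits + (bs$p < 0.05)
  }
  expect_gte(hits, 3L)
  expect_error(branch_site_test(toy4_alignment(10), toy4_tree()),
               "foreground")
})

test_that("empirical-Bayes posteriors match hand-computed Bayes ratios", {
  tr <- toy4_tree(fg = c(rep(FALSE, 4), TRUE))
  sim <- simulate_alignment(sim_spec(tr, "M2a_rel",
    list(kappa = 2, omega0 = 0.1, p0 = 0.6, p1 = 0.2, omega2 = 1.5),
    50, seed = 14))
  fit <- fit_codon_model(sim$alignment, tr, "M2a_rel", restarts = 1,
                         control = list(factr = 1e9))
  post <- site_class_posteriors(fit, "neb")
  # by hand from the cached per-class site likelihoods at the MLEs
  lik <- exp(fit$site_loglik)[fit$pat_id, , drop = FALSE]
  byhand <- sweep(lik, 2, fit$class_props, "*")
  byhand <- byhand / rowSums(byhand)
  expect_equal(post$class0, byhand[, 1], tolerance = 1e-12)
  expect_equal(post$class2, byhand[, 3], tolerance = 1e-12)
  expect_equal(post$selected, byhand[, 3], tolerance = 1e-12)
  # posteriors are proper
  expect_equal(post$class0 + post$class1 + post$class2, rep(1, 50),
               tolerance = 1e-12)
  # single-class model: posterior 1 everywhere
  m0 <- fit_codon_model(sim$alignment, tr, "M0", restarts = 1)
  expect_true(all(site_class_posteriors(m0)$selected == 1))
  # raising the flag threshold never adds flagged sites
  f75 <- site_class_posteriors(fit, "neb", threshold = 0.75)
  f90 <- site_class_posteriors(fit, "neb", threshold = 0.9)
  expect_true(all(f90$site[f90$flagged] %in% f75$site[f75$flagged]))
  # grid-averaged posteriors stay proper and correlate with NEB
  beb <- site_class_posteriors(fit, "beb")
  expect_true(all(beb$selected >= 0 & beb$selected <= 1))
  expect_gt(cor(beb$selected, post$selected), 0.8)
})

test_that("site-wise omega behaves per site", {
  tr <- toy4_tree()
  sim <- simulate_alignment(sim_spec(tr, "M0", list(kappa = 2, omega = 5),
                                     40, seed = 23))
  m0 <- fit_codon_model(sim$alignment, tr, "M0", restarts = 1)
  sw <- sitewise_omega(sim$alignment, tr, m0)
  expect_equal(nrow(sw), 40L)
  # positively selected simulation: most variable sites pull above 1
  expect_gt(mean(sw$omega > 1), 0.5)
  # invariant sites go to the lower bound with an LRT against neutrality
  aln2 <- codon_alignment(rbind(A = c("ATG", "ATG"), B = c("ATG", "ATG"),
                                C = c("ATG", "ATG"), D = c("ATG", "ATG")))
  m02 <- fit_codon_model(aln2, tr, "M0", restarts = 1, freq = "equal",
                         branch_lengths = "fixed")
  sw2 <- sitewise_omega(aln2, tr, m02)
  expect_lt(sw2$omega[1], 0.01)
  expect_true(all(is.finite(sw2$lrt)))
  # duplicating a site leaves its estimate unchanged
  aln3 <- codon_alignment(sim$alignment$codons[, c(1, 1, 2)])
  sw3 <- sitewise_omega(aln3, tr, m0)
  expect_equal(sw3$omega[1], sw3$omega[2])
  sw_orig <- sw$omega[1]
  expect_equal(sw3$omega[1], sw_orig, tolerance = 1e-6)
})

test_that("clade-model flags enrich for truly divergent sites and reports round-trip", {
  sim <- simulate_alignment(make_study_like_fixture("cmc-divergent"))
  cm <- clade_model_test(sim$alignment, sim$tree, gene = "toygene",
                         restarts = 0, seed = 2, control = list(factr = 1e9))
  expect_gte(cm$lnL_alt, cm$lnL_null - 1e-6)
  flagged <- cm$posterior$flagged
  truth <- sim$truth$class == 3
  # flagged sites are enriched for the divergent class relative to chance
  expect_gt(mean(truth[flagged]), mean(truth))
  f <- withr::local_tempfile()
  df <- write_test_report(list(cm), f, p_adjust = TRUE)
  back <- read.delim(f)
  expect_identical(names(back)[1:9],
                   c("gene", "model_alt", "model_null", "lnL_alt", "lnL_null",
                     "LRT", "df", "p", "significant"))
  expect_equal(back$LRT, cm$lrt, tolerance = 1e-9)
  expect_equal(back$p_BH, df$p_BH)
  f2 <- withr::local_tempfile()
  write_site_posteriors(cm, f2)
  ps <- read.delim(f2)
  expect_equal(nrow(ps), 600L)
})
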