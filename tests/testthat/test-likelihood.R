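test_that("degenerate trees reduce to equilibrium frequencies", {
  fr <- uniform_freqs()
  tr1 <- read_labeled_tree("(A:0.1);")
  a1 <- codon_alignment(matrix("AAA", 1, 1, dimnames = list("A", NULL)))
  expect_equal(site_likelihoods(a1, tr1, 2, 0.5, freq = fr),
               unname(fr["AAA"]), tolerance = 1e-12)
  # two identical leaves joined by zero-length branches
  tr2 <- read_labeled_tree("(A:0,B:0);")
  a2 <- codon_alignment(matrix("ACG", 2, 1, dimnames = list(c("A", "B"), NULL)))
  expect_equal(site_likelihoods(a2, tr2, 2, 0.5, freq = fr),
               unname(fr["ACG"]), tolerance = 1e-12)
})

test_that("pruning equals the brute-force enumeration oracle on 4-taxon trees", {
  tr <- toy4_tree()
  aln <- toy4_alignment(6, seed = 31)
  # add one column with a missing state to exercise marginalization
  codons <- cbind(aln$codons, c("NNN", "ACG", "ACG", "ACT"))
  aln <- codon_alignment(codons)
  fr <- codon_frequencies(aln, "F3x4")
  lik <- site_likelihoods(aln, tr, kappa = 1.8, omega = 0.6, freq = fr)
  for (s in seq_len(ncol(codons))) {
    expect_equal(lik[s],
                 oracle_site_lik(aln, tr, s, kappa = 1.8, omega = 0.6, fr),
                 tolerance = 1e-10)
  }
})

test_that("mixture likelihood identities hold", {
  tr <- read_labeled_tree("(((A:0.15 #1,B:0.2):0.1,C:0.2):0.05,(D:0.2,E:0.15):0.1,F:0.3);")
  sim <- simulate_alignment(sim_spec(tr, "CmC",
    list(kappa = 2, omega0 = 0.1, p0 = 0.7, p1 = 0.1, omega2 = 0.4, omega3 = 2),
    120, seed = 8))
  aln <- sim$alignment
  # degenerate mixture: single class with p = 1 equals the plain model
  lm <- mixture_loglik(aln, tr, "M2a_rel",
                       list(kappa = 2, omega0 = 0.3, p0 = 1 - 2e-9, p1 = 1e-9,
                            omega2 = 0.3))
  l0 <- mixture_loglik(aln, tr, "M0", list(kappa = 2, omega = 0.3))
  expect_equal(lm, l0, tolerance = 1e-6)
  # nesting identity: CmC with omega3 = omega2 is exactly M2a_rel
  base <- list(kappa = 2.2, omega0 = 0.08, p0 = 0.8, p1 = 0.05, omega2 = 0.9)
  expect_equal(mixture_loglik(aln, tr, "CmC", c(base, list(omega3 = 0.9))),
               mixture_loglik(aln, tr, "M2a_rel", base), tolerance = 1e-10)
  # root-placement invariance for the full mixture
  th <- list(kappa = 2, omega0 = 0.1, p0 = 0.7, p1 = 0.1, omega2 = 0.4,
             omega3 = 2)
  l_tree <- mixture_loglik(aln, tr, "CmC", th)
  for (node in c("C", "F")) {
    rr <- reroot_tree(tr, node)
    expect_equal(mixture_loglik(aln, rr, "CmC", th), l_tree, tolerance = 1e-8)
  }
  # invariance to taxon order and site order
  perm <- aln$codons[rev(rownames(aln$codons)), sample(ncol(aln$codons))]
  expect_equal(mixture_loglik(codon_alignment(perm), tr, "CmC", th), l_tree,
               tolerance = 1e-9)
})

test_that("M0 fitting recovers the generating omega", {
  tr <- read_labeled_tree(codonsel:::study_tree_newick())
  sim <- simulate_alignment(sim_spec(tr, "M0", list(kappa = 2, omega = 0.2),
                                     1000, seed = 12))
  fit <- fit_codon_model(sim$alignment, tr, "M0", restarts = 1,
                         control = list(factr = 1e4))
  expect_true(fit$converged)
  expect_lt(abs(fit$theta$omega - 0.2), 0.05)
  expect_lt(abs(fit$theta$kappa - 2), 0.5)
  # refitting from the returned optimum barely moves the likelihood
  fit2 <- fit_codon_model(sim$alignment, tr, "M0", restarts = 0,
                          init = fit$theta, control = list(factr = 1e4))
  expect_lt(abs(fit2$logLik - fit$logLik), 1e-6)
  # clamping a free parameter away from its MLE can only lower the likelihood
  th_clamped <- fit$theta
  th_clamped$omega <- fit$theta$omega * 1.5
  tr_fit <- fit$tree
  expect_lt(mixture_loglik(sim$alignment, tr_fit, "M0", th_clamped),
            fit$logLik + 1e-8)
})

test_that("M2a_rel fitting recovers proportions and class omegas", {
  tr <- read_labeled_tree(codonsel:::study_tree_newick())
  pars <- list(kappa = 2, omega0 = 0.05, p0 = 0.75, p1 = 0.05, omega2 = 0.5)
  sim <- simulate_alignment(sim_spec(tr, "M2a_rel", pars, 1000, seed = 21))
  fit <- fit_codon_model(sim$alignment, tr, "M2a_rel", restarts = 2,
                         control = list(factr = 1e9))
  expect_true(fit$converged)
  expect_lt(abs(fit$theta$omega0 - 0.05), 0.05)
  expect_lt(abs(fit$theta$p0 - 0.75), 0.15)
  expect_lt(abs(fit$theta$omega2 - 0.5), 0.35)
})

test_that("fit serialization round-trips", {
  tr <- toy4_tree()
  aln <- toy4_alignment(40, seed = 3)
  fit <- fit_codon_model(aln, tr, "M0", restarts = 1)
  f <- withr::local_tempfile()
  write_fit_report(fit, f)
  rt <- read_fit_report(f)
  expect_identical(rt$model, "M0")
  expect_identical(rt$lnL, fit$logLik)
  expect_equal(rt$param[["kappa"]], fit$theta$kappa)
})
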