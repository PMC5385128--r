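test_that("simulation is deterministic in the seed", {
  sp <- make_study_like_fixture("m0-purifying", n_sites = 60)
  a <- simulate_alignment(sp)
  b <- simulate_alignment(sp)
  expect_identical(a$alignment$codons, b$alignment$codons)
  expect_identical(a$truth, b$truth)
  sp2 <- make_study_like_fixture("m0-purifying", n_sites = 60, seed = 999)
  expect_false(identical(simulate_alignment(sp2)$alignment$codons,
                         a$alignment$codons))
})

test_that("a long branch equilibrates tip codon frequencies to pi", {
  # 50,000 sites keep the multinomial sampling noise (expected total
  # variation ~ sqrt(61 / (2 pi n))) well below the 0.02 acceptance band
  tr <- read_labeled_tree("(A:25,B:25);")
  sp <- sim_spec(tr, "M0", list(kappa = 2, omega = 0.8), 50000, seed = 6)
  sim <- simulate_alignment(sp)
  gc <- codonsel:::genetic_code("1")
  obs <- table(factor(sim$alignment$codons["A", ], levels = gc$codons))
  tv <- 0.5 * sum(abs(obs / sum(obs) - sp$freqs))
  expect_lt(tv, 0.02)
})

test_that("omega = 0 permits only synonymous change", {
  tr <- read_labeled_tree("((A:0.5,B:0.5):0.2,C:0.5,D:0.5);")
  sp <- sim_spec(tr, "M0", list(kappa = 2, omega = 0), 300, seed = 9)
  sim <- simulate_alignment(sp)
  gc <- codonsel:::genetic_code("1")
  root_aa <- unname(gc$aa[sim$truth$root])
  for (id in rownames(sim$alignment$codons)) {
    tip_aa <- unname(gc$aa[sim$alignment$codons[id, ]])
    expect_identical(tip_aa, root_aa)
  }
  # and substitutions did happen at the nucleotide level
  expect_false(identical(sim$alignment$codons["A", ], sim$truth$root))
})

test_that("truth-record class proportions converge to the mixture weights", {
  tr <- read_labeled_tree(codonsel:::study_tree_newick())
  pars <- list(kappa = 2, omega0 = 0.05, p0 = 0.75, p1 = 0.05, omega2 = 0.1,
               omega3 = 3)
  sp <- sim_spec(tr, "CmC", pars, 10000, seed = 13)
  sim <- simulate_alignment(sp)
  props <- tabulate(sim$truth$class, 3) / 10000
  expect_lt(max(abs(props - c(0.75, 0.05, 0.20))), 0.02)
  # ancestral states recorded for every node
  expect_false(anyNA(sim$truth$states))
})

test_that("study presets encode the intended regimes", {
  m0 <- make_study_like_fixture("m0-purifying")
  expect_identical(m0$model, "M0")
  expect_equal(m0$params$omega, 0.05)
  cmc <- make_study_like_fixture("cmc-divergent")
  p2 <- 1 - cmc$params$p0 - cmc$params$p1
  expect_gte(p2, 0.05); expect_lte(p2, 0.2)
  expect_lt(cmc$params$omega2, 1)   # background purifying
  expect_gt(cmc$params$omega3, 1)   # foreground elevated
  expect_equal(sum(make_study_like_fixture("m2arel-null")$tree$foreground), 1L)
  expect_error(make_study_like_fixture("nope"))
})

test_that("gap masking and fit-based simulation work", {
  sp <- make_study_like_fixture("m0-purifying", n_sites = 80)
  sp$mask_rate <- 0.1
  sim <- simulate_alignment(sp)
  gapped <- mean(sim$alignment$codons == "---")
  expect_gt(gapped, 0.05); expect_lt(gapped, 0.15)
  # simulate() method of a fitted model
  tr <- toy4_tree()
  fit <- fit_codon_model(toy4_alignment(50, seed = 2), tr, "M0", restarts = 1)
  re <- simulate(fit, nsim = 1, seed = 4, n_sites = 30)
  expect_s3_class(re$alignment, "codon_alignment")
  expect_equal(ncol(re$alignment$codons), 30L)
  # disk round trip of a simulation bundle
  pre <- withr::local_tempfile()
  write_simulation(sim, pre)
  expect_true(file.exists(paste0(pre, ".fasta")))
  tru <- read.delim(paste0(pre, "_truth.tsv"))
  expect_equal(nrow(tru), 80L)
})
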