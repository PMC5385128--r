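test_that("rate matrix obeys the Goldman-Yang structure", {
  fr <- uniform_freqs()
  # omega = 0 silences all nonsynonymous rates
  Q0 <- codon_rate_matrix(2, 0, fr)
  st <- codonsel:::codon_pair_structure("1")
  expect_true(all(Q0$Q[st$nonsyn] == 0))
  expect_true(any(Q0$Q[st$neighbor & !st$nonsyn] > 0))
  # rows sum to zero and the matrix is scaled to unit expected rate
  Q <- codon_rate_matrix(1.7, 0.4, fr)
  expect_lt(max(abs(rowSums(Q$Q))), 1e-12)
  expect_equal(-sum(fr * diag(Q$Q)), 1, tolerance = 1e-12)
  # detailed balance (time reversibility)
  F <- fr * Q$Q
  expect_lt(max(abs(F - t(F))), 1e-15)
  # multi-step and stop-codon changes are forbidden
  expect_true(all(Q$Q[!st$neighbor & row(Q$Q) != col(Q$Q)] == 0))
})

test_that("kappa = omega = 1 with uniform frequencies gives equal single-step rates", {
  fr <- uniform_freqs()
  Q <- codon_rate_matrix(1, 1, fr)
  # independent neighbor enumeration by explicit string comparison
  gc <- codonsel:::genetic_code("1")
  cods <- gc$codons
  nb <- outer(cods, cods, function(a, b) {
    mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) == 1L,
           a, b)
  })
  offdiag <- Q$Q[nb]
  expect_equal(length(offdiag), sum(nb))
  expect_lt(diff(range(offdiag)), 1e-14)
  expect_true(all(Q$Q[!nb & row(Q$Q) != col(Q$Q)] == 0))
})

test_that("transition probabilities behave like a reversible Markov semigroup", {
  fr <- uniform_freqs()
  Q <- codon_rate_matrix(2, 0.3, fr)
  expect_equal(transition_prob(Q, 0), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transition_prob(Q, 0.2)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= 0))
  # semigroup property P(t1 + t2) = P(t1) P(t2)
  expect_lt(max(abs(transition_prob(Q, 0.2) -
                      transition_prob(Q, 0.07) %*% transition_prob(Q, 0.13))),
            1e-9)
  # ergodic limit: every row converges to pi
  expect_lt(max(abs(sweep(transition_prob(Q, 100), 2, Q$pi))), 1e-6)
  # stationarity pi P(t) = pi
  for (t in c(0.05, 0.5, 3)) {
    expect_lt(max(abs(Q$pi %*% transition_prob(Q, t) - Q$pi)), 1e-12)
  }
  expect_error(transition_prob(Q, -0.1), "negative")
})

test_that("eigen-based matrix exponential agrees with a generic method", {
  aln <- toy4_alignment(20, seed = 9)
  fr <- codon_frequencies(aln, "F3x4")
  Q <- codon_rate_matrix(2.5, 0.15, fr)
  for (t in c(0.01, 0.3, 2)) {
    expect_lt(max(abs(transition_prob(Q, t) - expm_prob(Q$Q, t))), 1e-9)
  }
})

test_that("nonsynonymous flux increases strictly with omega before rescaling", {
  fr <- uniform_freqs()
  raw_ns <- vapply(c(0, 0.1, 0.5, 1, 2, 5), function(w) {
    Qo <- codon_rate_matrix(2, max(w, 1e-12), fr)
    Qo$rho_ns * Qo$rate  # unscaled nonsynonymous flux
  }, numeric(1))
  expect_true(all(diff(raw_ns) > 0))
})

test_that("frequency schemes match their definitions", {
  gc <- codonsel:::genetic_code("1")
  aln <- codon_alignment(rbind(A = "AAA", B = "AAA", C = "AAA"))
  eq <- codon_frequencies(aln, "equal")
  expect_equal(unname(eq), rep(1 / 61, 61))
  emp <- codon_frequencies(aln, "empirical")
  expect_equal(unname(emp["AAA"]), 1, tolerance = 1e-9)
  # F3x4 on a 3-sequence, 5-codon toy against a by-hand computation
  rows <- rbind(A = c("ATG", "CCA", "GGT", "ACA", "TTT"),
                B = c("ATG", "CCA", "GGC", "ACA", "TTC"),
                C = c("ATG", "CGA", "GGT", "GCA", "TAT"))
  aln2 <- codon_alignment(rows)
  f <- codon_frequencies(aln2, "F3x4")
  nt <- c("A", "C", "G", "T")
  pos <- sapply(1:3, function(p) {
    col <- substr(as.vector(rows), p, p)
    as.numeric(table(factor(col, levels = nt))) / length(col)
  })
  rownames(pos) <- nt
  by_hand <- vapply(gc$codons, function(cd) {
    prod(pos[cbind(match(strsplit(cd, "")[[1]], nt), 1:3)])
  }, numeric(1))
  by_hand <- by_hand / sum(by_hand)
  expect_equal(unname(f), unname(by_hand), tolerance = 1e-12)
  # F1x4 pools positions
  f1 <- codon_frequencies(aln2, "F1x4")
  pool <- as.numeric(table(factor(unlist(strsplit(as.vector(rows), "")), levels = nt)))
  pool <- pool / sum(pool)
  names(pool) <- nt
  bh1 <- vapply(gc$codons, function(cd) prod(pool[strsplit(cd, "")[[1]]]), numeric(1))
  expect_equal(unname(f1), unname(bh1 / sum(bh1)), tolerance = 1e-12)
  expect_error(codon_frequencies(codon_alignment(matrix(character(0), 0, 0)), "F3x4"),
               "empty")
})
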