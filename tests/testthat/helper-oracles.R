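# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/eigen code paths: transition probabilities come from
# Matrix::expm and likelihoods from explicit enumeration over internal-node
# state assignments.

uniform_freqs <- function() {
  gc <- codonsel:::genetic_code("1")
  stats::setNames(rep(1 / length(gc$codons), length(gc$codons)), gc$codons)
}

# P(t) by generic matrix exponential (independent of the eigen route)
expm_prob <- function(Q, t) {
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Brute-force single-class site likelihood: sum over all assignments of
# states to internal nodes of pi[root] * prod_edges P_e[parent, child].
oracle_site_lik <- function(aln, tree, site, kappa, omega, freqs) {
  Qo <- codon_rate_matrix(kappa, omega, freqs)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  ns <- length(freqs)
  states <- codonsel:::codon_states(aln)[phy$tip.label, site]
  P <- lapply(seq_len(nrow(phy$edge)), function(e)
    expm_prob(Qo$Q, phy$edge.length[e]))
  internal <- ntip + seq_len(nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nnode)))
  node_state <- function(n, assign_row) {
    if (n <= ntip) states[n] else assign_row[n - ntip]
  }
  total <- 0
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    w <- freqs[a[1]]  # root is ntip + 1, first internal
    for (e in seq_len(nrow(phy$edge))) {
      sp <- node_state(phy$edge[e, 1], a)
      sc <- node_state(phy$edge[e, 2], a)
      if (is.na(sc)) next  # unknown tip marginalizes to 1
      w <- w * P[[e]][sp, sc]
      if (w == 0) break
    }
    total <- total + w
  }
  unname(total)
}

# Brute-force marginal posterior at an internal node, same enumeration
oracle_node_posterior <- function(aln, tree, site, node, kappa, omega, freqs) {
  Qo <- codon_rate_matrix(kappa, omega, freqs)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  ns <- length(freqs)
  states <- codonsel:::codon_states(aln)[phy$tip.label, site]
  P <- lapply(seq_len(nrow(phy$edge)), function(e)
    expm_prob(Qo$Q, phy$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), phy$Nnode)))
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    v <- freqs[a[1]]
    for (e in seq_len(nrow(phy$edge))) {
      sp <- if (phy$edge[e, 1] <= ntip) states[phy$edge[e, 1]] else a[phy$edge[e, 1] - ntip]
      sc <- if (phy$edge[e, 2] <= ntip) states[phy$edge[e, 2]] else a[phy$edge[e, 2] - ntip]
      if (is.na(sc)) next
      v <- v * P[[e]][sp, sc]
      if (v == 0) break
    }
    w[r] <- v
  }
  post <- tapply(w, grid[, node - ntip], sum)
  out <- numeric(ns)
  out[as.integer(names(post))] <- post
  out / sum(out)
}

# chi-squared upper tail by numerical integration of the density
oracle_chisq_tail <- function(q, df) {
  stats::integrate(function(x) stats::dchisq(x, df), q, Inf,
                   rel.tol = 1e-12)$value
}

# small unrooted 4-taxon fixture tree used by the enumeration checks
toy4_tree <- function(fg = NULL) {
  tr <- read_labeled_tree("((A:0.15,B:0.25):0.1,C:0.2,D:0.35);")
  if (!is.null(fg)) tr <- labeled_tree(tr$phylo, foreground = fg)
  tr
}

toy4_alignment <- function(n_sites = 12, seed = 42, omega = 0.5) {
  sim <- simulate_alignment(sim_spec(toy4_tree(), "M0",
                                     list(kappa = 2, omega = omega),
                                     n_sites, seed = seed))
  sim$alignment
}
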