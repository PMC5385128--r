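#' Specify a codon-alignment simulation
#'
#' @param tree A `labeled_tree` (branch lengths in expected substitutions
#'   per codon; foreground labels used by two-partition models).
#' @param model Site-class model name (see [fit_codon_model()]); free-ratio
#'   simulation is not supported.
#' @param params Named list of model parameters (as in [mixture_loglik()]).
#' @param n_sites Number of codon sites (>= 1).
#' @param seed Random seed; the generator stream is consumed in a fixed,
#'   documented order (site classes, then root states, then branches
#'   parent-first), so equal specs give byte-identical alignments.
#' @param freq `"equal"` or a numeric frequency vector over sense codons.
#' @param code Genetic-code id.
#' @param mask_rate Optional proportion of tip codons replaced by gaps, to
#'   exercise missing-data handling (indels are not simulated).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(tree, model, params, n_sites, seed = 1L, freq = "equal",
                     code = "1", mask_rate = 0) {
  model <- match.arg(model, setdiff(MODELS, "free_ratio"))
  if (n_sites < 1) stop("n_sites must be >= 1")
  validate_theta(model, params)
  gc <- genetic_code(code)
  freqs <- if (is.numeric(freq)) freq else
    setNames(rep(1 / length(gc$codons), length(gc$codons)), gc$codons)
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  stopifnot(mask_rate >= 0, mask_rate < 1)
  structure(list(tree = tree, model = model, params = params,
                 n_sites = as.integer(n_sites), seed = as.integer(seed),
                 freqs = freqs, code = code, mask_rate = mask_rate),
            class = "sim_spec")
}

#' Simulate a codon alignment under a site-class model
#'
#' Each site draws a class from the class proportions; the root codon is
#' drawn from the equilibrium frequencies; states then evolve down the tree
#' with the class- and partition-appropriate transition matrices. The truth
#' record stores the per-site class and all ancestral states.
#'
#' @param spec A [sim_spec()].
#' @return List: `alignment` (a `codon_alignment`), `truth` (list with
#'   `class` per site, `root` codons, `states` node x site matrix of codon
#'   indices), `tree`, `spec`.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  gc <- genetic_code(spec$code)
  ns <- length(gc$codons)
  phy <- spec$tree$phylo
  ntip <- length(phy$tip.label)
  nnode_total <- ntip + phy$Nnode
  n <- spec$n_sites
  cls <- model_classes(spec$model, spec$params)
  K <- length(cls$props)
  site_class <- sample.int(K, n, replace = TRUE, prob = cls$props)
  root <- ntip + 1L
  states <- matrix(NA_integer_, nnode_total, n)
  states[root, ] <- sample.int(ns, n, replace = TRUE, prob = spec$freqs)
  # transition matrices per (class, edge); branch lengths are substitutions
  # per codon averaged over site classes, so class k evolves at relative
  # rate rate(omega_k)/mu within its branch partition
  uo <- unique(c(cls$wbg, cls$wfg))
  decs <- lapply(uo, function(w)
    codon_rate_matrix(spec$params$kappa, w, spec$freqs, spec$code))
  fc <- flux_constants(spec$freqs, spec$code)
  r_bg <- vapply(cls$wbg, function(w) raw_flux(fc, spec$params$kappa, w), 1)
  r_fg <- vapply(cls$wfg, function(w) raw_flux(fc, spec$params$kappa, w), 1)
  mu_bg <- sum(cls$props * r_bg)
  mu_fg <- sum(cls$props * r_fg)
  edge <- phy$edge  # cladewise: parents precede children
  fg <- spec$tree$foreground
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    for (k in seq_len(K)) {
      idx <- which(site_class == k)
      if (!length(idx)) next
      w <- if (fg[e]) cls$wfg[k] else cls$wbg[k]
      rel <- if (fg[e]) r_fg[k] / mu_fg else r_bg[k] / mu_bg
      P <- transition_prob(decs[[match(w, uo)]], phy$edge.length[e] * rel)
      for (s in seq_len(ns)) {
        at <- idx[states[par, idx] == s]
        if (length(at))
          states[ch, at] <- sample.int(ns, length(at), replace = TRUE,
                                       prob = P[s, ])
      }
    }
  }
  codons <- matrix(gc$codons[states[seq_len(ntip), , drop = FALSE]],
                   nrow = ntip, dimnames = list(phy$tip.label, NULL))
  if (spec$mask_rate > 0) {
    mask <- runif(length(codons)) < spec$mask_rate
    codons[mask] <- GAP_CODON
  }
  list(alignment = codon_alignment(codons, code = spec$code),
       truth = list(class = site_class,
                    root = gc$codons[states[root, ]],
                    states = states),
       tree = spec$tree, spec = spec)
}

#' Study-regime simulation presets
#'
#' Fully concrete simulation specs emulating the data regime of comparative
#' mammalian vision-gene analyses: 8 taxa, one foreground tip, mostly
#' strongly purifying sites (omega around 0.05 on 75-95 percent of sites)
#' with a small neutral class and a small selected or divergent class.
#'
#' @param preset One of `"m0-purifying"`, `"m2arel-null"`, `"cmc-divergent"`,
#'   `"branchsite-positive"`.
#' @param n_sites,seed Override the preset's alignment length and seed.
#' @return A [sim_spec()].
#' @export
make_study_like_fixture <- function(preset = c("m0-purifying", "m2arel-null",
                                               "cmc-divergent",
                                               "branchsite-positive"),
                                    n_sites = NULL, seed = NULL) {
  preset <- match.arg(preset)
  tree <- read_labeled_tree(study_tree_newick())
  p <- switch(preset,
    "m0-purifying" = list(model = "M0",
                          params = list(kappa = 2, omega = 0.05),
                          n_sites = 600, seed = 101L),
    "m2arel-null" = list(model = "M2a_rel",
                         params = list(kappa = 2, omega0 = 0.05, p0 = 0.75,
                                       p1 = 0.05, omega2 = 0.5),
                         n_sites = 600, seed = 202L),
    "cmc-divergent" = list(model = "CmC",
                           params = list(kappa = 2, omega0 = 0.05, p0 = 0.75,
                                         p1 = 0.05, omega2 = 0.1, omega3 = 3),
                           n_sites = 600, seed = 303L),
    "branchsite-positive" = list(model = "bsA",
                                 params = list(kappa = 2, omega0 = 0.05,
                                               p0 = 0.8, p1 = 0.1, omega2 = 5),
                                 n_sites = 600, seed = 404L))
  sim_spec(tree, p$model, p$params,
           n_sites = n_sites %||% p$n_sites, seed = seed %||% p$seed)
}

# the documented 8-taxon fixture tree: one foreground tip on a deeper
# terminal branch (0.20 expected substitutions per codon, enough sequence
# divergence for branch-wise inference), total length ~1.2
study_tree_newick <- function() {
  paste0("((((fg:0.20 #1,t2:0.08):0.05,t3:0.10):0.05,",
         "(t4:0.08,t5:0.08):0.06):0.04,t6:0.10,(t7:0.07,t8:0.07):0.05);")
}

#' Simulate alignments from a fitted codon model
#'
#' @param object A `codon_fit`.
#' @param nsim Number of alignments.
#' @param seed Base seed (replicate i uses `seed + i - 1`).
#' @param n_sites Number of codon sites (defaults to the fitted alignment's).
#' @param ... Unused.
#' @return A list of simulation results (see [simulate_alignment()]); a
#'   single result if `nsim = 1`.
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = 1L, n_sites = NULL, ...) {
  if (object$model == "free_ratio")
    stop("simulation under the free-ratio model is not supported")
  n <- n_sites %||% object$engine$nsites
  out <- lapply(seq_len(nsim), function(i) {
    sp <- sim_spec(object$tree, object$model, object$theta, n,
                   seed = seed + i - 1L, freq = object$freqs,
                   code = object$code)
    simulate_alignment(sp)
  })
  if (nsim == 1) out[[1]] else out
}

#' Write a simulation to disk
#'
#' Writes the alignment as FASTA, the truth record as TSV (site, class,
#' root codon) and the tree as Newick.
#'
#' @param sim Result of [simulate_alignment()].
#' @param prefix Output path prefix.
#' @export
write_simulation <- function(sim, prefix) {
  write_fasta(sim$alignment, paste0(prefix, ".fasta"))
  write.table(data.frame(site = seq_along(sim$truth$class),
                         class = sim$truth$class - 1L,
                         root_codon = sim$truth$root),
              paste0(prefix, "_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_labeled_tree(sim$tree, paste0(prefix, ".nwk"))
  invisible(prefix)
}
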