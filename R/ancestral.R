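#' Marginal ancestral codon reconstruction
#'
#' Posterior distribution over codon states at an internal node given the
#' tip data and a fitted model, computed by the standard inside-outside
#' (down/up) passes under each site class and averaged over classes with
#' their posterior weights. At a leaf with an observed codon the posterior
#' is a point mass on that codon.
#'
#' @param fit A converged `codon_fit`.
#' @param node Node id in `fit$tree$phylo` numbering, or a tip label.
#' @param sites Codon sites to reconstruct (default all).
#' @return An object of class `ancestral_codon`: `posterior` (sites x
#'   sense-codons matrix), `map` (MAP codon per site), `map_aa` (its
#'   translation), `map_prob`.
#' @export
ancestral_reconstruct <- function(fit, node, sites = NULL) {
  if (!inherits(fit, "codon_fit")) stop("fit must be a codon_fit")
  if (!fit$converged) warning("fit did not converge; posteriors may be unreliable")
  eng <- fit$engine
  phy <- fit$tree$phylo
  gc <- genetic_code(fit$code)
  ns <- length(gc$codons)
  if (is.character(node)) {
    nd <- match(node, phy$tip.label)
    if (is.na(nd)) stop("unknown node: ", node)
    node <- nd
  }
  if (node < 1 || node > eng$nnode_total) stop("unknown node: ", node)
  if (is.null(sites)) sites <- seq_len(eng$nsites)
  pats <- eng$pat_id[sites]
  upat <- sort(unique(pats))
  S <- length(upat)
  tip <- eng$tip[, upat, drop = FALSE]
  t_fit <- fit$tree$phylo$edge.length[eng$orig_index]
  pi <- fit$freqs
  edge <- eng$edge
  nedge <- nrow(edge)
  root <- edge[nedge, 1]

  if (fit$model == "free_ratio") {
    props <- 1
    omega_edge <- matrix(fit$theta$omegas, ncol = 1)
    rel_edge <- matrix(1, nedge, 1)
  } else {
    cls <- model_classes(fit$model, fit$theta)
    props <- cls$props
    fc <- flux_constants(pi, fit$code)
    r_bg <- vapply(cls$wbg, function(w) raw_flux(fc, fit$theta$kappa, w), 1)
    r_fg <- vapply(cls$wfg, function(w) raw_flux(fc, fit$theta$kappa, w), 1)
    mu_bg <- sum(props * r_bg)
    mu_fg <- sum(props * r_fg)
    omega_edge <- vapply(seq_along(props), function(k)
      ifelse(eng$fg, cls$wfg[k], cls$wbg[k]), numeric(nedge))
    omega_edge <- matrix(omega_edge, nrow = nedge)
    rel_edge <- vapply(seq_along(props), function(k)
      ifelse(eng$fg, r_fg[k] / mu_fg, r_bg[k] / mu_bg), numeric(nedge))
    rel_edge <- matrix(rel_edge, nrow = nedge)
  }
  K <- length(props)

  post_states <- matrix(0, ns, S)
  tot_lik <- rep(0, S)
  children <- split(seq_len(nedge), edge[, 1])

  for (k in seq_len(K)) {
    uo <- unique(omega_edge[, k])
    decs <- lapply(uo, function(w) codon_rate_matrix(fit$theta$kappa, w, pi, fit$code))
    Pk <- lapply(seq_len(nedge), function(e)
      transition_prob(decs[[match(omega_edge[e, k], uo)]],
                      t_fit[e] * rel_edge[e, k]))
    down <- vector("list", eng$nnode_total)
    contrib <- vector("list", nedge)
    for (i in seq_len(eng$ntip)) {
      m <- matrix(0, ns, S)
      st <- tip[i, ]
      m[cbind(st[st > 0], which(st > 0))] <- 1
      m[, st == 0] <- 1
      down[[i]] <- m
    }
    for (e in seq_len(nedge)) {
      ch <- edge[e, 2]
      contrib[[e]] <- Pk[[e]] %*% down[[ch]]
      p <- edge[e, 1]
      down[[p]] <- if (is.null(down[[p]])) contrib[[e]] else down[[p]] * contrib[[e]]
    }
    up <- vector("list", eng$nnode_total)
    up[[root]] <- matrix(pi, ns, S)
    for (e in rev(seq_len(nedge))) {
      u <- edge[e, 1]; v <- edge[e, 2]
      sib <- setdiff(children[[as.character(u)]], e)
      acc <- up[[u]]
      for (e2 in sib) acc <- acc * contrib[[e2]]
      up[[v]] <- crossprod(Pk[[e]], acc)
    }
    B <- down[[node]] * up[[node]]
    Lk <- colSums(down[[root]] * pi)
    post_states <- post_states + props[k] * B
    tot_lik <- tot_lik + props[k] * Lk
  }
  post_states <- sweep(post_states, 2, tot_lik, "/")
  post_states <- sweep(post_states, 2, colSums(post_states), "/")
  out <- t(post_states)[match(pats, upat), , drop = FALSE]
  colnames(out) <- gc$codons
  rownames(out) <- sites
  map_i <- max.col(out)
  structure(list(node = node, sites = sites, posterior = out,
                 map = gc$codons[map_i],
                 map_aa = unname(gc$aa[gc$codons[map_i]]),
                 map_prob = out[cbind(seq_along(sites), map_i)]),
            class = "ancestral_codon")
}

#' @export
print.ancestral_codon <- function(x, ...) {
  cat("Marginal ancestral codon reconstruction at node ", x$node, "\n", sep = "")
  n <- min(length(x$sites), 10L)
  df <- data.frame(site = x$sites[seq_len(n)], codon = x$map[seq_len(n)],
                   aa = x$map_aa[seq_len(n)],
                   posterior = round(x$map_prob[seq_len(n)], 4))
  print(df, row.names = FALSE)
  if (length(x$sites) > n) cat("... (", length(x$sites) - n, " more sites)\n", sep = "")
  invisible(x)
}
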