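MODELS <- c("M0", "M2a_rel", "CmC", "bsA", "bsA_null", "free_ratio")

# unroot a labeled tree (>= 3 tips), carrying foreground labels across by
# unrooted bipartition; reversible-model likelihoods are unchanged and the
# two non-identifiable root-adjacent branch lengths collapse to their sum
unroot_labeled <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (ntip < 3L || !ape::is.rooted(phy)) return(tree)
  fg_keys <- edge_keys_for(tree)[tree$foreground]
  un <- ape::unroot(phy)
  un_tree <- labeled_tree(un, foreground = rep(FALSE, nrow(un$edge)))
  keys <- edge_keys_for(un_tree)
  labeled_tree(un, foreground = keys %in% fg_keys)
}

# precomputed structures for repeated likelihood evaluation: site-pattern
# compression, postorder edge list, integer tip states (0 = unknown)
make_engine <- function(aln, tree, unroot = TRUE) {
  if (!inherits(aln, "codon_alignment")) stop("aln must be a codon_alignment")
  if (!inherits(tree, "labeled_tree")) stop("tree must be a labeled_tree")
  if (unroot) tree <- unroot_labeled(tree)
  phy <- tree$phylo
  states <- codon_states(aln)
  if (!setequal(rownames(states), phy$tip.label))
    stop("alignment ids and tree tip labels differ: ",
         paste(c(setdiff(rownames(states), phy$tip.label),
                 setdiff(phy$tip.label, rownames(states))), collapse = ", "))
  states <- states[phy$tip.label, , drop = FALSE]
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  tip <- states[, first, drop = FALSE]
  tip[is.na(tip)] <- 0L
  post <- ape::reorder.phylo(phy, "postorder")
  idx <- match(paste(post$edge[, 1], post$edge[, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
  list(edge = post$edge, t = post$edge.length,
       fg = tree$foreground[idx], orig_index = idx, tree = tree,
       tip = tip, pat_id = pat_id, weights = tabulate(pat_id, sum(first)),
       npat = sum(first), nsites = ncol(states),
       ntip = length(phy$tip.label),
       nnode_total = length(phy$tip.label) + phy$Nnode,
       code = aln$code)
}

# site-class structure of each model at parameter values th:
# proportions plus per-class background/foreground omega
model_classes <- function(model, th) {
  switch(model,
    M0 = list(props = 1, wbg = th$omega, wfg = th$omega),
    M2a_rel = {
      p <- c(th$p0, th$p1, 1 - th$p0 - th$p1)
      list(props = p, wbg = c(th$omega0, 1, th$omega2),
           wfg = c(th$omega0, 1, th$omega2))
    },
    CmC = {
      p <- c(th$p0, th$p1, 1 - th$p0 - th$p1)
      list(props = p, wbg = c(th$omega0, 1, th$omega2),
           wfg = c(th$omega0, 1, th$omega3))
    },
    bsA = ,
    bsA_null = {
      w2 <- if (model == "bsA_null") 1 else th$omega2
      psel <- 1 - th$p0 - th$p1
      denom <- max(th$p0 + th$p1, 1e-12)
      p <- c(th$p0, th$p1, psel * th$p0 / denom, psel * th$p1 / denom)
      list(props = p, wbg = c(th$omega0, 1, th$omega0, 1),
           wfg = c(th$omega0, 1, w2, w2))
    },
    stop("unknown model: ", model))
}

validate_theta <- function(model, th) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid theta: ", msg)
  chk(th$kappa > 0, "kappa must be > 0")
  if (model == "M0") chk(th$omega >= 0, "omega must be >= 0")
  if (model == "free_ratio") chk(all(th$omegas >= 0), "omegas must be >= 0")
  if (model %in% c("M2a_rel", "CmC", "bsA", "bsA_null")) {
    chk(th$omega0 > 0 && th$omega0 < 1, "omega0 must lie in (0, 1)")
    chk(th$p0 >= 0 && th$p1 >= 0 && th$p0 + th$p1 <= 1, "proportions off simplex")
  }
  if (model %in% c("M2a_rel", "CmC")) chk(th$omega2 > 0, "omega2 must be > 0")
  if (model == "CmC") chk(th$omega3 > 0, "omega3 must be > 0")
  if (model == "bsA") chk(th$omega2 >= 1, "branch-site alternative omega2 must be >= 1")
  invisible(TRUE)
}

# core evaluation: per-pattern per-class log-likelihoods and the mixture lnL.
# `cache` (an environment, one per fit) memoizes rate-matrix decompositions
# by (kappa, omega) and per-class site log-likelihood vectors by
# (kappa, scale, class omegas): quasi-Newton gradient steps perturb one
# parameter at a time, so most classes are unchanged between evaluations
engine_loglik <- function(eng, model, th, freqs, cache = NULL) {
  t_use <- eng$t * (if (is.null(th$scale)) 1 else th$scale)
  if (!is.null(th$t)) t_use <- th$t
  cacheable <- !is.null(cache) && is.null(th$t)
  nedge <- nrow(eng$edge)
  ns <- length(freqs)
  get_dec <- function(w) {
    if (!cacheable)
      return(codon_rate_matrix(th$kappa, w, freqs, eng$code))
    key <- paste0("d", format(th$kappa, digits = 15), "_", format(w, digits = 15))
    d <- cache[[key]]
    if (is.null(d)) {
      d <- codon_rate_matrix(th$kappa, w, freqs, eng$code)
      cache[[key]] <- d
    }
    d
  }
  scale_key <- format(th$scale %||% 1, digits = 15)
  # branch lengths are substitutions per codon averaged over site classes:
  # class k on a branch of partition part evolves at relative rate
  # rate(omega_k, part) / mu_part with mu_part the proportion-weighted mean
  class_ll <- function(wbg, wfg, rel_bg, rel_fg) {
    key <- paste0("c", format(th$kappa, digits = 15), "_", scale_key, "_",
                  format(wbg, digits = 15), "_", format(wfg, digits = 15), "_",
                  format(rel_bg, digits = 15), "_", format(rel_fg, digits = 15))
    if (cacheable && !is.null(cache[[key]])) return(cache[[key]])
    uo <- unique(c(wbg, wfg))
    decs <- lapply(uo, get_dec)
    P <- array(0, c(ns, ns, nedge))
    for (e in seq_len(nedge)) {
      wi <- match(if (eng$fg[e]) wfg else wbg, uo)
      rel <- if (eng$fg[e]) rel_fg else rel_bg
      P[, , e] <- transition_prob(decs[[wi]], t_use[e] * rel)
    }
    ll <- prune_loglik(eng$edge, P, eng$tip, freqs, eng$nnode_total)
    if (cacheable) cache[[key]] <- ll
    ll
  }
  if (model == "free_ratio") {
    P <- array(0, c(ns, ns, nedge))
    for (e in seq_len(nedge)) {
      pk <- paste0("p", format(th$kappa, digits = 15), "_",
                   format(th$omegas[e], digits = 15), "_",
                   format(t_use[e], digits = 15))
      Pe <- if (cacheable) cache[[pk]] else NULL
      if (is.null(Pe)) {
        Pe <- transition_prob(get_dec(th$omegas[e]), t_use[e])
        if (cacheable) cache[[pk]] <- Pe
      }
      P[, , e] <- Pe
    }
    site_ll <- matrix(prune_loglik(eng$edge, P, eng$tip, freqs, eng$nnode_total),
                      ncol = 1)
    props <- 1
  } else {
    cls <- model_classes(model, th)
    props <- cls$props
    fc <- if (cacheable && !is.null(cache[["fc"]])) cache[["fc"]] else {
      v <- flux_constants(freqs, eng$code)
      if (cacheable) cache[["fc"]] <- v
      v
    }
    r_bg <- vapply(cls$wbg, function(w) raw_flux(fc, th$kappa, w), 1)
    r_fg <- vapply(cls$wfg, function(w) raw_flux(fc, th$kappa, w), 1)
    mu_bg <- sum(props * r_bg)
    mu_fg <- sum(props * r_fg)
    site_ll <- vapply(seq_along(props),
                      function(k) class_ll(cls$wbg[k], cls$wfg[k],
                                           r_bg[k] / mu_bg, r_fg[k] / mu_fg),
                      numeric(eng$npat))
    if (eng$npat == 1L) site_ll <- matrix(site_ll, nrow = 1)
  }
  mx <- site_ll[, 1]
  for (k in seq_len(ncol(site_ll))[-1]) mx <- pmax(mx, site_ll[, k])
  pat_ll <- mx + log(as.vector(exp(site_ll - mx) %*% props))
  list(lnL = sum(eng$weights * pat_ll), site_loglik = site_ll,
       props = props, pat_ll = pat_ll)
}

#' Mixture log-likelihood of a codon site-class model
#'
#' Computes \eqn{\ln L = \sum_s \log \sum_k p_k L_s(k)} by Felsenstein
#' pruning, where class k assigns its partition-specific omega to each
#' branch. Gap/missing codons contribute all-ones partial vectors
#' (marginalized as fully unknown).
#'
#' @param aln A `codon_alignment`.
#' @param tree A `labeled_tree` with branch lengths (expected substitutions
#'   per codon) and, for two-partition models, foreground labels.
#' @param model One of `"M0"`, `"M2a_rel"`, `"CmC"`, `"bsA"`, `"bsA_null"`,
#'   `"free_ratio"`.
#' @param theta Named list of parameter values: `kappa` always; `omega`
#'   (M0); `omega0`, `p0`, `p1` plus `omega2` (M2a_rel, bsA alternative) and
#'   `omega3` (CmC); `omegas` per postorder edge (free_ratio); optional
#'   `scale` multiplying all branch lengths.
#' @param freq Frequency scheme (see [codon_frequencies()]) or a numeric
#'   frequency vector over the sense codons.
#' @param code Genetic-code id; defaults to the alignment's.
#' @return The log-likelihood (numeric scalar).
#' @export
mixture_loglik <- function(aln, tree, model, theta, freq = "F3x4", code = NULL) {
  model <- match.arg(model, MODELS)
  validate_theta(model, theta)
  eng <- make_engine(aln, tree)
  freqs <- if (is.numeric(freq)) freq else codon_frequencies(aln, freq, code)
  engine_loglik(eng, model, theta, freqs)$lnL
}

#' Per-site likelihoods under a single-omega codon model
#'
#' @inheritParams mixture_loglik
#' @param kappa,omega Model parameters.
#' @return Numeric vector of per-site likelihoods.
#' @export
site_likelihoods <- function(aln, tree, kappa, omega, freq = "F3x4", code = NULL) {
  eng <- make_engine(aln, tree)
  freqs <- if (is.numeric(freq)) freq else codon_frequencies(aln, freq, code)
  res <- engine_loglik(eng, "M0", list(kappa = kappa, omega = omega), freqs)
  exp(res$pat_ll)[eng$pat_id]
}

# parameter packing: every scalar parameter is optimized on a transformed
# scale (log for rates, additive log-ratio for simplex proportions)
make_par_map <- function(model, eng, blen_mode) {
  entries <- list(list(name = "kappa", lower = 0.01, upper = 100, start = 2))
  omax <- 999
  if (model == "M0")
    entries <- c(entries, list(list(name = "omega", lower = 1e-6, upper = omax, start = 0.2)))
  if (model %in% c("M2a_rel", "CmC", "bsA", "bsA_null")) {
    entries <- c(entries,
      list(list(name = "omega0", lower = 1e-6, upper = 1 - 1e-6, start = 0.08)),
      list(list(name = "a1", alr = TRUE, start = log(0.85 / 0.1))),
      list(list(name = "a2", alr = TRUE, start = log(0.05 / 0.1))))
  }
  if (model %in% c("M2a_rel", "CmC"))
    entries <- c(entries, list(list(name = "omega2", lower = 1e-6, upper = omax, start = 1.2)))
  if (model == "CmC")
    entries <- c(entries, list(list(name = "omega3", lower = 1e-6, upper = omax, start = 2)))
  if (model == "bsA")
    entries <- c(entries, list(list(name = "omega2", lower = 1, upper = omax, start = 2)))
  if (model == "free_ratio")
    for (e in seq_len(nrow(eng$edge)))
      entries <- c(entries, list(list(name = paste0("w", e),
                                      lower = 1e-6, upper = omax, start = 0.3)))
  if (blen_mode == "scale")
    entries <- c(entries, list(list(name = "scale", lower = 0.02, upper = 50, start = 1)))
  if (blen_mode == "estimate")
    for (e in seq_len(nrow(eng$edge)))
      entries <- c(entries, list(list(name = paste0("t", e), lower = 1e-8, upper = 50,
                                      start = max(eng$t[e], 1e-4))))
  nm <- vapply(entries, `[[`, "", "name")
  is_alr <- vapply(entries, function(x) isTRUE(x$alr), TRUE)
  nat_lo <- vapply(entries, function(x) x$lower %||% 1, 1)
  nat_hi <- vapply(entries, function(x) x$upper %||% 1, 1)
  nat_st <- vapply(entries, `[[`, 1, "start")
  lower <- upper <- start <- numeric(length(nm))
  lower[is_alr] <- -20; upper[is_alr] <- 20; start[is_alr] <- nat_st[is_alr]
  lower[!is_alr] <- log(nat_lo[!is_alr])
  upper[!is_alr] <- log(nat_hi[!is_alr])
  start[!is_alr] <- log(nat_st[!is_alr])
  names(start) <- nm

  unpack <- function(par) {
    v <- ifelse(is_alr, par, exp(par))
    names(v) <- nm
    th <- list(kappa = unname(v["kappa"]))
    if (model == "M0") th$omega <- unname(v["omega"])
    if (model %in% c("M2a_rel", "CmC", "bsA", "bsA_null")) {
      th$omega0 <- unname(v["omega0"])
      ez <- exp(c(v["a1"], v["a2"], 0))
      p <- ez / sum(ez)
      th$p0 <- p[1]; th$p1 <- p[2]
    }
    if (model %in% c("M2a_rel", "CmC", "bsA")) th$omega2 <- unname(v["omega2"])
    if (model == "CmC") th$omega3 <- unname(v["omega3"])
    if (model == "free_ratio")
      th$omegas <- unname(v[paste0("w", seq_len(nrow(eng$edge)))])
    if (blen_mode == "scale") th$scale <- unname(v["scale"])
    if (blen_mode == "estimate")
      th$t <- unname(v[paste0("t", seq_len(nrow(eng$edge)))])
    th
  }
  pack <- function(th) {
    par <- start
    set <- function(key, val, log_scale = TRUE)
      if (key %in% nm && !is.null(val)) par[key] <<- if (log_scale) log(val) else val
    set("kappa", th$kappa)
    set("omega", th$omega)
    if (!is.null(th$p0)) {
      p2 <- max(1 - th$p0 - th$p1, 1e-8)
      set("a1", log(max(th$p0, 1e-8) / p2), log_scale = FALSE)
      set("a2", log(max(th$p1, 1e-8) / p2), log_scale = FALSE)
    }
    set("omega0", th$omega0)
    set("omega2", th$omega2)
    set("omega3", th$omega3)
    set("scale", th$scale)
    if (!is.null(th$omegas))
      for (e in seq_along(th$omegas)) set(paste0("w", e), th$omegas[e])
    if (!is.null(th$t))
      for (e in seq_along(th$t)) set(paste0("t", e), th$t[e])
    pmin(pmax(par, lower), upper)
  }
  list(names = nm, lower = lower, upper = upper, start = start,
       unpack = unpack, pack = pack)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a codon site-class model by maximum likelihood
#'
#' The central fitting routine, covering the one-ratio model M0, the
#' free-ratio model (an independent omega on every branch), branch-site
#' model A and its null (foreground class omega fixed at 1), the three-class
#' M2a_rel model, and Clade Model C (third class with distinct background
#' and foreground omega). Optimization is bounded quasi-Newton (L-BFGS-B) on
#' transformed parameters (log for rates, additive log-ratio for class
#' proportions) with multiple dispersed restarts.
#'
#' Branch-length strategy: M0 estimates branch lengths jointly with kappa
#' and omega by default; site-class models hold them fixed at the supplied
#' values (typically an M0 fit) with a single free multiplicative rescale.
#'
#' @inheritParams mixture_loglik
#' @param freq Frequency scheme or numeric frequency vector.
#' @param branch_lengths `"estimate"`, `"scale"` (fixed shape, one free
#'   multiplier; the default for site-class models), `"fixed"`, or a
#'   `codon_fit` (typically M0) whose fitted lengths are adopted.
#' @param restarts Number of optimizer starts (first from default values,
#'   the rest dispersed deterministically from `seed`).
#' @param seed Integer seed controlling restart dispersal.
#' @param init Optional named list (or list of lists) of natural-scale
#'   parameter values used as additional warm starts.
#' @param control List: `maxit` (default 500), `factr` (default 1e8).
#' @return An object of class `codon_fit`.
#' @examples
#' \donttest{
#' tr <- read_labeled_tree("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
#' sim <- simulate_alignment(sim_spec(tr, "M0", list(kappa = 2, omega = 0.2),
#'                                    n_sites = 200, seed = 7))
#' fit <- fit_codon_model(sim$alignment, tr, "M0", restarts = 1)
#' coef(fit)
#' }
#' @export
fit_codon_model <- function(aln, tree, model = MODELS,
                            freq = "F3x4", code = NULL,
                            branch_lengths = NULL,
                            restarts = 3, seed = 1L, init = NULL,
                            control = list()) {
  model <- match.arg(model)
  cl <- match.call()
  if (inherits(branch_lengths, "codon_fit")) {
    tree <- branch_lengths$tree
    branch_lengths <- "scale"
  }
  blen_mode <- branch_lengths %||% (if (model == "M0") "estimate" else "scale")
  blen_mode <- match.arg(blen_mode, c("estimate", "scale", "fixed"))
  ctrl <- modifyList(list(maxit = 500, factr = 1e8), control)
  eng <- make_engine(aln, tree)
  freqs <- if (is.numeric(freq)) freq else codon_frequencies(aln, freq, code)
  pm <- make_par_map(model, eng, blen_mode)

  cache <- new.env(parent = emptyenv())
  negll <- function(par) {
    th <- pm$unpack(par)
    v <- tryCatch(engine_loglik(eng, model, th, freqs, cache)$lnL,
                  error = function(e) NA_real_)
    if (!is.finite(v)) return(1e10)
    -v
  }

  starts <- if (restarts >= 1) list(pm$start) else list()
  if (restarts > 1) {
    set.seed(as.integer(seed))
    for (r in seq_len(restarts - 1)) {
      jit <- pm$start + runif(length(pm$start), -1, 1)
      starts <- c(starts, list(pmin(pmax(jit, pm$lower), pm$upper)))
    }
  }
  if (!is.null(init)) {
    if (!is.null(names(init))) init <- list(init)
    starts <- c(lapply(init, pm$pack), starts)
  }
  if (!length(starts)) stop("restarts = 0 requires an init warm start")

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = pm$lower, upper = pm$upper,
            control = list(maxit = ctrl$maxit, factr = ctrl$factr)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed from every start")

  th <- pm$unpack(best$par)
  res <- engine_loglik(eng, model, th, freqs)
  fitted_tree <- eng$tree
  t_fit <- eng$t
  if (blen_mode == "estimate") t_fit <- th$t
  if (blen_mode == "scale") t_fit <- eng$t * th$scale
  fitted_tree$phylo$edge.length[eng$orig_index] <- t_fit

  cf <- unlist(th[!vapply(th, is.null, TRUE)])
  structure(list(call = cl, model = model, logLik = res$lnL,
                 df = length(pm$start), coef = cf, theta = th,
                 tree = fitted_tree, aln = aln,
                 freqs = freqs, freq_scheme = if (is.numeric(freq)) "given" else freq,
                 code = eng$code,
                 converged = best$convergence == 0,
                 convergence = best$convergence,
                 counts = best$counts, n_starts = length(starts),
                 site_loglik = res$site_loglik, class_props = res$props,
                 pat_id = eng$pat_id, pat_weights = eng$weights,
                 engine = eng),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon model fit: ", x$model, "\n", sep = "")
  cat("  lnL = ", format(x$logLik, digits = 10),
      " (", x$df, " free parameters",
      if (!x$converged) ", NOT converged" else "", ")\n", sep = "")
  om <- x$coef[grep("^omega", names(x$coef))]
  if (length(om))
    cat("  ", paste(names(om), "=", format(om, digits = 4), collapse = ", "), "\n")
  cat("  kappa = ", format(x$theta$kappa, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @method summary codon_fit
#' @export
summary.codon_fit <- function(object, ...) {
  x <- object
  cls <- if (x$model == "free_ratio") NULL else model_classes(x$model, x$theta)
  out <- list(model = x$model, logLik = x$logLik, df = x$df,
              converged = x$converged, coef = x$coef, classes = cls,
              kappa = x$theta$kappa, n_sites = x$engine$nsites,
              n_taxa = x$engine$ntip, tree_length = sum(x$tree$phylo$edge.length))
  class(out) <- "summary.codon_fit"
  out
}

#' @export
print.summary.codon_fit <- function(x, ...) {
  cat("Codon site-class model ", x$model, ": ", x$n_taxa, " taxa, ",
      x$n_sites, " codon sites\n", sep = "")
  cat("lnL = ", format(x$logLik, digits = 10), ", free parameters = ", x$df,
      ", converged = ", x$converged, "\n", sep = "")
  cat("kappa = ", format(x$kappa, digits = 4), ", tree length = ",
      format(x$tree_length, digits = 4), "\n", sep = "")
  if (!is.null(x$classes)) {
    df <- data.frame(class = seq_along(x$classes$props) - 1,
                     proportion = round(x$classes$props, 4),
                     omega_background = round(x$classes$wbg, 4),
                     omega_foreground = round(x$classes$wfg, 4))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.codon_fit <- function(object, ...) object$coef

#' @export
logLik.codon_fit <- function(object, ...)
  structure(object$logLik, df = object$df, class = "logLik")

#' Write a fit report
#'
#' Serializes a `codon_fit` as a small key-value text block plus a parameter
#' table; [read_fit_report()] round-trips the numeric content.
#'
#' @param fit A `codon_fit`.
#' @param path Output file.
#' @export
write_fit_report <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("model\t", fit$model),
               paste0("lnL\t", format(fit$logLik, digits = 17)),
               paste0("df\t", fit$df),
               paste0("converged\t", fit$converged)), con)
  for (nm in names(fit$coef))
    writeLines(paste0("param.", nm, "\t", format(fit$coef[[nm]], digits = 17)), con)
  invisible(path)
}

#' @rdname write_fit_report
#' @return `read_fit_report` returns a list with `model`, `lnL`, `df`,
#'   `converged` and named `param` vector.
#' @export
read_fit_report <- function(path) {
  ln <- strsplit(readLines(path), "\t")
  kv <- setNames(vapply(ln, `[`, "", 2), vapply(ln, `[`, "", 1))
  pn <- grep("^param\\.", names(kv), value = TRUE)
  list(model = unname(kv[["model"]]), lnL = as.numeric(kv[["lnL"]]),
       df = as.integer(kv[["df"]]), converged = as.logical(kv[["converged"]]),
       param = setNames(as.numeric(kv[pn]), sub("^param\\.", "", pn)))
}
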