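#' Chi-squared upper-tail p-value for a likelihood-ratio statistic
#'
#' @param lrt Likelihood-ratio statistic `2 (lnL_alt - lnL_null)`. Small
#'   negative values from optimizer noise (above `-tol`) are clamped to 0.
#' @param df Degrees of freedom (>= 1; both selection tests here use 1).
#' @param tol Clamp tolerance for negative statistics.
#' @return Upper-tail probability.
#' @examples
#' chisq_pvalue(5.3, 1)  # 0.02 at two decimals
#' @export
chisq_pvalue <- function(lrt, df = 1, tol = 1e-6) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(lrt < -tol)) stop("negative LRT statistic beyond tolerance: ", min(lrt))
  pchisq(pmax(lrt, 0), df = df, lower.tail = FALSE)
}

#' Per-branch dN, dS and dN/dS under the free-ratio model
#'
#' Fits M0 (shared omega; branch lengths and kappa), then the free-ratio
#' model in which every branch has its own omega. Each branch's length `t`
#' (expected substitutions per codon) is decomposed into
#' `dN = t * rhoN / (3 fN)` and `dS = t * rhoS / (3 fS)`, where `rhoN`/`rhoS`
#' are the nonsynonymous/synonymous substitution proportions at the branch's
#' omega and `fN`/`fS` the mutational-opportunity proportions of
#' nonsynonymous/synonymous sites (the same quantities computed at
#' omega = 1), so `dN/dS` equals the branch's ML omega by construction.
#'
#' @inheritParams mixture_loglik
#' @param m0 Optional M0 `codon_fit` supplying branch lengths and a warm
#'   start (fitted if omitted).
#' @param restarts,seed,control Passed to [fit_codon_model()].
#' @return A data frame of class `branch_rates` with one row per branch:
#'   `parent`, `child`, `label`, `t`, `omega`, `dN`, `dS`, plus attributes
#'   `kappa`, `lnL`, `converged` and the underlying `fit`.
#' @export
free_ratio <- function(aln, tree, m0 = NULL, freq = "F3x4", code = NULL,
                       restarts = 1, seed = 1L, control = list()) {
  if (length(tree$phylo$tip.label) < 3) stop("free-ratio model needs >= 3 taxa")
  if (is.null(m0))
    m0 <- fit_codon_model(aln, tree, "M0", freq = freq, code = code,
                          restarts = max(restarts, 1), seed = seed,
                          control = control)
  fr <- fit_codon_model(aln, tree, "free_ratio", freq = freq, code = code,
                        branch_lengths = m0, restarts = restarts, seed = seed,
                        init = list(kappa = m0$theta$kappa,
                                    omegas = rep(m0$theta$omega, nrow(m0$engine$edge))),
                        control = control)
  eng <- fr$engine
  phy <- fr$tree$phylo
  t_fit <- phy$edge.length[eng$orig_index]
  kap <- fr$theta$kappa
  f1 <- ns_flux_proportion(kap, 1, fr$freqs, fr$code)  # f_N at omega = 1
  rows <- lapply(seq_len(nrow(eng$edge)), function(e) {
    w <- fr$theta$omegas[e]
    rho_n <- ns_flux_proportion(kap, w, fr$freqs, fr$code)
    ch <- eng$edge[e, 2]
    lab <- if (ch <= eng$ntip) phy$tip.label[ch] else paste0("node", ch)
    data.frame(parent = eng$edge[e, 1], child = ch, label = lab,
               t = t_fit[e], omega = w,
               dN = t_fit[e] * rho_n / (3 * f1),
               dS = t_fit[e] * (1 - rho_n) / (3 * (1 - f1)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("branch_rates", "data.frame")
  attr(out, "kappa") <- kap
  attr(out, "lnL") <- fr$logLik
  attr(out, "converged") <- fr$converged
  attr(out, "fit") <- fr
  out
}

#' @export
print.branch_rates <- function(x, ...) {
  cat("Free-ratio branch rates (kappa = ",
      format(attr(x, "kappa"), digits = 4), ", lnL = ",
      format(attr(x, "lnL"), digits = 10), ")\n", sep = "")
  df <- as.data.frame(x)
  df[c("t", "omega", "dN", "dS")] <- lapply(df[c("t", "omega", "dN", "dS")],
                                            signif, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

# shared machinery for the two LRT-based tests: fit null, warm-start the
# alternative from it, clamp tiny negative statistics
run_lrt_pair <- function(aln, tree, alt_model, null_model, null_init, alt_init,
                         m0, freq, code, restarts, seed, control) {
  if (!any(tree$foreground)) stop("no foreground branch labeled on the tree")
  if (is.null(m0))
    m0 <- fit_codon_model(aln, tree, "M0", freq = freq, code = code,
                          restarts = 1, seed = seed, control = control)
  # the M0 fit may have unrooted the tree; keep its labeled version
  null <- fit_codon_model(aln, m0$tree, null_model, freq = freq, code = code,
                          branch_lengths = m0, restarts = restarts, seed = seed,
                          init = null_init(m0), control = control)
  alt <- fit_codon_model(aln, m0$tree, alt_model, freq = freq, code = code,
                         branch_lengths = m0, restarts = restarts, seed = seed,
                         init = alt_init(null), control = control)
  if (alt$logLik < null$logLik - 1e-6) {
    # nested models: retry the alternative straight from the null optimum
    alt2 <- fit_codon_model(aln, m0$tree, alt_model, freq = freq, code = code,
                            branch_lengths = m0, restarts = 1, seed = seed + 1L,
                            init = alt_init(null), control = control)
    if (alt2$logLik > alt$logLik) alt <- alt2
  }
  list(m0 = m0, null = null, alt = alt)
}

#' Branch-site test of positive selection
#'
#' Fits branch-site model A (alternative: foreground site class with
#' omega2 >= 1 free) and its null (omega2 = 1) on a tree with labeled
#' foreground branch(es); compares them with an LRT referred to the
#' chi-squared distribution with one degree of freedom; and reports
#' empirical-Bayes posterior probabilities that each site belongs to the
#' positively selected classes (2a + 2b) on the foreground.
#'
#' @inheritParams free_ratio
#' @param gene Dataset label carried into reports.
#' @param alpha Significance threshold.
#' @param mode Posterior mode, `"neb"` (at the MLEs) or `"beb"`
#'   (grid-averaged; see [site_class_posteriors()]).
#' @param restarts Optimizer restarts for the alternative/null fits.
#' @return An object of class `selection_test`.
#' @export
branch_site_test <- function(aln, tree, gene = "gene", m0 = NULL,
                             freq = "F3x4", code = NULL, alpha = 0.05,
                             mode = c("neb", "beb"), restarts = 2, seed = 1L,
                             control = list()) {
  mode <- match.arg(mode)
  fits <- run_lrt_pair(aln, tree, "bsA", "bsA_null",
                       null_init = function(m0) list(
                         kappa = m0$theta$kappa, omega0 = min(max(m0$theta$omega, 1e-4), 0.9),
                         p0 = 0.8, p1 = 0.1),
                       alt_init = function(null) list(
                         c(null$theta[c("kappa", "omega0", "p0", "p1")],
                           list(omega2 = 1, scale = null$theta$scale)),
                         c(null$theta[c("kappa", "omega0", "p0", "p1")],
                           list(omega2 = 4, scale = null$theta$scale))),
                       m0, freq, code, restarts, seed, control)
  finish_test(fits, gene, "branch-site", alpha, mode,
              selected_classes = 3:4, threshold = 0.5)
}

#' Clade-model test of selection divergence
#'
#' Fits Clade Model C (third site class with distinct background omega2 and
#' foreground omega3) against the M2a_rel null (shared omega2), LRT with one
#' degree of freedom, and flags sites whose posterior probability of
#' membership in the divergent class exceeds the threshold (0.75).
#'
#' @inheritParams branch_site_test
#' @param threshold Posterior probability above which divergent sites are
#'   flagged.
#' @return An object of class `selection_test`.
#' @export
clade_model_test <- function(aln, tree, gene = "gene", m0 = NULL,
                             freq = "F3x4", code = NULL, alpha = 0.05,
                             threshold = 0.75, mode = c("neb", "beb"),
                             restarts = 2, seed = 1L, control = list()) {
  mode <- match.arg(mode)
  fits <- run_lrt_pair(aln, tree, "CmC", "M2a_rel",
                       null_init = function(m0) list(
                         kappa = m0$theta$kappa, omega0 = min(max(m0$theta$omega, 1e-4), 0.9),
                         p0 = 0.8, p1 = 0.1, omega2 = 1.2),
                       alt_init = function(null) list(
                         c(null$theta[c("kappa", "omega0", "p0", "p1", "omega2")],
                           list(omega3 = null$theta$omega2,
                                scale = null$theta$scale)),
                         c(null$theta[c("kappa", "omega0", "p0", "p1")],
                           list(omega2 = null$theta$omega2 / 2,
                                omega3 = max(3, 2 * null$theta$omega2),
                                scale = null$theta$scale))),
                       m0, freq, code, restarts, seed, control)
  finish_test(fits, gene, "clade-model", alpha, mode,
              selected_classes = 3, threshold = threshold)
}

finish_test <- function(fits, gene, type, alpha, mode, selected_classes, threshold) {
  lrt <- 2 * (fits$alt$logLik - fits$null$logLik)
  p <- chisq_pvalue(max(lrt, 0), df = 1)
  post <- site_class_posteriors(fits$alt, mode = mode,
                                selected = selected_classes,
                                threshold = threshold)
  structure(list(gene = gene, type = type,
                 alt = fits$alt, null = fits$null, m0 = fits$m0,
                 lnL_alt = fits$alt$logLik, lnL_null = fits$null$logLik,
                 lrt = max(lrt, 0), df = 1, p = p,
                 significant = p < alpha, alpha = alpha,
                 posterior = post, threshold = threshold,
                 flagged = post$site[post$flagged]),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(x$type, " test for '", x$gene, "': ", x$alt$model, " vs ",
      x$null$model, "\n", sep = "")
  cat("  lnL_alt = ", format(x$lnL_alt, digits = 10),
      ", lnL_null = ", format(x$lnL_null, digits = 10), "\n", sep = "")
  cat("  LRT = ", format(x$lrt, digits = 4), " (df = ", x$df, "), p = ",
      format.pval(x$p, digits = 3), if (x$significant) "  *" else "",
      "\n", sep = "")
  if (length(x$flagged))
    cat("  sites above posterior ", x$threshold, ": ",
        paste(x$flagged, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Empirical-Bayes site-class posterior probabilities
#'
#' `"neb"` (naive empirical Bayes) evaluates the class posterior at the
#' maximum-likelihood estimates: `P(k | site) = p_k L_site(k) / sum_j p_j
#' L_site(j)` from the fit's cached per-site per-class likelihoods. `"beb"`
#' averages the same quantity over a discrete grid on the class proportions
#' (simplex step 0.1) and the selected-class omega (10-point grid), with a
#' uniform prior and the remaining parameters held at their MLEs; this
#' accounts for sampling error in the mixture weights in the spirit of the
#' Bayes-empirical-Bayes procedure.
#'
#' @param fit A `codon_fit` for a site-class model.
#' @param mode `"neb"` or `"beb"`.
#' @param selected Class indices (1-based) whose summed posterior forms the
#'   `selected` column; defaults to the divergent/selected class of the
#'   model (class 3 for CmC/M2a_rel, classes 3+4 for branch-site A).
#' @param threshold Flagging threshold on the selected posterior.
#' @return Data frame: `site`, per-class posteriors, `selected`, `flagged`.
#' @export
site_class_posteriors <- function(fit, mode = c("neb", "beb"), selected = NULL,
                                  threshold = 0.75) {
  mode <- match.arg(mode)
  K <- ncol(fit$site_loglik)
  if (is.null(selected))
    selected <- switch(fit$model, bsA = , bsA_null = 3:4,
                       CmC = , M2a_rel = 3, seq_len(K))
  if (K == 1) {
    post <- matrix(1, fit$engine$nsites, 1)
  } else if (mode == "neb") {
    ll <- fit$site_loglik
    lp <- sweep(ll, 2, log(fit$class_props), "+")
    mx <- apply(lp, 1, max)
    w <- exp(lp - mx)
    post <- (w / rowSums(w))[fit$pat_id, , drop = FALSE]
  } else {
    post <- beb_posteriors(fit)[fit$pat_id, , drop = FALSE]
  }
  sel <- rowSums(post[, selected, drop = FALSE])
  out <- data.frame(site = seq_len(nrow(post)))
  for (k in seq_len(ncol(post))) out[[paste0("class", k - 1)]] <- post[, k]
  out$selected <- sel
  out$flagged <- sel > threshold
  out
}

# grid-averaged posteriors: vary the proportion simplex and the
# selected-class omega; everything else at the MLEs
beb_posteriors <- function(fit, n_omega = 10) {
  eng <- fit$engine
  th <- fit$theta
  model <- fit$model
  if (!model %in% c("M2a_rel", "CmC", "bsA", "bsA_null"))
    stop("beb posteriors are defined for site-class models only")
  # per-class site log-likelihood columns as a function of the grid omega:
  # classes 1 and 2 (purifying, neutral) do not depend on it
  base_ll <- fit$site_loglik
  omega_grid <- if (model == "bsA") seq(1, 11, length.out = n_omega)
    else exp(seq(log(0.05), log(20), length.out = n_omega))
  if (model == "bsA_null") omega_grid <- 1
  # grid over (p0, p1) with step 0.1
  pg <- expand.grid(p0 = seq(0.05, 0.95, 0.1), p1 = seq(0.05, 0.95, 0.1))
  pg <- pg[pg$p0 + pg$p1 <= 1, ]
  ll_for_omega <- function(w) {
    th2 <- th
    if (model %in% c("M2a_rel", "CmC")) th2$omega2 <- w
    if (model == "CmC") th2$omega3 <- w * (th$omega3 / max(th$omega2, 1e-8))
    if (model %in% c("bsA", "bsA_null")) th2$omega2 <- w
    engine_loglik(eng, if (model == "bsA_null") "bsA" else model, th2,
                  fit$freqs)$site_loglik
  }
  acc_num <- matrix(0, eng$npat, ncol(base_ll))
  logw <- c(); nums <- list(); dens <- list()
  gi <- 0L
  for (w in omega_grid) {
    ll <- ll_for_omega(w)
    for (r in seq_len(nrow(pg))) {
      gi <- gi + 1L
      th3 <- th; th3$p0 <- pg$p0[r]; th3$p1 <- pg$p1[r]
      pk <- model_classes(model, th3)$props
      lp <- sweep(ll, 2, log(pmax(pk, 1e-12)), "+")
      mx <- apply(lp, 1, max)
      sitew <- exp(lp - mx)
      den <- rowSums(sitew)
      logw[gi] <- sum(eng$weights * (mx + log(den)))
      nums[[gi]] <- sitew / den
    }
  }
  W <- exp(logw - max(logw))
  W <- W / sum(W)
  post <- Reduce(`+`, Map(`*`, nums, W))
  post / rowSums(post)
}

#' Site-wise omega estimates and LRT against neutrality
#'
#' For each codon site, maximizes the single-class likelihood over omega
#' with kappa, branch lengths and codon frequencies fixed at an M0 fit, and
#' reports the likelihood-ratio statistic against omega = 1 (the site-wise
#' likelihood ratio analysis used to display per-site selection pressure).
#'
#' @inheritParams free_ratio
#' @param m0 An M0 `codon_fit` providing kappa, branch lengths and
#'   frequencies.
#' @param grid_n Size of the log-spaced omega grid scanned before local
#'   refinement.
#' @return Data frame: `site`, `omega`, `lnL`, `lnL_neutral`, `lrt`, `p`
#'   (chi-squared df 1, two-sided away from omega = 1 is not distinguished).
#'   All-gap sites yield `NA`.
#' @export
sitewise_omega <- function(aln, tree, m0, grid_n = 25) {
  eng <- make_engine(aln, m0$tree)
  freqs <- m0$freqs
  kap <- m0$theta$kappa
  grid <- sort(unique(c(exp(seq(log(1e-4), log(50), length.out = grid_n)), 1)))
  ll_grid <- vapply(grid, function(w)
    engine_loglik(eng, "M0", list(kappa = kap, omega = w), freqs)$site_loglik[, 1],
    numeric(eng$npat))
  if (eng$npat == 1L) ll_grid <- matrix(ll_grid, nrow = 1)
  i_neutral <- which(grid == 1)
  all_gap <- colSums(eng$tip > 0) == 0
  res <- lapply(seq_len(eng$npat), function(s) {
    if (all_gap[s]) return(c(NA_real_, NA_real_, NA_real_))
    i <- which.max(ll_grid[s, ])
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    sub_tip <- eng$tip[, s, drop = FALSE]
    f <- function(lw) {
      e2 <- eng; e2$tip <- sub_tip; e2$npat <- 1L; e2$weights <- 1
      engine_loglik(e2, "M0", list(kappa = kap, omega = exp(lw)), freqs)$lnL
    }
    opt <- optimize(f, c(log(lo), log(hi)), maximum = TRUE, tol = 1e-4)
    if (opt$objective >= ll_grid[s, i])
      c(exp(opt$maximum), opt$objective, ll_grid[s, i_neutral])
    else c(grid[i], ll_grid[s, i], ll_grid[s, i_neutral])
  })
  m <- do.call(rbind, res)[eng$pat_id, , drop = FALSE]
  lrt <- pmax(2 * (m[, 2] - m[, 3]), 0)
  data.frame(site = seq_len(eng$nsites), omega = m[, 1], lnL = m[, 2],
             lnL_neutral = m[, 3], lrt = lrt,
             p = ifelse(is.na(lrt), NA, pchisq(lrt, 1, lower.tail = FALSE)))
}

#' Write a Table-1-style test report
#'
#' One TSV row per test: gene, models, log-likelihoods, LRT, df, p,
#' significance, class proportions and omegas (foreground omega3 where the
#' model has one). Optionally appends Benjamini-Hochberg adjusted p-values
#' across the supplied tests (the per-gene tests themselves are reported
#' uncorrected, as is conventional for this analysis).
#'
#' @param tests A `selection_test` or list of them.
#' @param path Output TSV.
#' @param p_adjust Add a BH-adjusted p column.
#' @return The data frame written, invisibly.
#' @export
write_test_report <- function(tests, path, p_adjust = FALSE) {
  if (inherits(tests, "selection_test")) tests <- list(tests)
  rows <- lapply(tests, function(x) {
    cls <- model_classes(x$alt$model, x$alt$theta)
    p <- cls$props
    data.frame(gene = x$gene, model_alt = x$alt$model, model_null = x$null$model,
               lnL_alt = x$lnL_alt, lnL_null = x$lnL_null,
               LRT = x$lrt, df = x$df, p = x$p, significant = x$significant,
               p0 = p[1], p1 = p[2], p2 = sum(p[-(1:2)]),
               w0 = cls$wbg[1], w1 = cls$wbg[2],
               w2 = cls$wbg[3], w3 = cls$wfg[3])
  })
  df <- do.call(rbind, rows)
  if (p_adjust) df$p_BH <- stats::p.adjust(df$p, "BH")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write per-site posterior probabilities as TSV
#'
#' @param test A `selection_test` (or the posterior data frame itself).
#' @param path Output TSV.
#' @export
write_site_posteriors <- function(test, path) {
  df <- if (inherits(test, "selection_test")) test$posterior else test
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
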