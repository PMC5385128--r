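#' Goldman-Yang codon rate matrix
#'
#' Builds the reversible 61-state (standard code) codon rate matrix in which
#' a single-nucleotide change from codon i to codon j has rate proportional
#' to the target frequency \eqn{\pi_j}, multiplied by \eqn{\kappa} if the
#' change is a transition and by \eqn{\omega} if it is nonsynonymous.
#' Multi-step changes and changes to stop codons have rate zero. The matrix
#' is scaled so the expected substitution rate \eqn{-\sum_i \pi_i q_{ii}} is
#' one per codon per unit branch length.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param freqs Equilibrium frequencies over the sense codons (summing to 1),
#'   in the order of `genetic_code(code)$codons`.
#' @param code Genetic-code id.
#' @return A list of class `codon_Q`: `Q` (scaled rate matrix), `pi`,
#'   `kappa`, `omega`, `rho_ns` (proportion of the substitution rate that is
#'   nonsynonymous, after scaling), and the eigen-decomposition used for
#'   transition probabilities.
#' @export
codon_rate_matrix <- function(kappa, omega, freqs, code = "1") {
  stopifnot(kappa > 0, omega >= 0)
  gc <- genetic_code(code)
  ns <- length(gc$codons)
  if (length(freqs) != ns) stop("freqs must have one entry per sense codon")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be nonnegative and sum to 1")
  st <- codon_pair_structure(code)
  R <- matrix(0, ns, ns, dimnames = list(gc$codons, gc$codons))
  R[st$neighbor] <- rep(freqs, each = ns)[st$neighbor]
  R[st$neighbor & st$transition] <- R[st$neighbor & st$transition] * kappa
  R[st$neighbor & st$nonsyn] <- R[st$neighbor & st$nonsyn] * omega
  diag(R) <- -rowSums(R)
  rate <- -sum(freqs * diag(R))
  if (rate <= 0) stop("degenerate rate matrix (zero total rate)")
  Q <- R / rate
  flux_ns <- sum(freqs * rowSums(R * st$nonsyn)) / rate
  dec <- decompose_Q(Q, freqs)
  # `rate` is the raw flux of the unscaled generator; ratios of raw fluxes
  # across site classes give the classes' relative evolutionary rates when
  # branch lengths are defined as substitutions per codon averaged over the
  # class mixture
  structure(list(Q = Q, pi = freqs, kappa = kappa, omega = omega,
                 code = code, rho_ns = flux_ns, rate = rate, decomp = dec),
            class = "codon_Q")
}

# pairwise structure of the sense-codon state space: single-nucleotide
# neighbors, transition vs transversion, synonymous vs nonsynonymous
codon_pair_structure <- function(code = "1") {
  key <- paste0("pairs", code)
  cached <- get0(key, envir = .codonsel_cache)
  if (!is.null(cached)) return(cached)
  gc <- genetic_code(code)
  cods <- gc$codons
  ns <- length(cods)
  mat <- do.call(rbind, strsplit(cods, ""))
  aa <- gc$aa[cods]
  neighbor <- matrix(FALSE, ns, ns)
  transition <- matrix(FALSE, ns, ns)
  nonsyn <- matrix(FALSE, ns, ns)
  ts_pair <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (pos in 1:3) {
    same_other <- TRUE
    for (q in setdiff(1:3, pos))
      same_other <- same_other & outer(mat[, q], mat[, q], "==")
    diff_here <- outer(mat[, pos], mat[, pos], "!=")
    nb <- same_other & diff_here
    neighbor <- neighbor | nb
    transition[nb] <- outer(mat[, pos], mat[, pos], ts_pair)[nb]
  }
  nonsyn <- outer(aa, aa, "!=")
  out <- list(neighbor = neighbor, transition = transition,
              nonsyn = nonsyn & neighbor)
  assign(key, out, envir = .codonsel_cache)
  out
}

# symmetrized eigen-decomposition of a reversible Q: with D = diag(sqrt(pi)),
# D Q D^-1 is symmetric; P(t) = U exp(Lambda t) Uinv with U = D^-1 V
decompose_Q <- function(Q, pi) {
  d <- sqrt(pi)
  A <- Q * (d %o% (1 / d))
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values,
       U = e$vectors / d,
       Uinv = t(e$vectors) * rep(d, each = length(d)))
}

#' Transition probability matrix P(t)
#'
#' Matrix exponential of `Q t`, computed from the symmetrized
#' eigen-decomposition of the reversible generator. Tiny negative entries
#' from roundoff are clipped to zero and rows renormalized.
#'
#' @param Qobj A `codon_Q` object from [codon_rate_matrix()].
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @return Row-stochastic matrix over the sense codons.
#' @export
transition_prob <- function(Qobj, t) {
  if (t < 0) stop("negative branch length")
  dec <- Qobj$decomp
  P <- (dec$U * rep(exp(dec$values * t), each = nrow(dec$U))) %*% dec$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Equilibrium codon frequency estimation
#'
#' @param aln A `codon_alignment`.
#' @param scheme `"F3x4"` (position-specific nucleotide frequencies,
#'   codeml's default), `"F1x4"` (pooled nucleotide frequencies), `"equal"`,
#'   or `"empirical"` (observed sense-codon proportions). F3x4/F1x4 products
#'   are renormalized over the sense codons; exact zeros are floored at
#'   1e-12 before renormalization so the rate matrix stays irreducible.
#' @param code Genetic-code id (defaults to the alignment's).
#' @return Frequency vector over the sense codons, summing to 1.
#' @export
codon_frequencies <- function(aln, scheme = c("F3x4", "F1x4", "equal", "empirical"),
                              code = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(code)) code <- aln$code
  gc <- genetic_code(code)
  cods <- gc$codons
  if (length(aln$codons) == 0L) stop("empty alignment")
  obs <- aln$codons[aln$codons %in% cods]
  if (scheme == "equal") return(setNames(rep(1 / length(cods), length(cods)), cods))
  if (!length(obs)) stop("alignment has no usable codons")
  if (scheme == "empirical") {
    tab <- table(factor(obs, levels = cods))
    f <- as.numeric(tab) / sum(tab)
  } else {
    nt <- c("A", "C", "G", "T")
    mat <- do.call(rbind, strsplit(obs, ""))
    if (scheme == "F3x4") {
      fpos <- apply(mat, 2, function(col) {
        tb <- table(factor(col, levels = nt)); as.numeric(tb) / sum(tb)
      })
      rownames(fpos) <- nt
      cm <- do.call(rbind, strsplit(cods, ""))
      f <- fpos[cm[, 1], 1] * fpos[cm[, 2], 2] * fpos[cm[, 3], 3]
    } else {
      tb <- table(factor(as.vector(mat), levels = nt))
      fp <- as.numeric(tb) / sum(tb)
      names(fp) <- nt
      cm <- do.call(rbind, strsplit(cods, ""))
      f <- fp[cm[, 1]] * fp[cm[, 2]] * fp[cm[, 3]]
    }
  }
  f[f == 0] <- 1e-12
  setNames(f / sum(f), cods)
}

# proportions of the substitution rate that are nonsynonymous/synonymous at
# a given omega; at omega = 1 these are the mutational-opportunity
# proportions of nonsynonymous/synonymous "sites" (f_N, f_S) used to convert
# branch lengths into dN and dS
ns_flux_proportion <- function(kappa, omega, freqs, code = "1") {
  codon_rate_matrix(kappa, omega, freqs, code)$rho_ns
}

# raw-flux constants: the unscaled generator's total flux decomposes as
# rate(kappa, omega) = A + kappa B + omega C + omega kappa D with
# A/B/C/D the pi-weighted synonymous-transversion / synonymous-transition /
# nonsynonymous-transversion / nonsynonymous-transition neighbor fluxes
flux_constants <- function(freqs, code = "1") {
  st <- codon_pair_structure(code)
  po <- freqs %o% freqs
  syn <- st$neighbor & !st$nonsyn
  c(A = sum(po[syn & !st$transition]),
    B = sum(po[syn & st$transition]),
    C = sum(po[st$nonsyn & !st$transition]),
    D = sum(po[st$nonsyn & st$transition]))
}

raw_flux <- function(fc, kappa, omega) {
  unname(fc["A"] + kappa * fc["B"] + omega * (fc["C"] + kappa * fc["D"]))
}
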