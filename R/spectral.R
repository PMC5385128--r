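#' Five-sites rule for L-opsin spectral tuning
#'
#' The wavelength of maximal absorption (lambda_max) of mammalian
#' long-wavelength (L/LWS) cone pigments is, to good approximation,
#' determined additively by the residues at five sites of the opsin (human
#' L-opsin numbering): 180, 197, 277, 285 and 308. Relative to the
#' reference genotype S180/H197/Y277/T285/A308 ("SHYTA", 560 nm), the
#' substitutions S180A, H197Y, Y277F, T285A and A308S shift lambda_max down
#' by 7, 28, 7, 15 and 16 nm respectively, and the reverse substitutions
#' shift it up by the same amounts.
#'
#' @name five_sites
#' @keywords internal
NULL

FIVE_SITES <- c(180L, 197L, 277L, 285L, 308L)
LAMBDA_ANCHOR <- 560
# per site: the anchor residue (shift 0) and the alternative with its
# red-to-blue shift in nm
SITE_SHIFTS <- list(
  "180" = c(S = 0, A = 7),
  "197" = c(H = 0, Y = 28),
  "277" = c(Y = 0, F = 7),
  "285" = c(T = 0, A = 15),
  "308" = c(A = 0, S = 16)
)

#' Predict L-opsin lambda_max from the five tuning sites
#'
#' Additive five-sites prediction anchored at SHYTA = 560 nm. Residues
#' outside the canonical alternatives for a site (180: S/A, 197: H/Y,
#' 277: Y/F, 285: T/A, 308: A/S) make the prediction unavailable (`NA`)
#' rather than guessed; the offending sites are reported in the
#' `"unavailable_sites"` attribute.
#'
#' @param genotype Five residues at sites 180/197/277/285/308: a single
#'   5-letter string (e.g. `"SHYTA"`) or a character vector of length 5.
#' @return Predicted lambda_max in nm (numeric scalar; `NA` if any residue
#'   is non-canonical or missing).
#' @examples
#' predict_lambda_max("SHYTA")  # 560
#' predict_lambda_max("AHYTA")  # 553
#' predict_lambda_max("SHFTA")  # 552
#' @export
predict_lambda_max <- function(genotype) {
  res <- if (length(genotype) == 1L && nchar(genotype) == 5L)
    strsplit(toupper(genotype), "")[[1]] else toupper(genotype)
  if (length(res) != 5L)
    stop("genotype must supply exactly five residues (sites 180/197/277/285/308)")
  shifts <- vapply(seq_len(5L), function(i) {
    tab <- SITE_SHIFTS[[i]]
    unname(tab[res[i]])
  }, numeric(1))
  bad <- FIVE_SITES[is.na(shifts)]
  if (length(bad)) {
    out <- NA_real_
    attr(out, "unavailable_sites") <- bad
    return(out)
  }
  LAMBDA_ANCHOR - sum(shifts)
}

#' Read the five tuning-site residues off an aligned opsin sequence
#'
#' Site numbering follows the human L-opsin convention of the five-sites
#' literature. Because species sequences differ in length, extraction is
#' alignment-mediated: the query is globally aligned to an annotated
#' reference carrying the canonical numbering, and residues are read off
#' the query at the mapped positions. The bundled default reference is a
#' synthetic sequence (see
#' `system.file("extdata", "lopsin_reference_synthetic.fasta", package =
#' "codonsel")`) carrying the anchor residues at the annotated sites; any
#' reference whose residue numbering matches the convention can be supplied
#' instead.
#'
#' Site 233 (S/T, a spectrally relevant position in transmembrane domain 5)
#' is reported alongside but never enters the lambda_max prediction, whose
#' additive rule is defined on the five sites only.
#'
#' @param query Amino-acid sequence (string).
#' @param reference Ungapped reference amino-acid string whose positions
#'   define the site numbering; default is the bundled synthetic reference.
#' @param alignment Optional pre-computed pairwise alignment: a list with
#'   equal-length gapped strings `query` and `reference`. If omitted, a
#'   global Needleman-Wunsch alignment (BLOSUM62, gap open 10, extend 0.5)
#'   is computed with [Biostrings::pairwiseAlignment()].
#' @return An object of class `spectral_genotype`: residues at the five
#'   sites plus site 233, the 5-letter genotype string (`-` for unmapped
#'   sites), and the predicted lambda_max (`NA` when unavailable).
#' @export
extract_genotype <- function(query, reference = NULL, alignment = NULL) {
  if (is.null(reference)) reference <- bundled_reference()
  query <- toupper(gsub("-", "", query))
  reference <- toupper(reference)
  if (nchar(reference) < max(FIVE_SITES))
    stop("reference lacks annotated site positions (too short for site ",
         max(FIVE_SITES), ")")
  if (is.null(alignment)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(reference),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    aq <- as.character(Biostrings::alignedPattern(pa))
    ar <- as.character(Biostrings::alignedSubject(pa))
  } else {
    aq <- toupper(alignment$query)
    ar <- toupper(alignment$reference)
    if (nchar(aq) != nchar(ar)) stop("alignment rows differ in length")
  }
  qa <- strsplit(aq, "")[[1]]
  ra <- strsplit(ar, "")[[1]]
  ref_pos <- cumsum(ra != "-")
  sites <- c(FIVE_SITES, 233L)
  residues <- vapply(sites, function(s) {
    col <- which(ref_pos == s & ra != "-")
    if (!length(col)) return(NA_character_)
    r <- qa[col[1]]
    if (r == "-") NA_character_ else r
  }, character(1))
  names(residues) <- sites
  five <- residues[as.character(FIVE_SITES)]
  genotype <- paste(ifelse(is.na(five), "-", five), collapse = "")
  structure(list(residues = residues, genotype = genotype,
                 site233 = unname(residues["233"]),
                 lambda_max = if (anyNA(five)) NA_real_ else
                   predict_lambda_max(unname(five))),
            class = "spectral_genotype")
}

#' @export
print.spectral_genotype <- function(x, ...) {
  cat("Five-sites genotype: ", x$genotype,
      " (site 233: ", ifelse(is.na(x$site233), "?", x$site233), ")\n", sep = "")
  if (is.na(x$lambda_max)) {
    cat("  predicted lambda_max unavailable",
        " (non-canonical or unmapped residue)\n", sep = "")
  } else {
    cat("  predicted lambda_max: ", x$lambda_max, " nm\n", sep = "")
  }
  invisible(x)
}

bundled_reference <- function() {
  path <- system.file("extdata", "lopsin_reference_synthetic.fasta",
                      package = "codonsel")
  if (!nzchar(path)) stop("bundled reference not found")
  unname(read_fasta(path, type = "aa"))
}

#' Species panel of five-sites genotypes and predicted lambda_max
#'
#' Applies [extract_genotype()] to every sequence of a panel, producing a
#' table of residues at the tuning sites, genotype strings and predicted
#' lambda_max, with an experimental lambda_max column passed through when
#' supplied. Per-row failures are collected into rows with `NA` values, not
#' raised; duplicated species ids are kept with a warning.
#'
#' @param panel Named character vector of amino-acid sequences (or path to
#'   an amino-acid FASTA).
#' @param reference Optional reference (see [extract_genotype()]).
#' @param experimental Optional named numeric vector of experimentally
#'   measured lambda_max values, joined by species id.
#' @return Data frame: `species`, residue columns `s180`..`s308`, `s233`,
#'   `genotype`, `lambda_pred`, `lambda_exp`, `note`.
#' @export
genotype_table <- function(panel, reference = NULL, experimental = NULL) {
  if (is.character(panel) && length(panel) == 1L && file.exists(panel))
    panel <- read_fasta(panel, type = "aa")
  if (length(panel) && (is.null(names(panel)) || any(!nzchar(names(panel)))))
    stop("panel sequences must be named")
  if (anyDuplicated(names(panel)))
    warning("duplicated species id(s): ",
            paste(unique(names(panel)[duplicated(names(panel))]), collapse = ", "))
  rows <- lapply(seq_along(panel), function(i) {
    id <- names(panel)[i]
    g <- tryCatch(extract_genotype(panel[[i]], reference = reference),
                  error = function(e) e)
    if (inherits(g, "error")) {
      data.frame(species = id, s180 = NA, s197 = NA, s277 = NA, s285 = NA,
                 s308 = NA, s233 = NA, genotype = NA, lambda_pred = NA_real_,
                 note = conditionMessage(g))
    } else {
      r <- g$residues
      data.frame(species = id, s180 = r[["180"]], s197 = r[["197"]],
                 s277 = r[["277"]], s285 = r[["285"]], s308 = r[["308"]],
                 s233 = ifelse(is.na(g$site233), NA, g$site233),
                 genotype = g$genotype, lambda_pred = g$lambda_max,
                 note = if (is.na(g$lambda_max)) "prediction unavailable" else "")
    }
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), s180 = character(), s197 = character(),
               s277 = character(), s285 = character(), s308 = character(),
               s233 = character(), genotype = character(),
               lambda_pred = numeric(), note = character())
  df$lambda_exp <- if (is.null(experimental)) rep(NA_real_, nrow(df)) else
    unname(experimental[df$species])
  rownames(df) <- NULL
  df
}
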