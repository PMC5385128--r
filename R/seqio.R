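#' @useDynLib codonsel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize pchisq runif setNames simulate coef logLik
#' @importFrom utils write.table modifyList
NULL

GAP_CODON <- "---"
MISSING_CODON <- "NNN"

#' Genetic-code tables
#'
#' Sense codons and translations for a numeric NCBI genetic-code id
#' (\code{"1"} is the standard nuclear code used for all mammalian nuclear
#' genes). Tables come from [Biostrings::getGeneticCode()].
#'
#' @param code Genetic-code id accepted by [Biostrings::getGeneticCode()].
#' @return A list with elements `codons` (sense codons, alphabetical order),
#'   `aa` (named translation vector over all 64 codons), `stops` (stop codons).
#' @keywords internal
genetic_code <- function(code = "1") {
  key <- paste0("gc", code)
  cached <- get0(key, envir = .codonsel_cache)
  if (!is.null(cached)) return(cached)
  gc <- Biostrings::getGeneticCode(code)
  nt <- c("A", "C", "G", "T")
  all64 <- sort(apply(expand.grid(nt, nt, nt), 1, paste0, collapse = ""))
  aa <- gc[all64]
  names(aa) <- all64
  stops <- all64[aa == "*"]
  out <- list(codons = all64[aa != "*"], aa = aa, stops = stops)
  assign(key, out, envir = .codonsel_cache)
  out
}

.codonsel_cache <- new.env(parent = emptyenv())

#' Translate an in-frame coding sequence
#'
#' Translates a nucleotide coding sequence codon by codon. A terminal stop
#' codon is silently stripped; an internal stop is a hard error naming the
#' offending codon (the discard-on-internal-stop rule applied when screening
#' coding sequences). Codons containing `N` translate to `X` and are treated
#' as fully unknown downstream.
#'
#' @param cds A nucleotide string over `A,C,G,T,N` with length divisible by 3.
#' @param code Genetic-code id (default standard nuclear code).
#' @return Amino-acid string, one letter per codon, terminal stop removed.
#' @examples
#' translate_cds("ATGGCGTGA")  # "MA"
#' @export
translate_cds <- function(cds, code = "1") {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("coding sequence length ", nchar(cds), " is not divisible by 3")
  bad <- gsub("[ACGTN]", "", cds)
  if (nzchar(bad))
    stop("non-ACGTN character(s) in coding sequence: ", substr(bad, 1, 5))
  gc <- genetic_code(code)
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- ifelse(grepl("N", codons), "X", unname(gc$aa[codons]))
  n <- length(aa)
  if (n > 0L && !is.na(aa[n]) && aa[n] == "*") {
    aa <- aa[-n]
    codons <- codons[-n]
    n <- n - 1L
  }
  internal <- which(aa == "*")
  if (length(internal))
    stop("internal stop codon ", codons[internal[1]], " at codon ",
         internal[1], " of ", n)
  paste(aa, collapse = "")
}

#' Codon alignment container
#'
#' A codon alignment is a taxa x sites character matrix whose entries are
#' sense codons of the active genetic code, the gap token `"---"`, or the
#' missing token `"NNN"` (any codon containing N or other ambiguity).
#'
#' @param codons Character matrix (rows = taxa, columns = codon sites) with
#'   row names giving taxon ids, or a named list/vector of equal-length
#'   in-frame nucleotide strings which is split into codons.
#' @param code Genetic-code id used to validate states.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons, code = "1") {
  if (!is.matrix(codons)) {
    seqs <- toupper(unlist(codons))
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named")
    len <- unique(nchar(seqs))
    if (length(len) != 1L)
      stop("sequences differ in length")
    if (len %% 3L != 0L)
      stop("sequence length ", len, " is not divisible by 3")
    starts <- seq(1L, len, 3L)
    codons <- t(vapply(seqs, function(s)
      substring(s, starts, starts + 2L), character(length(starts))))
    if (len == 3L) {  # vapply drops to vector orientation for one codon
      codons <- matrix(codons, ncol = 1L, dimnames = list(names(seqs), NULL))
    }
  }
  codons <- toupper(codons)
  gc <- genetic_code(code)
  ok <- codons %in% gc$codons | codons == GAP_CODON
  amb <- grepl("[^ACGT]", codons) & codons != GAP_CODON
  if (any(!ok & !amb)) {
    off <- codons[!ok & !amb][1]
    if (off %in% gc$stops)
      stop("stop codon ", off, " in alignment; screen sequences with translate_cds() first")
    stop("invalid codon state: ", off)
  }
  codons[amb] <- MISSING_CODON
  structure(list(ids = rownames(codons), codons = codons, code = code),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", nrow(x$codons), " taxa, ", ncol(x$codons),
      " codon sites (genetic code ", x$code, ")\n", sep = "")
  n_gap <- sum(x$codons == GAP_CODON)
  n_mis <- sum(x$codons == MISSING_CODON)
  cat("  gap states: ", n_gap, ", missing states: ", n_mis, "\n", sep = "")
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$codons)

#' Integer state encoding of a codon alignment
#'
#' @param aln A `codon_alignment`.
#' @return Integer matrix (taxa x sites): index into the sense-codon list,
#'   `NA` for gap/missing (fully unknown under the likelihood).
#' @keywords internal
codon_states <- function(aln) {
  gc <- genetic_code(aln$code)
  m <- matrix(match(aln$codons, gc$codons), nrow = nrow(aln$codons),
              dimnames = dimnames(aln$codons))
  m
}

#' Back-translate coding sequences along a protein alignment guide
#'
#' Reconstructs a codon alignment from unaligned in-frame coding sequences
#' and a protein alignment of their translations (the RevTrans procedure):
#' every amino-acid column becomes one codon column, and amino-acid gaps
#' become codon gap tokens. Each coding sequence must translate exactly to
#' its guide row with gaps removed.
#'
#' @param guide Named character vector of aligned amino-acid rows (equal
#'   length, `-` for gaps), or an `AAStringSet`.
#' @param cds Named character vector (or `DNAStringSet`) of in-frame coding
#'   sequences, one per guide row; terminal stops are stripped.
#' @param code Genetic-code id.
#' @return A `codon_alignment` with one column per guide column.
#' @export
back_translate <- function(guide, cds, code = "1") {
  guide <- setNames(as.character(guide), names(guide))
  cds <- setNames(toupper(as.character(cds)), names(cds))
  if (is.null(names(guide)) || is.null(names(cds)))
    stop("guide rows and coding sequences must be named")
  if (!all(names(guide) %in% names(cds)))
    stop("missing coding sequence for: ",
         paste(setdiff(names(guide), names(cds)), collapse = ", "))
  width <- unique(nchar(guide))
  if (length(width) != 1L)
    stop("guide alignment rows differ in length")
  rows <- lapply(names(guide), function(id) {
    aa_row <- strsplit(guide[[id]], "")[[1]]
    seq <- cds[[id]]
    prot <- translate_cds(seq, code)
    ungapped <- paste(aa_row[aa_row != "-"], collapse = "")
    if (prot != ungapped) {
      mism <- which(strsplit(prot, "")[[1]] != strsplit(ungapped, "")[[1]])
      pos <- if (length(mism)) mism[1] else min(nchar(prot), nchar(ungapped)) + 1L
      stop("translation of '", id, "' does not match its guide row ",
           "(first mismatch at ungapped position ", pos, ")")
    }
    starts <- seq(1L, by = 3L, length.out = nchar(prot))
    codons <- substring(seq, starts, starts + 2L)
    out <- rep(GAP_CODON, width)
    out[aa_row != "-"] <- codons
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(guide)
  codon_alignment(m, code = code)
}

#' Drop unusable alignment columns
#'
#' @param aln A `codon_alignment`.
#' @param policy `"all-gap"` removes columns with no sense-codon state;
#'   `"any-gap"` removes columns containing any gap or missing state
#'   (codeml's cleandata behaviour). Both policies are offered because
#'   published analyses rarely state which was used.
#' @return The filtered `codon_alignment`; attribute `"kept"` maps new
#'   column indices to original ones.
#' @export
drop_unusable_columns <- function(aln, policy = c("all-gap", "any-gap")) {
  policy <- match.arg(policy)
  usable <- aln$codons != GAP_CODON & aln$codons != MISSING_CODON
  keep <- if (policy == "all-gap") colSums(usable) > 0L else colSums(usable) == nrow(aln$codons)
  out <- codon_alignment(aln$codons[, keep, drop = FALSE], code = aln$code)
  attr(out, "kept") <- which(keep)
  out
}

#' Read sequences from FASTA
#'
#' Identifiers are the header up to the first whitespace.
#'
#' @param path FASTA file.
#' @param type `"dna"` or `"aa"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readBStringSet(path) else
    Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or a `codon_alignment` (codon states
#'   are concatenated; missing codons written as `NNN`).
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "codon_alignment"))
    seqs <- setNames(apply(seqs$codons, 1L, paste, collapse = ""), seqs$ids)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
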