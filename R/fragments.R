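#' @include AllClasses.R
NULL

#' Construct a peptic peptide fragment
#'
#' @param sequence One-letter amino-acid string (20 standard residues,
#'   upper case).
#' @param name Label; defaults to \code{"start-end"} when a range is given,
#'   otherwise to the sequence itself.
#' @param start,end 1-based inclusive residue range in the parent protein
#'   (optional; must match the sequence length when given).
#' @return A \linkS4class{PeptideFragment}.
#' @examples
#' peptideFragment("DRVYIHPF", name = "angiotensin II")
#' peptideFragment("FERRIGQPTLL", start = 107, end = 117)
#' @export
peptideFragment <- function(sequence, name = NULL, start = NA, end = NA) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- which(!strsplit(sequence, "")[[1]] %in% .AA_ALPHABET)
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 substr(sequence, bad[1], bad[1]), bad[1], sequence))
  if (is.null(name))
    name <- if (!is.na(start)) sprintf("%d-%d", start, end) else sequence
  new("PeptideFragment", name = name, sequence = sequence,
      rangeStart = as.integer(start), rangeEnd = as.integer(end),
      charge = 1L)
}

#' Read a fragment table from CSV/TSV
#'
#' The table lists the peptic fragments to analyze, one per row, with header
#' columns \code{name}, \code{sequence}, \code{start}, \code{end}
#' (\code{start}/\code{end} may be empty). The delimiter (comma or tab) is
#' detected from the header line.
#'
#' @param path Path to the table.
#' @return A list of \linkS4class{PeptideFragment} objects.
#' @export
readFragmentTable <- function(path) {
  if (!file.exists(path)) stop("fragment table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("name", "sequence")
  if (!all(need %in% names(tab)))
    stop("fragment table must have columns 'name' and 'sequence'")
  if (nrow(tab) == 0L) stop("fragment table is empty")
  lapply(seq_len(nrow(tab)), function(i) {
    s <- if ("start" %in% names(tab)) tab$start[i] else NA
    e <- if ("end" %in% names(tab)) tab$end[i] else NA
    peptideFragment(tab$sequence[i], name = as.character(tab$name[i]),
                    start = if (is.na(s) || s == "") NA else as.integer(s),
                    end = if (is.na(e) || e == "") NA else as.integer(e))
  })
}

#' Elemental composition of a neutral peptide
#'
#' Sums the residue formulas of the sequence and adds one water for the
#' termini, giving C/H/N/O/S counts of the neutral (uncharged) peptide.
#'
#' @param fragment A \linkS4class{PeptideFragment}.
#' @return Named integer vector with elements \code{C}, \code{H}, \code{N},
#'   \code{O}, \code{S}.
#' @examples
#' compositionFromSequence(peptideFragment("GG"))  # C4 H8 N2 O3
#' @export
compositionFromSequence <- function(fragment) {
  stopifnot(is(fragment, "PeptideFragment"))
  res <- strsplit(fragment@sequence, "")[[1]]
  counts <- colSums(.RESIDUE_FORMULAS[res, , drop = FALSE])
  counts["H"] <- counts["H"] + 2  # + H2O
  counts["O"] <- counts["O"] + 1
  storage.mode(counts) <- "integer"
  counts
}

#' Monoisotopic mass of a composition or fragment
#'
#' @param x Named integer composition vector (C/H/N/O/S) or a
#'   \linkS4class{PeptideFragment}.
#' @param protonated If TRUE, return the singly protonated ion mass
#'   [M+H]+ rather than the neutral mass.
#' @return Monoisotopic mass in Da.
#' @export
monoisotopicMass <- function(x, protonated = FALSE) {
  if (is(x, "PeptideFragment")) x <- compositionFromSequence(x)
  m <- sum(vapply(names(x), function(el) x[[el]] * .ISOTOPES[[el]]$mass[1],
                  numeric(1)))
  if (protonated) m + .PROTON_MASS else m
}

#' Count exchangeable hydrogen sites of a peptide
#'
#' Partitions the hydrogens of a peptide into the three classes relevant to
#' HDX-MS: exchange-monitored backbone amide hydrogens, fast-exchanging
#' labile side-chain/terminal hydrogens (fully re-equilibrated with solvent
#' at the acid quench), and carbon-bound hydrogens that do not exchange.
#'
#' The amide count follows the standard rule: one amide NH per residue except
#' the N-terminal residue (its nitrogen carries the free amine) and prolines
#' at positions >= 2 (no amide hydrogen). Labile side-chain counts use the
#' neutral-form table (R:4, K:2, H:1, D:1, E:1, S:1, T:1, N:2, Q:2, Y:1, W:1,
#' C:1) plus 2 for the N-terminal amine and 1 for the C-terminal carboxyl.
#'
#' @param fragment A \linkS4class{PeptideFragment}.
#' @return Named integer vector with \code{n_amide}, \code{n_side},
#'   \code{n_fixed}; the three sum to the H count of the neutral composition.
#' @examples
#' countExchangeSites(peptideFragment("DRVYIHPF"))[["n_amide"]]     # 6
#' countExchangeSites(peptideFragment("FERRIGQPTLL"))[["n_amide"]]  # 9
#' @export
countExchangeSites <- function(fragment) {
  stopifnot(is(fragment, "PeptideFragment"))
  res <- strsplit(fragment@sequence, "")[[1]]
  L <- length(res)
  nProInternal <- sum(res[-1] == "P")
  nAmide <- max(0L, L - 1L - nProInternal)
  side <- .LABILE_SIDECHAIN[res]
  nSide <- sum(side, na.rm = TRUE) + .LABILE_NTERM + .LABILE_CTERM
  totalH <- compositionFromSequence(fragment)[["H"]]
  out <- c(n_amide = as.integer(nAmide), n_side = as.integer(nSide),
           n_fixed = as.integer(totalH - nAmide - nSide))
  stopifnot(sum(out) == totalH)  # partition of the neutral-peptide hydrogens
  out
}

#' Construct a composition profile directly
#'
#' Mostly useful for worked examples and for feeding known ground truth to
#' the simulator; deconvolution results are produced by
#' \code{\link{fitComposition}}.
#'
#' @param fractions Numeric vector of length nAmide + 1: element k + 1 is the
#'   fraction of molecules carrying exactly k amide deuteriums. Must be
#'   non-negative; normalized to unit sum.
#' @param nAmide Number of exchangeable amides; defaults to
#'   \code{length(fractions) - 1}.
#' @return A \linkS4class{CompositionProfile}.
#' @examples
#' ## two populations: 6.3% with 5 D, 93.7% with 6 D
#' compositionProfile(c(0, 0, 0, 0, 0, 0.063, 0.937))
#' @export
compositionProfile <- function(fractions, nAmide = length(fractions) - 1L) {
  stopifnot(all(fractions >= 0), sum(fractions) > 0)
  new("CompositionProfile", fractions = fractions / sum(fractions),
      nAmide = as.integer(nAmide))
}
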