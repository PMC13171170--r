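#' Affine gap model
#'
#' Under the default convention a gap of length L costs
#' \code{open + (L-1) * extend}; the alternative convention
#' (\code{"open+L*ext"}), used by some alignment engines, charges
#' \code{open + L * extend}. Terminal gaps are always penalized (true
#' global / Needleman-Wunsch semantics).
#'
#' @param open gap opening penalty (GOP), non-negative.
#' @param extend gap extension penalty (GEP), non-negative.
#' @param convention gap-cost convention, see Details.
#' @return A list of class \code{GapModel}.
#' @export
gapModel <- function(open, extend,
                     convention = c("open+(L-1)ext", "open+L*ext")) {
    convention <- match.arg(convention)
    stopifnot(is.numeric(open), is.numeric(extend),
              length(open) == 1L, length(extend) == 1L,
              open >= 0, extend >= 0)
    structure(list(open = as.numeric(open), extend = as.numeric(extend),
                   convention = convention), class = "GapModel")
}

.as_gap <- function(gaps) {
    if (inherits(gaps, "GapModel")) return(gaps)
    if (is.numeric(gaps) && length(gaps) == 2L)
        return(gapModel(gaps[1], gaps[2]))
    stop("gaps must be a GapModel or c(open, extend)")
}

.residue_index <- function(seq, alphabet, what = "sequence") {
    ch <- strsplit(seq, "")[[1]]
    idx <- match(ch, alphabet)
    if (anyNA(idx)) {
        p <- which(is.na(idx))[1]
        stop(sprintf("%s has residue '%s' at position %d outside the matrix alphabet",
                     what, ch[p], p))
    }
    idx
}

#' Global alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment of two sequences under a substitution
#' matrix and an affine gap model, returning the maximum score and one
#' optimal traceback. Traceback ties are broken deterministically in the
#' order diagonal > gap-in-b > gap-in-a.
#'
#' @param seqA,seqB residue strings over the matrix alphabet.
#' @param matrix a [SubstitutionMatrix-class].
#' @param gaps a [gapModel()] or \code{c(open, extend)}.
#' @return List with \code{score}, \code{alignedA}, \code{alignedB}
#'   (equal-length gapped strings) and \code{columns}.
#' @examples
#' globalAlign("HEAGAWGHEE", "PAWHEAE", standardMatrix("BLOSUM62"),
#'             gapModel(10, 1))
#' @export
globalAlign <- function(seqA, seqB, matrix, gaps) {
    stopifnot(is(matrix, "SubstitutionMatrix"),
              nzchar(seqA), nzchar(seqB))
    gaps <- .as_gap(gaps)
    al <- alphabet(matrix)
    ia <- .residue_index(seqA, al, "seqA")
    ib <- .residue_index(seqB, al, "seqB")
    S <- scores(matrix)[ia, ib, drop = FALSE]
    r <- .gotoh_core(S, gaps$open, gaps$extend,
                     gaps$convention == "open+L*ext")
    ca <- strsplit(seqA, "")[[1]]
    cb <- strsplit(seqB, "")[[1]]
    ixa <- ifelse(r$path_a < 0, NA_integer_, r$path_a + 1L)
    ixb <- ifelse(r$path_b < 0, NA_integer_, r$path_b + 1L)
    outA <- ifelse(is.na(ixa), "-", ca[ixa])
    outB <- ifelse(is.na(ixb), "-", cb[ixb])
    list(score = r$score,
         alignedA = paste(outA, collapse = ""),
         alignedB = paste(outB, collapse = ""),
         columns = length(outA))
}

#' Global alignment score only
#'
#' Faster score-only variant of [globalAlign()] for bulk scoring.
#' @inheritParams globalAlign
#' @return Numeric score.
#' @export
globalAlignScore <- function(seqA, seqB, matrix, gaps) {
    stopifnot(is(matrix, "SubstitutionMatrix"))
    gaps <- .as_gap(gaps)
    al <- alphabet(matrix)
    ia <- .residue_index(seqA, al, "seqA")
    ib <- .residue_index(seqB, al, "seqB")
    S <- scores(matrix)[ia, ib, drop = FALSE]
    .gotoh_score(S, gaps$open, gaps$extend, gaps$convention == "open+L*ext")
}

#' Exact integer scaling of a matrix and gap penalties
#'
#' Finds the smallest positive integer factor that turns every matrix score
#' and both gap penalties into integers (the benchmark penalty grid uses
#' half-integer steps, so the factor is typically 1 or 2). Alignment scores
#' under the scaled system equal factor times the unscaled scores, exactly.
#'
#' @param matrix a [SubstitutionMatrix-class].
#' @param gaps a [gapModel()].
#' @param maxFactor largest factor tried before erroring.
#' @return List with \code{matrix}, \code{gaps} (both scaled, integer) and
#'   \code{factor}.
#' @export
integerScale <- function(matrix, gaps, maxFactor = 1000L) {
    stopifnot(is(matrix, "SubstitutionMatrix"))
    gaps <- .as_gap(gaps)
    vals <- c(as.vector(scores(matrix)), gaps$open, gaps$extend)
    is_int <- function(x) all(abs(x - round(x)) < 1e-9)
    factor <- NA_integer_
    for (f in seq_len(maxFactor)) {
        if (is_int(vals * f)) { factor <- f; break }
    }
    if (is.na(factor))
        stop("no integer scaling factor up to ", maxFactor,
             "; penalties must be rational with a small denominator")
    sm <- SubstitutionMatrix(round(scores(matrix) * factor),
                             name = sprintf("%s x%d", matrixName(matrix),
                                            factor))
    list(matrix = sm,
         gaps = gapModel(gaps$open * factor, gaps$extend * factor,
                         gaps$convention),
         factor = factor)
}

#' Sequence identity from a global alignment
#'
#' Aligns two sequences globally (BLOSUM62, gap open 10, extend 1 by
#' default — the standard identity-filter setting) and returns the fraction
#' of alignment columns with identical residues.
#'
#' @param seqA,seqB residue strings.
#' @param matrix scoring matrix for the alignment.
#' @param gaps gap model.
#' @return Identity fraction in \[0, 1\] (identical columns / all columns).
#' @export
sequenceIdentity <- function(seqA, seqB,
                             matrix = standardMatrix("BLOSUM62"),
                             gaps = gapModel(10, 1)) {
    if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
    r <- globalAlign(seqA, seqB, matrix, gaps)
    a <- strsplit(r$alignedA, "")[[1]]
    b <- strsplit(r$alignedB, "")[[1]]
    mean(a == b & a != "-")
}
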