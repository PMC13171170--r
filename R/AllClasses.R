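#' SubstitutionMatrix: a symmetric amino-acid score table
#'
#' Square, symmetric table of (log-odds) scores over the 20 canonical amino
#' acids in fixed order A R N D C Q E G H I L K M F P S T W Y V. Extended
#' residue codes (B, Z, X, J, *) are dropped when files are loaded.
#'
#' @slot name short label, e.g. "BLOSUM62".
#' @slot alphabet ordered character vector of residue codes.
#' @slot scores numeric matrix, \code{length(alphabet)} square, symmetric.
#' @slot integerValued logical; TRUE when every score is a whole number.
#' @exportClass SubstitutionMatrix
setClass("SubstitutionMatrix",
    representation(name = "character", alphabet = "character",
                   scores = "matrix", integerValued = "logical"))

setValidity("SubstitutionMatrix", function(object) {
    a <- object@alphabet
    s <- object@scores
    if (anyDuplicated(a)) return("alphabet entries must be unique")
    if (!all(a %in% AA_ALPHABET)) {
        return(paste0("non-canonical residue code(s): ",
                      paste(setdiff(a, AA_ALPHABET), collapse = ", ")))
    }
    if (!is.numeric(s) || nrow(s) != length(a) || ncol(s) != length(a))
        return("scores must be a numeric square matrix over the alphabet")
    if (any(!is.finite(s))) return("scores must be finite")
    asym <- which(abs(s - t(s)) > 1e-9, arr.ind = TRUE)
    if (nrow(asym) > 0) {
        i <- asym[1, 1]; j <- asym[1, 2]
        return(sprintf("scores not symmetric: (%s,%s) = %g but (%s,%s) = %g",
                       a[i], a[j], s[i, j], a[j], a[i], s[j, i]))
    }
    if (object@integerValued && any(abs(s - round(s)) > 1e-9))
        return("integerValued is TRUE but scores are not whole numbers")
    TRUE
})

#' WeightedCounts: family-weighted substitution frequencies
#'
#' Symmetric table f of weighted counts over unordered amino-acid pairs.
#' Each aligned column (x, y) contributes its family weight to both
#' f(x, y) and f(y, x), so the unordered-pair mass of (x, y), x != y, is
#' f(x, y) == f(y, x), and the mass of (x, x) is f(x, x).
#'
#' @slot f symmetric non-negative numeric matrix over the canonical alphabet.
#' @slot total total unique-entry mass (sum of weighted columns).
#' @slot nFamilies number of families that contributed counts.
#' @exportClass WeightedCounts
setClass("WeightedCounts",
    representation(f = "matrix", total = "numeric", nFamilies = "integer"))

setValidity("WeightedCounts", function(object) {
    f <- object@f
    if (nrow(f) != 20L || ncol(f) != 20L) return("f must be 20x20")
    if (any(f < 0)) return("counts must be non-negative")
    if (any(abs(f - t(f)) > 1e-9)) return("f must be symmetric")
    TRUE
})

#' UngappedPairBlock: a gap-free aligned sequence pair
#'
#' Two equal-length residue strings observed column-by-column as substitution
#' events, tagged with the family they came from.
#'
#' @slot familyId family label used to look up the family weight.
#' @slot seqA,seqB equal-length ungapped residue strings.
#' @exportClass UngappedPairBlock
setClass("UngappedPairBlock",
    representation(familyId = "character", seqA = "character",
                   seqB = "character"))

setValidity("UngappedPairBlock", function(object) {
    if (length(object@seqA) != 1L || length(object@seqB) != 1L)
        return("seqA and seqB must be single strings")
    if (nchar(object@seqA) != nchar(object@seqB))
        return("seqA and seqB must have equal length")
    if (nchar(object@seqA) < 1L) return("block must have length >= 1")
    ch <- unique(c(strsplit(object@seqA, "")[[1]],
                   strsplit(object@seqB, "")[[1]]))
    bad <- setdiff(ch, AA_ALPHABET)
    if (length(bad) > 0) {
        if (any(bad %in% c("-", ".")))
            return("gap characters are not allowed in an ungapped block")
        return(paste0("non-canonical residue(s): ", paste(bad, collapse = ", ")))
    }
    TRUE
})

#' StructureChain: one protein chain as an ordered CA trace
#'
#' @slot chainId chain identifier.
#' @slot residues one-letter residue codes in file order.
#' @slot coords n x 3 matrix of alpha-carbon coordinates (Angstrom).
#' @slot resno original author residue numbering, kept for reporting.
#' @exportClass StructureChain
setClass("StructureChain",
    representation(chainId = "character", residues = "character",
                   coords = "matrix", resno = "integer"))

setValidity("StructureChain", function(object) {
    n <- length(object@residues)
    if (n < 3L) return("a chain needs at least 3 residues")
    if (nrow(object@coords) != n || ncol(object@coords) != 3L)
        return("coords must be an n x 3 matrix matching residues")
    if (any(!is.finite(object@coords))) return("coordinates must be finite")
    if (length(object@resno) != n) return("resno must match residues")
    TRUE
})

#' Correspondence: monotone residue index pairing between two chains
#'
#' @slot pairs integer matrix with columns indexA, indexB (0-based), both
#'   strictly increasing top to bottom.
#' @slot distances CA-CA distance (Angstrom) per pair after superposition;
#'   may be empty when unknown.
#' @exportClass Correspondence
setClass("Correspondence",
    representation(pairs = "matrix", distances = "numeric"))

setValidity("Correspondence", function(object) {
    p <- object@pairs
    if (ncol(p) != 2L) return("pairs must have two columns")
    if (nrow(p) > 0) {
        if (any(p < 0)) return("indices are 0-based and non-negative")
        if (nrow(p) > 1 && (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) <= 0)))
            return("indices must be strictly increasing in both chains")
    }
    if (length(object@distances) > 0 && length(object@distances) != nrow(p))
        return("distances must be empty or one per pair")
    TRUE
})

#' Msa: a rectangular multiple sequence alignment
#'
#' Rows are equal-length gapped sequences; '-' is the only gap character
#' after normalization ('.' on input is mapped to '-').
#'
#' @slot ids sequence identifiers.
#' @slot rows gapped sequences, all the same width.
#' @exportClass Msa
setClass("Msa", representation(ids = "character", rows = "character"))

setValidity("Msa", function(object) {
    if (length(object@ids) != length(object@rows))
        return("ids and rows must have equal length")
    if (length(object@rows) < 2L) return("an alignment needs >= 2 sequences")
    w <- nchar(object@rows)
    if (length(unique(w)) != 1L)
        return(sprintf("ragged alignment: row '%s' has width %d, expected %d",
                       object@ids[which(w != w[1])[1]],
                       w[which(w != w[1])[1]], w[1]))
    if (any(vapply(strsplit(object@rows, ""), function(x) all(x == "-"),
                   logical(1))))
        return("all-gap rows are not allowed")
    if (anyDuplicated(object@ids)) return("duplicate sequence ids")
    TRUE
})
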