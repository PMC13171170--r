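#' Log-odds estimation parameters
#'
#' @param scaleBits bits per score unit; the default 0.5 gives half-bit
#'   scores, i.e. score = 2 * log2(observed/expected).
#' @param pseudocount non-negative mass added to every unique count cell
#'   before normalization, so that sparse data do not produce -Inf scores.
#'   The default \code{NA} resolves to 1e-6 of the total count mass at
#'   estimation time; set 0 to forbid zero cells outright.
#' @param rounding "nearest" (half away from zero) or "none".
#' @return A list of class \code{LogOddsParams}.
#' @export
logOddsParams <- function(scaleBits = 0.5, pseudocount = NA_real_,
                          rounding = c("nearest", "none")) {
    rounding <- match.arg(rounding)
    stopifnot(scaleBits > 0, is.na(pseudocount) || pseudocount >= 0)
    structure(list(scaleBits = scaleBits, pseudocount = pseudocount,
                   rounding = rounding), class = "LogOddsParams")
}

#' Family weighting factor
#'
#' A family with n members has n(n-1)/2 within-family pairs; weighting each
#' pair by 2/(n(n-1)) makes every family contribute the same total mass per
#' alignment column, regardless of size.
#'
#' @param nMembers number of member proteins, >= 2.
#' @return The weight 2 / (n * (n - 1)).
#' @examples
#' familyWeight(2)    # 1
#' familyWeight(100)  # 2/9900
#' @export
familyWeight <- function(nMembers) {
    stopifnot(length(nMembers) >= 1L)
    if (any(nMembers < 2L))
        stop("a family needs at least 2 members to form a pair")
    2 / (nMembers * (nMembers - 1))
}

#' Create an ungapped pair block
#'
#' @param seqA,seqB equal-length ungapped residue strings.
#' @param familyId family label.
#' @return An [UngappedPairBlock-class].
#' @export
pairBlock <- function(seqA, seqB, familyId = "family") {
    obj <- new("UngappedPairBlock", familyId = as.character(familyId),
               seqA = toupper(seqA), seqB = toupper(seqB))
    validObject(obj)
    obj
}

# ordered count matrix of one block: column (x, y) increments C[x, y]
.block_counts <- function(block) {
    ia <- match(strsplit(block@seqA, "")[[1]], AA_ALPHABET)
    ib <- match(strsplit(block@seqB, "")[[1]], AA_ALPHABET)
    matrix(tabulate((ia - 1L) * 20L + ib, nbins = 400L), 20L, 20L,
           byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))
}

#' Accumulate family-weighted substitution counts
#'
#' Every aligned column of every block contributes its family's weight to the
#' unordered residue pair it shows: the symmetric table f gains w at both
#' \code{[x, y]} and \code{[y, x]} for a mismatch column and w at
#' \code{[x, x]} for a match column. The total mass therefore equals the
#' weighted number of columns.
#'
#' @param blocks list of [UngappedPairBlock-class] objects.
#' @param weights named numeric vector mapping family id to weight
#'   (see [familyWeight()]).
#' @return A [WeightedCounts-class].
#' @examples
#' b <- pairBlock("AR", "RA", "f1")
#' countSubstitutions(list(b), c(f1 = 1))
#' @export
countSubstitutions <- function(blocks, weights) {
    stopifnot(length(blocks) >= 1L, !is.null(names(weights)))
    C <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    fams <- character(0)
    for (b in blocks) {
        stopifnot(is(b, "UngappedPairBlock"))
        if (!(b@familyId %in% names(weights)))
            stop("no weight for family '", b@familyId, "'")
        w <- weights[[b@familyId]]
        C <- C + w * .block_counts(b)
        fams <- c(fams, b@familyId)
    }
    f <- C + t(C)
    diag(f) <- diag(C)
    new("WeightedCounts", f = f, total = sum(C),
        nFamilies = length(unique(fams)))
}

# half-away-from-zero rounding; round() would use banker's rounding
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate a log-odds substitution matrix from weighted counts
#'
#' The classical BLOSUM recipe: normalize the unique-entry counts to observed
#' pair frequencies q, form residue background frequencies
#' p_i = q_ii + sum_j q_ij / 2, expected frequencies e_ii = p_i^2 and
#' e_ij = 2 p_i p_j, and score s_ij = log2(q_ij / e_ij) / scaleBits. With the
#' default scaleBits = 0.5 this is 2 * log2(q/e) — half-bit units — rounded
#' to the nearest integer.
#'
#' @param counts a [WeightedCounts-class] with positive total.
#' @param params a [logOddsParams()].
#' @return A [SubstitutionMatrix-class].
#' @export
estimateLogOdds <- function(counts, params = logOddsParams()) {
    stopifnot(is(counts, "WeightedCounts"))
    if (counts@total <= 0) stop("counts total must be positive")
    f <- counts@f
    pseudo <- params$pseudocount
    if (is.na(pseudo)) pseudo <- 1e-6 * counts@total
    # residues never observed carry no information; their scores stay 0,
    # the log-odds (and the pseudocount) apply to the observed sub-alphabet
    present <- rowSums(f) > 0
    u <- f[present, present, drop = FALSE]
    u[upper.tri(u)] <- u[upper.tri(u)] + pseudo
    diag(u) <- diag(u) + pseudo
    u[lower.tri(u)] <- t(u)[lower.tri(u)]
    uniq <- upper.tri(u, diag = TRUE)
    if (any(u[uniq] <= 0)) {
        bad <- which(u <= 0 & uniq, arr.ind = TRUE)[1, ]
        al <- AA_ALPHABET[present]
        stop(sprintf("zero count for pair (%s,%s) with pseudocount 0",
                     al[bad[1]], al[bad[2]]))
    }
    q <- u / sum(u[uniq])
    p <- diag(q) + (rowSums(q) - diag(q)) / 2
    e <- 2 * outer(p, p)
    diag(e) <- p^2
    s <- log2(q / e) / params$scaleBits
    if (params$rounding == "nearest") s <- .round_half_away(s)
    full <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    full[present, present] <- s
    SubstitutionMatrix(full, name = "log-odds")
}
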