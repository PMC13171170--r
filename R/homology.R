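#' Score all sequence pairs of a labeled dataset
#'
#' Global affine-gap alignment score for every unordered pair, flagged by
#' whether the two entries share a superfamily label. Fractional gap
#' penalties are handled by exact integer scaling ([integerScale()]) before
#' scoring, matching how integer-only alignment engines are driven.
#'
#' @param sequences named character vector of sequences (unique names).
#' @param labels character vector of superfamily labels, parallel to
#'   \code{sequences} (or named by sequence id).
#' @param matrix a [SubstitutionMatrix-class].
#' @param gaps a [gapModel()] or \code{c(open, extend)}.
#' @return data.frame with idA, idB, score, sameSuperfamily; n(n-1)/2 rows.
#' @export
allVsAllScores <- function(sequences, labels, matrix, gaps) {
    n <- length(sequences)
    stopifnot(n >= 2L, !is.null(names(sequences)))
    if (anyDuplicated(names(sequences))) stop("duplicate sequence ids")
    if (!is.null(names(labels))) labels <- labels[names(sequences)]
    stopifnot(length(labels) == n)
    gaps <- .as_gap(gaps)
    sc <- integerScale(matrix, gaps)
    pairs <- utils::combn(n, 2L)
    score <- vapply(seq_len(ncol(pairs)), function(k) {
        globalAlignScore(sequences[[pairs[1, k]]], sequences[[pairs[2, k]]],
                         sc$matrix, sc$gaps) / sc$factor
    }, numeric(1))
    data.frame(idA = names(sequences)[pairs[1, ]],
               idB = names(sequences)[pairs[2, ]],
               score = score,
               sameSuperfamily = labels[pairs[1, ]] == labels[pairs[2, ]],
               stringsAsFactors = FALSE)
}

#' ROC AUC (Mann-Whitney convention)
#'
#' The probability that a uniformly random positive outscores a uniformly
#' random negative, with ties counting one half — equivalently the area
#' under the trapezoidal ROC curve. Invariant under strictly increasing
#' transforms of the scores.
#'
#' @param scores numeric scores, higher = more positive.
#' @param flags logical (or 0/1) class flags.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
rocAuc <- function(scores, flags) {
    flags <- as.logical(flags)
    np <- sum(flags); nn <- sum(!flags)
    if (np == 0L || nn == 0L)
        stop("AUC undefined: need at least one positive and one negative")
    r <- rank(scores)   # ties averaged -> half credit
    (sum(r[flags]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision-recall AUC (average precision)
#'
#' Step-wise integration of the precision-recall curve: sum over score
#' thresholds (descending, tied scores grouped) of the recall increment
#' times the precision at that threshold. This is the conservative
#' step interpolation, not trapezoidal.
#'
#' @inheritParams rocAuc
#' @return AUC in \[0, 1\].
#' @export
prAuc <- function(scores, flags) {
    flags <- as.logical(flags)
    np <- sum(flags)
    if (np == 0L || np == length(flags))
        stop("AUC undefined: need at least one positive and one negative")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; f <- flags[o]
    cum_tp <- cumsum(f)
    cum_n <- seq_along(f)
    # evaluate at the last index of each tied score group
    last <- which(c(s[-1] != s[-length(s)], TRUE))
    prec <- cum_tp[last] / cum_n[last]
    rec <- cum_tp[last] / np
    sum(diff(c(0, rec)) * prec)
}

#' Nearest-neighbor retrieval and micro-averaged one-vs-rest AUC
#'
#' Finds each entry's nearest neighbor (excluding itself) under Euclidean
#' (L2) distance, scores each entry-class combination by the indicator that
#' the retrieved neighbor carries that class label, binarizes the true
#' labels one-vs-rest, and computes a single micro-averaged ROC AUC over the
#' flattened entry x class table.
#'
#' @param vectors numeric matrix, one row per entry (rownames = ids).
#' @param labels class labels, parallel to rows.
#' @return List with \code{neighbors} (data.frame id, neighbor, distance,
#'   labelMatch) and \code{microAuc}.
#' @export
nnRetrievalAuc <- function(vectors, labels) {
    vectors <- as.matrix(vectors)
    n <- nrow(vectors)
    stopifnot(n >= 2L, ncol(vectors) >= 1L, length(labels) == n,
              all(is.finite(vectors)))
    if (length(unique(labels)) < 2L)
        stop("need at least 2 distinct labels")
    if (is.null(rownames(vectors))) rownames(vectors) <- paste0("v", 1:n)
    sq <- rowSums(vectors^2)
    D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(vectors)
    diag(D2) <- Inf
    nn <- max.col(-D2, ties.method = "first")
    nb <- data.frame(id = rownames(vectors),
                     neighbor = rownames(vectors)[nn],
                     distance = sqrt(pmax(D2[cbind(1:n, nn)], 0)),
                     labelMatch = labels[nn] == labels,
                     stringsAsFactors = FALSE)
    classes <- sort(unique(labels))
    pred <- vapply(classes, function(cl) as.numeric(labels[nn] == cl),
                   numeric(n))
    truth <- vapply(classes, function(cl) labels == cl, logical(n))
    list(neighbors = nb,
         microAuc = rocAuc(as.vector(pred), as.vector(truth)))
}
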