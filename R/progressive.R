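# profile = list(ids, rows); column scores between two profiles are mean
# sum-of-pairs substitution scores, gap-residue and gap-gap pairs scoring 0
.profile_counts <- function(rows, alphabet) {
    mat <- do.call(rbind, strsplit(rows, ""))
    apply(mat, 2, function(col) tabulate(match(col, alphabet),
                                         nbins = length(alphabet)))
}

.align_profiles <- function(pa, pb, matrix, gaps) {
    al <- alphabet(matrix)
    CA <- .profile_counts(pa$rows, al)
    CB <- .profile_counts(pb$rows, al)
    if (is.null(dim(CA))) CA <- matrix(CA, ncol = 1)
    if (is.null(dim(CB))) CB <- matrix(CB, ncol = 1)
    nA <- length(pa$rows); nB <- length(pb$rows)
    S <- t(CA) %*% scores(matrix) %*% CB / (nA * nB)
    r <- .gotoh_core(S, gaps$open, gaps$extend,
                     gaps$convention == "open+L*ext")
    expand <- function(rows, path) {
        idx <- ifelse(path < 0, NA_integer_, path + 1L)
        vapply(strsplit(rows, ""), function(x) {
            paste(ifelse(is.na(idx), "-", x[idx]), collapse = "")
        }, character(1))
    }
    list(ids = c(pa$ids, pb$ids),
         rows = c(expand(pa$rows, r$path_a), expand(pb$rows, r$path_b)))
}

#' Progressive multiple alignment
#'
#' Builds a UPGMA guide tree from pairwise identity distances (identity from
#' global alignment under the same matrix and gap model), then merges
#' profiles along the tree with profile-profile global alignment under mean
#' sum-of-pairs column scoring. Deterministic for a fixed input.
#'
#' @param seqs named character vector of >= 2 ungapped sequences.
#' @param matrix a [SubstitutionMatrix-class].
#' @param gaps a [gapModel()] or \code{c(open, extend)}.
#' @return An [Msa-class].
#' @export
progressiveAlign <- function(seqs, matrix, gaps) {
    gaps <- .as_gap(gaps)
    n <- length(seqs)
    if (n < 2L) stop("need at least 2 sequences")
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
    if (n == 2L) {
        r <- globalAlign(seqs[[1]], seqs[[2]], matrix, gaps)
        return(msa(c(r$alignedA, r$alignedB), names(seqs)))
    }
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            D[i, j] <- D[j, i] <-
                1 - sequenceIdentity(seqs[[i]], seqs[[j]], matrix, gaps)
        }
    }
    hc <- hclust(as.dist(D), method = "average")
    profiles <- lapply(seq_len(n), function(i)
        list(ids = names(seqs)[i], rows = unname(seqs[i])))
    merged <- vector("list", n - 1L)
    for (step in seq_len(n - 1L)) {
        pick <- function(k) if (k < 0) profiles[[-k]] else merged[[k]]
        merged[[step]] <- .align_profiles(pick(hc$merge[step, 1]),
                                          pick(hc$merge[step, 2]),
                                          matrix, gaps)
    }
    res <- merged[[n - 1L]]
    ord <- match(names(seqs), res$ids)
    msa(res$rows[ord], res$ids[ord])
}

#' Exhaustive gap-penalty grid search
#'
#' For every (GOP, GEP) cell of the grid, strips each reference alignment of
#' gaps, realigns the sequences (with [progressiveAlign()] or an injected
#' aligner) and scores the result against the reference with [qScore()] and
#' [tcScore()]. Returns the full grid and, per metric, the best cell; exact
#' ties go to the smaller GOP, then the smaller GEP.
#'
#' @param references list of [Msa-class] reference alignments.
#' @param matrix a [SubstitutionMatrix-class].
#' @param gopRange,gepRange numeric vectors of penalties (defaults: GOP 0-10
#'   step 1, GEP 0-5 step 0.5).
#' @param aligner function(seqs, matrix, gaps) returning an [Msa-class];
#'   default [progressiveAlign()].
#' @return List with \code{grid} (data.frame gop, gep, meanQ, meanTC),
#'   \code{bestQ} and \code{bestTC} (rows of the grid).
#' @export
gapGridSearch <- function(references, matrix, gopRange = 0:10,
                          gepRange = seq(0, 5, by = 0.5),
                          aligner = progressiveAlign) {
    stopifnot(length(references) >= 1L)
    if (length(gopRange) == 0L || length(gepRange) == 0L)
        stop("empty penalty range")
    cells <- expand.grid(gep = gepRange, gop = gopRange)[, c("gop", "gep")]
    stripped <- lapply(references, stripGaps)
    res <- lapply(seq_len(nrow(cells)), function(k) {
        g <- gapModel(cells$gop[k], cells$gep[k])
        qs <- tcs <- numeric(length(references))
        for (r in seq_along(references)) {
            test <- aligner(stripped[[r]], matrix, g)
            qs[r] <- qScore(test, references[[r]])
            tcs[r] <- tcScore(test, references[[r]])
        }
        c(meanQ = mean(qs), meanTC = mean(tcs))
    })
    grid <- cbind(cells, do.call(rbind, res))
    # grid rows are ordered gop-major then gep, so which.max's first-hit
    # rule implements the (smaller gop, then smaller gep) tie-break
    ord <- order(grid$gop, grid$gep)
    grid <- grid[ord, ]
    rownames(grid) <- NULL
    list(grid = grid,
         bestQ = grid[which.max(grid$meanQ), ],
         bestTC = grid[which.max(grid$meanTC), ])
}
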