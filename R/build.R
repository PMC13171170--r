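# evaluate code under a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Define a protein family for matrix construction
#'
#' @param familyId label.
#' @param sequences named character vector of member sequences.
#' @param structures optional named list of [StructureChain-class] objects
#'   (names matching \code{sequences}); when present, residue correspondences
#'   are extracted structurally.
#' @return A list of class \code{ProteinFamily}.
#' @export
proteinFamily <- function(familyId, sequences, structures = NULL) {
    stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
    if (!is.null(structures))
        stopifnot(all(names(sequences) %in% names(structures)))
    structure(list(familyId = as.character(familyId),
                   sequences = sequences, structures = structures),
              class = "ProteinFamily")
}

# per-family pipeline: enumerate pairs, identity-filter, extract blocks.
# returns the family's unweighted ordered count matrix and bookkeeping.
.family_blocks <- function(family, identityThreshold, proximityThreshold,
                           identityMatrix, identityGaps) {
    members <- names(family$sequences)
    structural <- !is.null(family$structures)
    if (structural)
        members <- members[members %in% names(family$structures)]
    n <- length(members)
    out <- list(familyId = family$familyId, nMembers = n,
                pairsGenerated = 0L, pairsFiltered = 0L, pairsAligned = 0L,
                blocks = list())
    if (n < 2L) return(out)
    pairs <- utils::combn(members, 2L)
    out$pairsGenerated <- ncol(pairs)
    for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        sid <- sequenceIdentity(family$sequences[[a]], family$sequences[[b]],
                                identityMatrix, identityGaps)
        if (sid > identityThreshold) {
            out$pairsFiltered <- out$pairsFiltered + 1L
            next
        }
        blk <- NULL
        if (structural) {
            co <- extractCorrespondences(family$structures[[a]],
                                         family$structures[[b]],
                                         proximityThreshold = proximityThreshold)
            if (length(co) > 0)
                blk <- pairBlockFromCorrespondence(family$structures[[a]],
                                                   family$structures[[b]],
                                                   co, family$familyId)
        } else if (nchar(family$sequences[[a]]) ==
                   nchar(family$sequences[[b]])) {
            blk <- pairBlock(family$sequences[[a]], family$sequences[[b]],
                             family$familyId)
        } else {
            stop("family '", family$familyId, "': members of unequal length ",
                 "need structures for correspondence extraction")
        }
        if (!is.null(blk)) {
            out$pairsAligned <- out$pairsAligned + 1L
            out$blocks <- c(out$blocks, list(blk))
        }
    }
    out
}

#' Build a substitution matrix from protein families
#'
#' End-to-end estimation: enumerate all within-family member pairs, drop
#' pairs with sequence identity strictly above \code{identityThreshold},
#' extract ungapped residue correspondences (structurally when structures are
#' present, otherwise members must be column-comparable equal-length
#' sequences), weight each family inversely to its pair count
#' (see [familyWeight()]), accumulate weighted counts and convert them to
#' half-bit log-odds scores.
#'
#' @param families list of [proteinFamily()] objects.
#' @param identityThreshold pairs with identity strictly above this are
#'   dropped (default 0.62).
#' @param proximityThreshold CA-CA distance cutoff (Angstrom) for structural
#'   correspondence extraction.
#' @param params a [logOddsParams()].
#' @return List with \code{matrix} (a [SubstitutionMatrix-class]),
#'   \code{counts} (a [WeightedCounts-class]) and \code{report}.
#' @export
buildMatrix <- function(families, identityThreshold = 0.62,
                        proximityThreshold = 5.0,
                        params = logOddsParams()) {
    stopifnot(length(families) >= 1L)
    identityMatrix <- standardMatrix("BLOSUM62")
    identityGaps <- gapModel(10, 1)
    fam_res <- lapply(families, function(fam) {
        if (length(fam$sequences) < 2L) {
            warning("family '", fam$familyId, "' has < 2 members; skipped")
            return(NULL)
        }
        .family_blocks(fam, identityThreshold, proximityThreshold,
                       identityMatrix, identityGaps)
    })
    fam_res <- Filter(Negate(is.null), fam_res)
    used <- Filter(function(fr) length(fr$blocks) > 0, fam_res)
    if (length(used) == 0L)
        stop("empty counts: no pairs survived filtering and alignment")
    weights <- setNames(familyWeight(vapply(used, `[[`, 0L, "nMembers")),
                        vapply(used, `[[`, "", "familyId"))
    counts <- countSubstitutions(unlist(lapply(used, `[[`, "blocks"),
                                        recursive = FALSE), weights)
    report <- list(
        familiesUsed = length(used),
        familiesSkipped = length(families) - length(used),
        pairsGenerated = sum(vapply(fam_res, `[[`, 0L, "pairsGenerated")),
        pairsFiltered = sum(vapply(fam_res, `[[`, 0L, "pairsFiltered")),
        pairsAligned = sum(vapply(fam_res, `[[`, 0L, "pairsAligned")),
        countsTotal = counts@total)
    list(matrix = estimateLogOdds(counts, params), counts = counts,
         report = report)
}

#' Convergence of the matrix with the number of families
#'
#' For each subset size n, draws random family subsets, rebuilds the matrix
#' from each subset, and reports the mean and standard deviation of the total
#' absolute difference (summed over the 210 unique entries) to the matrix
#' built from all families. At full size the difference is 0 with zero
#' variance.
#'
#' @param families list of [proteinFamily()] objects.
#' @param subsetSizes integer sizes, each in 1..length(families).
#' @param replicates random subsets per size.
#' @param seed RNG seed for subset draws.
#' @inheritParams buildMatrix
#' @return data.frame with columns size, mean, sd.
#' @export
convergenceCurve <- function(families, subsetSizes, replicates = 50L,
                             seed = 1L, identityThreshold = 0.62,
                             proximityThreshold = 5.0,
                             params = logOddsParams()) {
    K <- length(families)
    if (any(subsetSizes < 1L) || any(subsetSizes > K))
        stop("subset sizes must be in 1..", K)
    stopifnot(replicates >= 1L)
    identityMatrix <- standardMatrix("BLOSUM62")
    identityGaps <- gapModel(10, 1)
    # per-family weighted count matrices computed once, then re-summed
    fam_counts <- lapply(families, function(fam) {
        fr <- .family_blocks(fam, identityThreshold, proximityThreshold,
                             identityMatrix, identityGaps)
        if (length(fr$blocks) == 0L) return(NULL)
        w <- familyWeight(fr$nMembers)
        C <- Reduce(`+`, lapply(fr$blocks, .block_counts)) * w
        C
    })
    fam_counts <- Filter(Negate(is.null), fam_counts)
    K <- length(fam_counts)
    as_counts <- function(Clist) {
        C <- Reduce(`+`, Clist)
        f <- C + t(C)
        diag(f) <- diag(C)
        new("WeightedCounts", f = f, total = sum(C),
            nFamilies = length(Clist))
    }
    full <- scores(estimateLogOdds(as_counts(fam_counts), params))
    uniq <- upper.tri(full, diag = TRUE)
    .with_seed(seed, {
        res <- lapply(subsetSizes, function(n) {
            d <- vapply(seq_len(replicates), function(r) {
                idx <- sample.int(K, n)
                m <- scores(estimateLogOdds(as_counts(fam_counts[idx]),
                                            params))
                sum(abs(m[uniq] - full[uniq]))
            }, numeric(1))
            s <- if (replicates > 1L) stats::sd(d) else 0
            c(mean = mean(d), sd = s)
        })
        data.frame(size = subsetSizes,
                   mean = vapply(res, `[[`, 0, "mean"),
                   sd = vapply(res, `[[`, 0, "sd"))
    })
}
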