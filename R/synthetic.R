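#' Stationary residue frequency presets
#'
#' @param preset "uniform" (1/20 each) or "skewed" (frequencies decaying
#'   geometrically over the canonical order, exercising marginal handling).
#' @return Named numeric vector over the canonical alphabet, summing to 1.
#' @export
stationaryFrequencies <- function(preset = c("uniform", "skewed")) {
    preset <- match.arg(preset)
    p <- switch(preset,
                uniform = rep(1 / 20, 20),
                skewed = { w <- 0.92^(0:19); w / sum(w) })
    setNames(p, AA_ALPHABET)
}

#' A column-wise substitution process with closed-form log-odds
#'
#' The joint residue-pair distribution per aligned column is a direct
#' interpolation between perfect conservation and independence:
#' \deqn{Q = (1 - d) diag(p) + d (p p^T)}
#' so both marginals equal p at every divergence, d = 0 gives the diagonal
#' (identical sequences) and d = 1 statistical independence. The implied
#' half-bit log-odds matrix is available in closed form via
#' [analyticLogOdds()], which is what makes exact parameter-recovery tests
#' possible.
#'
#' @param divergence d in \[0, 1\].
#' @param frequencies stationary residue frequencies p (sum 1).
#' @return List of class \code{SubstitutionProcess} with elements
#'   \code{p}, \code{d}, \code{Q}.
#' @export
substitutionProcess <- function(divergence,
                                frequencies = stationaryFrequencies()) {
    stopifnot(divergence >= 0, divergence <= 1,
              length(frequencies) == 20L, all(frequencies > 0),
              abs(sum(frequencies) - 1) < 1e-9)
    p <- setNames(as.numeric(frequencies), AA_ALPHABET)
    Q <- (1 - divergence) * diag(p) + divergence * outer(p, p)
    dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
    structure(list(p = p, d = divergence, Q = Q),
              class = "SubstitutionProcess")
}

#' Process governing pairs of family members
#'
#' Family members are drawn independently given a latent ancestor column, so
#' the joint distribution of a member pair is the process composed with
#' itself; under the interpolation parameterization that is again an
#' interpolation process with divergence \code{1 - (1 - d)^2}.
#'
#' @param process a [substitutionProcess()].
#' @return The member-pair \code{SubstitutionProcess}.
#' @export
pairProcess <- function(process) {
    stopifnot(inherits(process, "SubstitutionProcess"))
    substitutionProcess(1 - (1 - process$d)^2, process$p)
}

#' Closed-form half-bit log-odds of a substitution process
#'
#' Applies the same observed/expected log-odds recipe as
#' [estimateLogOdds()] to the exact pair distribution Q instead of counts:
#' the target that estimation from simulated data must recover.
#'
#' @param process a [substitutionProcess()] (use [pairProcess()] for the
#'   matrix implied between family members).
#' @param params a [logOddsParams()].
#' @return A [SubstitutionMatrix-class].
#' @export
analyticLogOdds <- function(process, params = logOddsParams(pseudocount = 0)) {
    stopifnot(inherits(process, "SubstitutionProcess"))
    Q <- process$Q
    if (any(Q[upper.tri(Q, diag = TRUE)] <= 0))
        stop("process has zero-probability pairs; log-odds undefined")
    # unordered-pair masses: q_ii = Q_ii, q_ij = 2 Q_ij
    q <- 2 * Q
    diag(q) <- diag(Q)
    p <- process$p
    e <- 2 * outer(p, p)
    diag(e) <- p^2
    s <- log2(q / e) / params$scaleBits
    if (params$rounding == "nearest") s <- .round_half_away(s)
    SubstitutionMatrix(s, name = sprintf("analytic d=%.3g", process$d))
}

.draw_residues <- function(n, prob) {
    AA_ALPHABET[sample.int(20L, n, replace = TRUE, prob = prob)]
}

#' Simulate a homologous protein family
#'
#' Draws an ancestor sequence from the stationary frequencies, then each
#' member column-by-column from the conditional of Q given the ancestor
#' residue. All members have the same length, so raw member pairs are
#' directly column-comparable ungapped blocks.
#'
#' @param nMembers number of members (>= 2).
#' @param length sequence length.
#' @param process a [substitutionProcess()].
#' @param seed RNG seed.
#' @param familyId label.
#' @return List of class \code{ToyFamily}: \code{family} (a
#'   [proteinFamily()]), \code{ancestor}, \code{process}, and
#'   \code{pairProcess} (the member-pair process whose [analyticLogOdds()]
#'   estimation should recover).
#' @export
simulateFamily <- function(nMembers, length, process, seed = 1L,
                           familyId = "fam1") {
    stopifnot(nMembers >= 2L, length >= 1L,
              inherits(process, "SubstitutionProcess"))
    .with_seed(seed, {
        anc_idx <- sample.int(20L, length, replace = TRUE, prob = process$p)
        # conditional of Q given ancestor a: (1-d) delta_a + d p
        members <- vapply(seq_len(nMembers), function(k) {
            mut <- runif(length) < process$d
            idx <- anc_idx
            if (any(mut))
                idx[mut] <- sample.int(20L, sum(mut), replace = TRUE,
                                       prob = process$p)
            paste(AA_ALPHABET[idx], collapse = "")
        }, character(1))
        names(members) <- paste0("m", seq_len(nMembers))
        structure(list(
            family = proteinFamily(familyId, members),
            ancestor = paste(AA_ALPHABET[anc_idx], collapse = ""),
            process = process,
            pairProcess = pairProcess(process)), class = "ToyFamily")
    })
}

# ideal helical CA trace with exactly 3.8 A between consecutive residues
.helix_coords <- function(n, rise = 1.5, turn_deg = 100) {
    radius <- sqrt(3.8^2 - rise^2) / (2 * sin(turn_deg / 2 * pi / 180))
    t <- seq_len(n) - 1L
    ang <- t * turn_deg * pi / 180
    cbind(radius * cos(ang), radius * sin(ang), rise * t)
}

.random_rotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
}

#' Simulate a pair of homologous toy structures
#'
#' The base chain lies on a regular helical curve with 3.8 Angstrom between
#' consecutive alpha-carbons; the homolog is a copy with a contiguous run of
#' residues deleted, Gaussian coordinate noise added, and a random rigid
#' motion applied. The true residue correspondence is recorded.
#'
#' @param length residues in the base chain.
#' @param deletionRun length of the contiguous deletion in the homolog
#'   (0 = none); must be < length - 3.
#' @param coordinateNoiseSd isotropic Gaussian noise sd (Angstrom).
#' @param seed RNG seed.
#' @return List with \code{chainA}, \code{chainB}
#'   ([StructureChain-class]) and \code{truth} (a [Correspondence-class]
#'   mapping A indices to B indices).
#' @export
simulateStructurePair <- function(length, deletionRun = 0L,
                                  coordinateNoiseSd = 0, seed = 1L) {
    stopifnot(length >= 6L, deletionRun >= 0L, deletionRun < length - 3L)
    .with_seed(seed, {
        res <- .draw_residues(length, rep(1 / 20, 20))
        xyz <- .helix_coords(length)
        keep <- seq_len(length)
        if (deletionRun > 0L) {
            start <- sample.int(length - deletionRun + 1L, 1L)
            keep <- setdiff(keep, start:(start + deletionRun - 1L))
        }
        xyzB <- xyz[keep, , drop = FALSE]
        if (coordinateNoiseSd > 0)
            xyzB <- xyzB + matrix(rnorm(length(xyzB), sd = coordinateNoiseSd),
                                  ncol = 3)
        R <- .random_rotation()
        tr <- runif(3, -20, 20)
        xyzB <- sweep(xyzB %*% t(R), 2, tr, `+`)
        truth <- new("Correspondence",
                     pairs = cbind(keep - 1L, seq_along(keep) - 1L),
                     distances = numeric(0))
        list(chainA = structureChain(res, xyz, "A"),
             chainB = structureChain(res[keep], xyzB, "B"),
             truth = truth)
    })
}

#' Simulate a reference alignment with known truth
#'
#' Columns are drawn from the substitution process (members conditionally on
#' a latent ancestor residue, as in [simulateFamily()]); gaps are then
#' punched independently per cell with probability \code{gapRate}. The
#' returned alignment is the ground truth that realignment should recover.
#'
#' @param n sequences.
#' @param length alignment columns.
#' @param gapRate per-cell gap probability in \[0, 1).
#' @param process a [substitutionProcess()].
#' @param seed RNG seed.
#' @return List with \code{msa} (an [Msa-class]) and \code{sequences}
#'   (gap-stripped rows).
#' @export
simulateReferenceMsa <- function(n, length, gapRate, process, seed = 1L) {
    stopifnot(n >= 2L, length >= 2L, gapRate >= 0, gapRate < 1,
              inherits(process, "SubstitutionProcess"))
    .with_seed(seed, {
        anc <- sample.int(20L, length, replace = TRUE, prob = process$p)
        rows <- vapply(seq_len(n), function(k) {
            mut <- runif(length) < process$d
            idx <- anc
            if (any(mut))
                idx[mut] <- sample.int(20L, sum(mut), replace = TRUE,
                                       prob = process$p)
            ch <- AA_ALPHABET[idx]
            gap <- runif(length) < gapRate
            if (all(gap)) gap[1] <- FALSE   # forbid all-gap rows
            ch[gap] <- "-"
            paste(ch, collapse = "")
        }, character(1))
        m <- msa(rows)
        list(msa = m, sequences = stripGaps(m))
    })
}

#' Simulate labeled pair scores
#'
#' Positive scores from N(separation, 1), negatives from N(0, 1).
#'
#' @param nPos,nNeg counts (>= 1).
#' @param separation positive-negative mean separation in sd units.
#' @param seed RNG seed.
#' @return data.frame with score and flag columns.
#' @export
simulateLabeledScores <- function(nPos, nNeg, separation, seed = 1L) {
    stopifnot(nPos >= 1L, nNeg >= 1L)
    .with_seed(seed, {
        data.frame(score = c(rnorm(nPos, mean = separation), rnorm(nNeg)),
                   flag = rep(c(TRUE, FALSE), c(nPos, nNeg)))
    })
}

#' Simulate labeled vector clusters
#'
#' One Gaussian cluster per label, centers 10 units apart along orthogonal
#' axes, isotropic noise \code{clusterSd}.
#'
#' @param nPerLabel vectors per label.
#' @param labels label names.
#' @param clusterSd cluster standard deviation (0 = identical vectors).
#' @param seed RNG seed.
#' @return List with \code{vectors} (matrix, rownames = ids) and
#'   \code{labels}.
#' @export
simulateVectors <- function(nPerLabel, labels, clusterSd = 1, seed = 1L) {
    stopifnot(nPerLabel >= 1L, length(labels) >= 2L)
    k <- length(labels)
    dim <- max(2L, k)
    .with_seed(seed, {
        V <- do.call(rbind, lapply(seq_len(k), function(i) {
            center <- rep(0, dim); center[i] <- 10
            matrix(rnorm(nPerLabel * dim, sd = clusterSd),
                   ncol = dim) + rep(center, each = nPerLabel)
        }))
        rownames(V) <- paste0(rep(labels, each = nPerLabel), "_",
                              rep(seq_len(nPerLabel), k))
        list(vectors = V, labels = rep(labels, each = nPerLabel))
    })
}
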