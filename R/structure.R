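#' Construct a StructureChain from residues and CA coordinates
#'
#' @param residues one-letter residue codes.
#' @param coords n x 3 matrix of alpha-carbon coordinates (Angstrom).
#' @param chainId chain label.
#' @param resno author residue numbering (defaults to 1..n).
#' @return A [StructureChain-class].
#' @export
structureChain <- function(residues, coords, chainId = "A", resno = NULL) {
    if (is.null(resno)) resno <- seq_along(residues)
    obj <- new("StructureChain", chainId = as.character(chainId),
               residues = toupper(residues),
               coords = as.matrix(coords), resno = as.integer(resno))
    validObject(obj)
    obj
}

#' Read one chain from a PDB or mmCIF file as a CA trace
#'
#' Keeps one alpha-carbon per residue (first altloc); residues without an
#' alpha-carbon are dropped with a warning, as are residues whose code does
#' not map to the canonical 20.
#'
#' @param file path to a .pdb or .cif file.
#' @param chain chain identifier; default: the first chain in the file.
#' @return A [StructureChain-class].
#' @export
readChain <- function(file, chain = NULL) {
    is_cif <- grepl("\\.cif(\\.gz)?$", file, ignore.case = TRUE)
    pdb <- if (is_cif) bio3d::read.cif(file) else bio3d::read.pdb(file)
    at <- pdb$atom
    if (is.null(chain)) chain <- at$chain[1]
    sel <- at[at$chain == chain, , drop = FALSE]
    if (nrow(sel) == 0) stop("chain '", chain, "' not found in ", file)
    reskey <- paste(sel$resno, sel$insert)
    n_res <- length(unique(reskey))
    ca <- sel[sel$elety == "CA", , drop = FALSE]
    ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
    if (nrow(ca) < n_res)
        warning(n_res - nrow(ca), " residue(s) without an alpha-carbon ",
                "dropped from chain ", chain)
    res1 <- bio3d::aa321(ca$resid)
    ok <- res1 %in% AA_ALPHABET
    if (any(!ok))
        warning(sum(!ok), " non-canonical residue(s) dropped from chain ",
                chain)
    ca <- ca[ok, , drop = FALSE]
    if (nrow(ca) < 3L) stop("chain '", chain, "' has < 3 usable residues")
    structureChain(res1[ok], cbind(ca$x, ca$y, ca$z), chainId = chain,
                   resno = ca$resno)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation and translation mapping the paired
#' residues of \code{chainB} onto \code{chainA}.
#'
#' @param chainA,chainB [StructureChain-class] objects.
#' @param pairs a [Correspondence-class] with >= 3 pairs.
#' @return List of class \code{RigidTransform} with \code{rotation} (3x3,
#'   det +1), \code{translation}, \code{rmsd} (Angstrom over the fitted
#'   pairs) and \code{degenerate} (TRUE when the point sets are rank
#'   deficient, e.g. collinear).
#' @export
kabschSuperpose <- function(chainA, chainB, pairs) {
    stopifnot(is(chainA, "StructureChain"), is(chainB, "StructureChain"),
              is(pairs, "Correspondence"))
    if (nrow(pairs@pairs) < 3L)
        stop("at least 3 pairs are required for superposition")
    X <- chainA@coords[pairs@pairs[, 1] + 1L, , drop = FALSE]
    Y <- chainB@coords[pairs@pairs[, 2] + 1L, , drop = FALSE]
    xc <- colMeans(X); yc <- colMeans(Y)
    Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
    H <- t(Yc) %*% Xc
    sv <- svd(H)
    degenerate <- sv$d[3] < 1e-8 * max(sv$d[1], 1e-300)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tr <- xc - as.vector(R %*% yc)
    fitted <- Yc %*% t(R)
    rmsd <- sqrt(mean(rowSums((Xc - fitted)^2)))
    structure(list(rotation = R, translation = tr, rmsd = rmsd,
                   degenerate = degenerate), class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
    cat(sprintf("RigidTransform: rmsd %.4f A%s\n", x$rmsd,
                if (x$degenerate) " (degenerate point set)" else ""))
    invisible(x)
}

.apply_transform <- function(coords, tf) {
    sweep(coords %*% t(tf$rotation), 2, tf$translation, `+`)
}

# longest strictly-monotone subset of (ia, ib) pairs; among equal-length
# solutions the one with the smaller total distance wins
.monotone_prune <- function(ia, ib, dist) {
    o <- order(ia)
    ia <- ia[o]; ib <- ib[o]; dist <- dist[o]
    n <- length(ia)
    if (n == 0L) return(integer(0))
    len <- rep(1L, n); tot <- dist; prev <- rep(0L, n)
    for (i in seq_len(n)) {
        for (j in seq_len(i - 1L)) {
            if (ib[j] < ib[i] && ia[j] < ia[i]) {
                cand_len <- len[j] + 1L
                cand_tot <- tot[j] + dist[i]
                if (cand_len > len[i] ||
                    (cand_len == len[i] && cand_tot < tot[i])) {
                    len[i] <- cand_len; tot[i] <- cand_tot; prev[i] <- j
                }
            }
        }
    }
    best <- which(len == max(len))
    best <- best[which.min(tot[best])]
    path <- integer(0)
    while (best != 0L) { path <- c(best, path); best <- prev[best] }
    o[path]
}

#' Extract residue correspondences between two chains
#'
#' Iterative superposition-reassignment: (1) seed the pairing with a global
#' sequence alignment under the identity matrix (unit 1/0), so that no
#' substitution-matrix knowledge enters the structural stage; (2) superpose
#' with [kabschSuperpose()] on the current pairs; (3) re-pair residues as
#' mutual nearest alpha-carbon neighbors within \code{proximityThreshold},
#' pruned to the longest strictly-monotone subset (ties to the smaller
#' distance); repeat until the pair set is stable or \code{maxIters}.
#'
#' @param chainA,chainB [StructureChain-class] objects (>= 3 residues).
#' @param proximityThreshold CA-CA distance cutoff in Angstrom.
#' @param maxIters iteration cap.
#' @return A [Correspondence-class]; empty when no residues pair up within
#'   the threshold.
#' @export
extractCorrespondences <- function(chainA, chainB, proximityThreshold = 5.0,
                                   maxIters = 20L) {
    stopifnot(is(chainA, "StructureChain"), is(chainB, "StructureChain"))
    seqA <- paste(chainA@residues, collapse = "")
    seqB <- paste(chainB@residues, collapse = "")
    aln <- globalAlign(seqA, seqB, unitMatrix(1, 0), gapModel(1, 0.5))
    ca <- strsplit(aln$alignedA, "")[[1]]
    cb <- strsplit(aln$alignedB, "")[[1]]
    posA <- cumsum(ca != "-") - 1L
    posB <- cumsum(cb != "-") - 1L
    both <- ca != "-" & cb != "-"
    cur <- cbind(posA[both], posB[both])
    if (nrow(cur) < 3L) {
        n <- min(length(chainA), length(chainB))
        cur <- cbind(seq_len(n) - 1L, seq_len(n) - 1L)
    }
    dist_kept <- numeric(0)
    for (it in seq_len(maxIters)) {
        tf <- kabschSuperpose(chainA, chainB,
                              new("Correspondence", pairs = cur,
                                  distances = numeric(0)))
        Bt <- .apply_transform(chainB@coords, tf)
        # all-pairs CA distances after superposition
        D <- sqrt(pmax(outer(rowSums(chainA@coords^2), rowSums(Bt^2), `+`) -
                       2 * chainA@coords %*% t(Bt), 0))
        nnB <- max.col(-D, ties.method = "first")        # per A row
        nnA <- max.col(-t(D), ties.method = "first")     # per B row
        ia <- which(nnA[nnB] == seq_len(nrow(D)))
        ib <- nnB[ia]
        d <- D[cbind(ia, ib)]
        keep <- d <= proximityThreshold
        ia <- ia[keep]; ib <- ib[keep]; d <- d[keep]
        if (length(ia) == 0L)
            return(new("Correspondence",
                       pairs = matrix(integer(0), 0, 2),
                       distances = numeric(0)))
        sel <- .monotone_prune(ia, ib, d)
        nxt <- cbind(ia[sel] - 1L, ib[sel] - 1L)
        dist_kept <- d[sel]
        if (nrow(nxt) == nrow(cur) && all(nxt == cur)) break
        cur <- nxt
        if (nrow(cur) < 3L) break
    }
    new("Correspondence", pairs = cur, distances = dist_kept)
}

#' Ungapped pair block from a structural correspondence
#'
#' @param chainA,chainB [StructureChain-class] objects.
#' @param corr a non-empty [Correspondence-class].
#' @param familyId family label for the block.
#' @return An [UngappedPairBlock-class] of length \code{length(corr)}.
#' @export
pairBlockFromCorrespondence <- function(chainA, chainB, corr,
                                        familyId = "family") {
    stopifnot(is(corr, "Correspondence"))
    if (nrow(corr@pairs) == 0L) stop("empty correspondence")
    pairBlock(paste(chainA@residues[corr@pairs[, 1] + 1L], collapse = ""),
              paste(chainB@residues[corr@pairs[, 2] + 1L], collapse = ""),
              familyId)
}

#' Write a StructureChain as a minimal PDB file (CA trace)
#'
#' @param chain a [StructureChain-class].
#' @param file path.
#' @export
writeChainPdb <- function(chain, file) {
    stopifnot(is(chain, "StructureChain"))
    res3 <- bio3d::aa123(chain@residues)
    lines <- sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_along(res3), res3, substr(chain@chainId, 1, 1), chain@resno,
        chain@coords[, 1], chain@coords[, 2], chain@coords[, 3])
    writeLines(c(lines, "END"), file)
    invisible(file)
}

#' Read / write a correspondence as TSV
#'
#' The TSV dialect has columns \code{index_a}, \code{index_b} (0-based) and
#' optionally \code{distance} (Angstrom); external structural aligners can
#' inject their correspondences through this format.
#'
#' @param file path.
#' @return [Correspondence-class] for the reader.
#' @export
readCorrespondence <- function(file) {
    d <- read.table(file, header = TRUE, sep = "\t")
    new("Correspondence",
        pairs = cbind(as.integer(d$index_a), as.integer(d$index_b)),
        distances = if ("distance" %in% names(d)) as.numeric(d$distance)
                    else numeric(0))
}

#' @rdname readCorrespondence
#' @param corr a [Correspondence-class].
#' @export
writeCorrespondence <- function(corr, file) {
    stopifnot(is(corr, "Correspondence"))
    d <- data.frame(index_a = corr@pairs[, 1], index_b = corr@pairs[, 2])
    if (length(corr@distances) > 0) d$distance <- corr@distances
    utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(file)
}
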