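#' Construct a SubstitutionMatrix from a score table
#'
#' Low-level constructor; most users will call [loadMatrix()],
#' [standardMatrix()] or [unitMatrix()].
#'
#' @param scores square numeric matrix with residue dimnames.
#' @param name label.
#' @return A [SubstitutionMatrix-class] restricted to the canonical 20
#'   residues in canonical order.
#' @export
SubstitutionMatrix <- function(scores, name = "matrix") {
    stopifnot(is.matrix(scores), !is.null(rownames(scores)),
              !is.null(colnames(scores)))
    keep <- intersect(AA_ALPHABET, rownames(scores))
    missing <- setdiff(AA_ALPHABET, rownames(scores))
    if (length(missing) > 0)
        stop("matrix is missing canonical residue(s): ",
             paste(missing, collapse = ", "))
    s <- scores[AA_ALPHABET, AA_ALPHABET, drop = FALSE]
    storage.mode(s) <- "double"
    obj <- new("SubstitutionMatrix", name = name, alphabet = AA_ALPHABET,
               scores = s,
               integerValued = all(abs(s - round(s)) < 1e-9))
    validObject(obj)
    obj
}

#' Read an NCBI-style substitution matrix file
#'
#' Parses the whitespace-delimited table format used by NCBI and EMBOSS: '#'
#' comment lines, a header row of residue codes, then one labeled row per
#' residue. Extended codes (B, Z, X, J, *, and anything else outside the
#' canonical 20) are dropped; the result is restricted to the canonical
#' alphabet in canonical order and checked for symmetry.
#'
#' @param file path to the matrix file, or a character vector of lines.
#' @param name label; defaults to the file base name.
#' @return A [SubstitutionMatrix-class].
#' @examples
#' b62 <- standardMatrix("BLOSUM62")
#' scores(b62)["A", "A"]   # 4
#' @export
loadMatrix <- function(file, name = NULL) {
    lines <- if (length(file) == 1L && file.exists(file)) {
        if (is.null(name))
            name <- sub("\\.[^.]*$", "", basename(file))
        readLines(file)
    } else as.character(file)
    if (is.null(name)) name <- "matrix"
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("not a matrix file: no header/data rows")
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    labels <- vapply(rows, `[`, character(1), 1L)
    vals <- lapply(rows, function(r) {
        v <- suppressWarnings(as.numeric(r[-1]))
        if (anyNA(v) || length(v) != length(header))
            stop("malformed matrix row for residue '", r[1], "'")
        v
    })
    m <- do.call(rbind, vals)
    dimnames(m) <- list(toupper(labels), toupper(header))
    # symmetry is checked over the full parsed table before restriction
    common <- intersect(rownames(m), colnames(m))
    mm <- m[common, common, drop = FALSE]
    asym <- which(abs(mm - t(mm)) > 1e-9, arr.ind = TRUE)
    if (nrow(asym) > 0) {
        i <- asym[1, 1]; j <- asym[1, 2]
        stop(sprintf(
            "asymmetric matrix: (%s,%s) = %g but (%s,%s) = %g",
            common[i], common[j], mm[i, j], common[j], common[i], mm[j, i]))
    }
    SubstitutionMatrix(m, name = name)
}

#' Write a SubstitutionMatrix as an NCBI-style table
#'
#' Integer matrices round-trip bit-exactly through [loadMatrix()];
#' real-valued matrices are rendered with 4 decimals.
#'
#' @param m a [SubstitutionMatrix-class].
#' @param file path, or NULL to return the lines invisibly.
#' @return The text lines, invisibly when written to a file.
#' @export
writeMatrix <- function(m, file = NULL) {
    stopifnot(is(m, "SubstitutionMatrix"))
    a <- m@alphabet
    fmt <- if (m@integerValued) "%d" else "%.4f"
    cell <- function(v) {
        if (m@integerValued) sprintf("%4d", as.integer(round(v)))
        else sprintf("%9.4f", v)
    }
    wid <- if (m@integerValued) 4L else 9L
    out <- c(paste0("# ", m@name),
             paste0(" ", paste(formatC(a, width = wid), collapse = "")),
             vapply(seq_along(a), function(i) {
                 paste0(a[i], paste(cell(m@scores[i, ]), collapse = ""))
             }, character(1)))
    if (is.null(file)) return(out)
    writeLines(out, file)
    invisible(out)
}

#' Baseline unit matrix
#'
#' A matrix carrying no substitution preference: one score for matches
#' (diagonal) and one for all mismatches. The baseline matrices 5/0 and 5/-1
#' use a match score of 5 to mimic the average conservation signal of
#' BLOSUM62; 1/0 is the plain identity indicator.
#'
#' @param match diagonal score.
#' @param mismatch off-diagonal score.
#' @return A [SubstitutionMatrix-class].
#' @examples
#' unitMatrix(5, -1)
#' @export
unitMatrix <- function(match, mismatch) {
    s <- matrix(mismatch, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    diag(s) <- match
    SubstitutionMatrix(s, name = sprintf("unit %g/%g", match, mismatch))
}

#' Embedded standard matrices
#'
#' Returns one of the standard published matrices shipped with the package in
#' its commonly distributed NCBI integer version.
#'
#' @param name one of "BLOSUM45", "BLOSUM62", "BLOSUM80", "PAM120", "PAM250".
#' @return A [SubstitutionMatrix-class].
#' @export
standardMatrix <- function(name = c("BLOSUM62", "BLOSUM45", "BLOSUM80",
                                    "PAM120", "PAM250")) {
    name <- match.arg(name)
    f <- system.file("extdata", "matrices", paste0(name, ".txt"),
                     package = "submatkit", mustWork = TRUE)
    loadMatrix(f, name = name)
}

.vectorize <- function(m, vectorization) {
    s <- scores(m)
    switch(vectorization,
           full = as.vector(s),
           unique = s[upper.tri(s, diag = TRUE)],
           stop("vectorization must be 'full' or 'unique'"))
}

#' Pearson correlation between two substitution matrices
#'
#' Correlation of the two score tables vectorized either over all 400 entries
#' ("full", the default — this is the whole-matrix convention that reproduces
#' the published correlation-to-BLOSUM62 figures) or over the 210 unique
#' entries of the upper triangle including the diagonal ("unique").
#'
#' @param a,b [SubstitutionMatrix-class] objects over the same alphabet.
#' @param vectorization "full" (400 entries) or "unique" (210 entries).
#' @return Correlation in \[-1, 1\].
#' @examples
#' matrixCorrelation(unitMatrix(1, 0), standardMatrix("BLOSUM62"))  # ~0.72
#' @export
matrixCorrelation <- function(a, b, vectorization = c("full", "unique")) {
    vectorization <- match.arg(vectorization)
    stopifnot(is(a, "SubstitutionMatrix"), is(b, "SubstitutionMatrix"))
    if (!identical(alphabet(a), alphabet(b)))
        stop("matrices must share the same alphabet")
    va <- .vectorize(a, vectorization)
    vb <- .vectorize(b, vectorization)
    if (length(unique(va)) < 2L || length(unique(vb)) < 2L)
        stop("correlation undefined: matrix '",
             if (length(unique(va)) < 2L) a@name else b@name,
             "' is constant")
    cor(va, vb)
}

#' Evolutionary distance of a substitution matrix
#'
#' The absolute value of the mean diagonal (match) score divided by the mean
#' off-diagonal (mismatch) score. Larger values indicate a matrix tuned for
#' more divergent sequences. Invariant to uniform positive rescaling.
#' Undefined (NA) when the mean off-diagonal score is exactly zero, as for
#' the unit matrix 5/0.
#'
#' @param m a [SubstitutionMatrix-class].
#' @return Positive real, or NA when undefined.
#' @examples
#' evolutionaryDistance(standardMatrix("BLOSUM62"))  # ~4.1
#' evolutionaryDistance(unitMatrix(5, -1))           # 5
#' @export
evolutionaryDistance <- function(m) {
    stopifnot(is(m, "SubstitutionMatrix"))
    s <- scores(m)
    d <- mean(diag(s))
    o <- mean(s[row(s) != col(s)])
    if (o == 0) return(NA_real_)
    abs(d / o)
}

#' Fraction of identical unique entries between two integer matrices
#'
#' Compares the 210 unique entries (upper triangle including diagonal) of two
#' integer-valued matrices and returns the fraction that agree exactly.
#'
#' @param a,b integer-valued [SubstitutionMatrix-class] objects over the same
#'   alphabet.
#' @return Fraction in \[0, 1\].
#' @export
identicalFraction <- function(a, b) {
    stopifnot(is(a, "SubstitutionMatrix"), is(b, "SubstitutionMatrix"))
    if (!identical(alphabet(a), alphabet(b)))
        stop("matrices must share the same alphabet")
    if (!a@integerValued || !b@integerValued)
        stop("identicalFraction is defined for integer-valued matrices only")
    va <- .vectorize(a, "unique")
    vb <- .vectorize(b, "unique")
    mean(round(va) == round(vb))
}

#' Principal component projection of a set of matrices
#'
#' Each matrix is vectorized over its 210 unique entries; the vectors are
#' mean-centered and projected onto the top two principal components.
#'
#' @param ms list of [SubstitutionMatrix-class] objects over a common
#'   alphabet.
#' @return List with \code{coordinates} (one row per matrix, columns PC1,
#'   PC2) and \code{explained} (variance fractions, non-increasing).
#' @export
matrixPCA <- function(ms) {
    if (length(ms) < 2L) stop("need at least 2 matrices for PCA")
    al <- alphabet(ms[[1]])
    if (!all(vapply(ms, function(m) identical(alphabet(m), al), logical(1))))
        stop("matrices must share a common alphabet")
    X <- t(vapply(ms, .vectorize, numeric(210L), vectorization = "unique"))
    rownames(X) <- vapply(ms, matrixName, character(1))
    p <- prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(p$x))
    coords <- p$x[, seq_len(k), drop = FALSE]
    if (k < 2L) coords <- cbind(coords, PC2 = 0)
    ev <- p$sdev^2
    list(coordinates = coords[, 1:2, drop = FALSE],
         explained = (ev / sum(ev))[1:2])
}

#' Summary statistics of a matrix against a reference
#'
#' @param m matrix to summarize.
#' @param reference reference matrix (conventionally BLOSUM62); NULL skips
#'   the comparative columns.
#' @param vectorization passed to [matrixCorrelation()].
#' @return data.frame with name, evo_dist, corr_to_reference,
#'   identical_fraction (NA when undefined).
#' @export
matrixSummary <- function(m, reference = NULL,
                          vectorization = c("full", "unique")) {
    vectorization <- match.arg(vectorization)
    corr <- idf <- NA_real_
    if (!is.null(reference)) {
        corr <- matrixCorrelation(m, reference, vectorization)
        if (m@integerValued && reference@integerValued)
            idf <- identicalFraction(m, reference)
    }
    data.frame(name = m@name,
               evo_dist = evolutionaryDistance(m),
               corr_to_reference = corr,
               identical_fraction = idf,
               stringsAsFactors = FALSE)
}
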