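#' Construct an Msa from gapped sequences
#'
#' @param rows character vector of equal-length gapped sequences ('-' or '.'
#'   as gap; normalized to '-', case-folded to upper).
#' @param ids sequence identifiers (default seq1..seqN).
#' @return An [Msa-class].
#' @export
msa <- function(rows, ids = NULL) {
    if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
    rows <- unname(toupper(gsub(".", "-", rows, fixed = TRUE)))
    obj <- new("Msa", ids = as.character(ids), rows = rows)
    validObject(obj)
    obj
}

#' Read a multiple alignment from aligned FASTA or Stockholm
#'
#' Format is chosen by content: files whose first non-blank line starts with
#' "# STOCKHOLM" are parsed as Stockholm (multi-block sequence lines
#' concatenated, '#' annotations ignored), anything else as aligned FASTA via
#' Biostrings. '.' gaps are normalized to '-' and sequences upper-cased.
#'
#' @param file path.
#' @return An [Msa-class].
#' @export
readMsa <- function(file) {
    first <- readLines(file, n = 50L)
    first <- first[nzchar(trimws(first))]
    if (length(first) > 0 && grepl("^# STOCKHOLM", first[1])) {
        lines <- readLines(file)
        lines <- lines[nzchar(trimws(lines))]
        lines <- lines[!grepl("^#", lines) & !grepl("^//", lines)]
        parts <- strsplit(trimws(lines), "\\s+")
        ids <- vapply(parts, `[`, character(1), 1L)
        seqs <- vapply(parts, `[`, character(1), 2L)
        agg <- tapply(seqs, factor(ids, levels = unique(ids)), paste,
                      collapse = "")
        return(msa(as.character(agg), names(agg)))
    }
    ss <- Biostrings::readBStringSet(file)
    msa(as.character(ss), names(ss))
}

#' Write an Msa as aligned FASTA
#' @param x an [Msa-class].
#' @param file path.
#' @export
writeMsa <- function(x, file) {
    stopifnot(is(x, "Msa"))
    writeLines(paste0(">", x@ids, "\n", x@rows), file)
    invisible(file)
}

#' Remove all gap characters from alignment rows
#'
#' @param x an [Msa-class].
#' @return Named character vector of ungapped sequences, order preserved.
#' @export
stripGaps <- function(x) {
    stopifnot(is(x, "Msa"))
    setNames(gsub("-", "", x@rows, fixed = TRUE), x@ids)
}

.msa_matrix <- function(x) {
    do.call(rbind, strsplit(x@rows, ""))
}

# per-row residue index at every alignment column (NA at gaps), rows
# matched between test and ref by id
.residue_positions <- function(mat) {
    t(apply(mat, 1, function(r) {
        p <- cumsum(r != "-")
        p[r == "-"] <- NA
        p
    }))
}

.check_same_sequences <- function(test, ref) {
    st <- stripGaps(test); sr <- stripGaps(ref)
    if (!setequal(names(st), names(sr)))
        stop("test and reference alignments contain different sequence ids")
    if (!identical(st[names(sr)], sr))
        stop("test and reference alignments contain different sequences")
}

# set of aligned residue pairs of an alignment, encoded as strings
# "rowi:posi|rowj:posj" over id-sorted rows
.pair_set <- function(x) {
    mat <- .msa_matrix(x)[order(x@ids), , drop = FALSE]
    pos <- .residue_positions(mat)
    n <- nrow(mat)
    out <- character(0)
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            ok <- !is.na(pos[i, ]) & !is.na(pos[j, ])
            if (any(ok))
                out <- c(out, paste0(i, ":", pos[i, ok], "|",
                                     j, ":", pos[j, ok]))
        }
    }
    out
}

#' Q-score: aligned residue-pair recall against a reference
#'
#' The fraction of residue pairs aligned in the reference (every within-
#' column pair of residues, identified by sequence and residue index) that
#' are also aligned in the test alignment. Both alignments must contain the
#' same sequences; rows are matched by id.
#'
#' @param test,ref [Msa-class] objects over the same sequences.
#' @return Fraction in \[0, 1\] (1 when the reference has no residue pairs).
#' @examples
#' ref <- msa(c("A-C", "AGC")); test <- msa(c("AC-", "AGC"))
#' qScore(test, ref)   # 0.5
#' @export
qScore <- function(test, ref) {
    .check_same_sequences(test, ref)
    rp <- .pair_set(ref)
    if (length(rp) == 0L) return(1)
    tp <- .pair_set(test)
    mean(rp %in% tp)
}

#' TC-score: exact-column recall against a reference
#'
#' The fraction of reference columns whose full residue content (which
#' residue index of every non-gap row, and which rows are gapped) occurs as
#' one column of the test alignment. Columns of the reference that are all
#' gaps are excluded from the denominator.
#'
#' @inheritParams qScore
#' @return Fraction in \[0, 1\].
#' @examples
#' ref <- msa(c("A-C", "AGC")); test <- msa(c("AC-", "AGC"))
#' tcScore(test, ref)  # 1/3
#' @export
tcScore <- function(test, ref) {
    .check_same_sequences(test, ref)
    ord_t <- order(test@ids); ord_r <- order(ref@ids)
    pos_r <- .residue_positions(.msa_matrix(ref)[ord_r, , drop = FALSE])
    pos_t <- .residue_positions(.msa_matrix(test)[ord_t, , drop = FALSE])
    col_key <- function(p) apply(p, 2, paste, collapse = ",")
    kr <- col_key(pos_r)
    kt <- col_key(pos_t)
    allgap <- apply(pos_r, 2, function(c) all(is.na(c)))
    kr <- kr[!allgap]
    if (length(kr) == 0L) return(1)
    mean(kr %in% kt)
}

#' Alignment summary statistics
#'
#' Rates are computed over all within-column sequence pairs: a pair of
#' identical residues is a match, differing residues a mismatch, and a
#' residue opposite a gap a gap pair; gap-gap pairs are ignored. The three
#' rates sum to 1. Mean pairwise identity is computed on the gap-stripped
#' sequences by global alignment (BLOSUM62, gap open 10, extend 1).
#'
#' @param x an [Msa-class].
#' @param identity compute mean pairwise identity (alignment per pair;
#'   quadratic cost — switch off for large alignments).
#' @return List with nSequences, meanSequenceLength, matchRate,
#'   mismatchRate, gapRate, meanPairwiseIdentity.
#' @export
msaStats <- function(x, identity = TRUE) {
    stopifnot(is(x, "Msa"))
    mat <- .msa_matrix(x)
    n <- nrow(mat)
    match <- mismatch <- gap <- 0
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            a <- mat[i, ]; b <- mat[j, ]
            ga <- a == "-"; gb <- b == "-"
            match <- match + sum(!ga & !gb & a == b)
            mismatch <- mismatch + sum(!ga & !gb & a != b)
            gap <- gap + sum(xor(ga, gb))
        }
    }
    tot <- match + mismatch + gap
    seqs <- stripGaps(x)
    mpi <- NA_real_
    if (identity && n >= 2) {
        pid <- utils::combn(seq_len(n), 2, function(ij)
            sequenceIdentity(seqs[[ij[1]]], seqs[[ij[2]]]))
        mpi <- mean(pid)
    }
    list(nSequences = n,
         meanSequenceLength = mean(nchar(seqs)),
         matchRate = if (tot > 0) match / tot else 0,
         mismatchRate = if (tot > 0) mismatch / tot else 0,
         gapRate = if (tot > 0) gap / tot else 0,
         meanPairwiseIdentity = mpi)
}
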