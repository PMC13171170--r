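# Independent oracles used across the suite. Deliberately naive: they
# enumerate rather than recurse the production code paths.

# All global alignments of a vs b as op strings ("M", "A" = gap in b
# consuming a, "B" = gap in a consuming b), scored independently by
# scanning gap runs. Exponential; only for short sequences.
brute_align_score <- function(a, b, mat, gop, gep, open_plus_ext = FALSE) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    S <- scores(mat)
    first <- if (open_plus_ext) gop + gep else gop
    score_path <- function(ops) {
        i <- 0L; j <- 0L; sc <- 0; prev <- ""
        for (op in ops) {
            if (op == "M") {
                i <- i + 1L; j <- j + 1L
                sc <- sc + S[ca[i], cb[j]]
            } else if (op == "A") {
                i <- i + 1L
                sc <- sc - if (prev == "A") gep else first
            } else {
                j <- j + 1L
                sc <- sc - if (prev == "B") gep else first
            }
            prev <- op
        }
        sc
    }
    best <- -Inf
    rec <- function(i, j, ops) {
        if (i == length(ca) && j == length(cb)) {
            s <- score_path(ops)
            if (s > best) best <<- s
            return(invisible())
        }
        if (i < length(ca) && j < length(cb)) rec(i + 1L, j + 1L, c(ops, "M"))
        if (i < length(ca)) rec(i + 1L, j, c(ops, "A"))
        if (j < length(cb)) rec(i, j + 1L, c(ops, "B"))
    }
    rec(0L, 0L, character(0))
    best
}

# column-wise re-score of a returned alignment (gap runs priced by scan)
rescore_alignment <- function(alignedA, alignedB, mat, gop, gep,
                              open_plus_ext = FALSE) {
    a <- strsplit(alignedA, "")[[1]]
    b <- strsplit(alignedB, "")[[1]]
    S <- scores(mat)
    first <- if (open_plus_ext) gop + gep else gop
    sc <- 0; prev <- "M"
    for (k in seq_along(a)) {
        if (a[k] != "-" && b[k] != "-") {
            sc <- sc + S[a[k], b[k]]; prev <- "M"
        } else if (b[k] == "-") {
            sc <- sc - if (prev == "A") gep else first; prev <- "A"
        } else {
            sc <- sc - if (prev == "B") gep else first; prev <- "B"
        }
    }
    sc
}

# ROC AUC as the exhaustive positive-negative win rate
winrate_auc <- function(scores, flags) {
    pos <- scores[as.logical(flags)]
    neg <- scores[!as.logical(flags)]
    tot <- 0
    for (p in pos) for (n in neg)
        tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
}

random_seq <- function(len, alphabet = c("A", "R", "N", "D")) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# fraction of truth correspondence pairs recovered
recovery_fraction <- function(found, truth) {
    key <- function(co) paste(corrPairs(co)[, 1], corrPairs(co)[, 2])
    mean(key(truth) %in% key(found))
}

make_helix_chain <- function(res, chainId = "A") {
    n <- nchar(res)
    r <- strsplit(res, "")[[1]]
    xyz <- submatkit:::.helix_coords(n)
    structureChain(r, xyz, chainId)
}
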