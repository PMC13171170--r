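test_that("family weights follow 1/C(n,2)", {
    expect_equal(familyWeight(2), 1.0)
    expect_equal(familyWeight(3), 1 / 3)
    expect_equal(familyWeight(100), 2 / 9900)
    expect_error(familyWeight(1), "at least 2")
})

test_that("weighted counting accumulates unordered column pairs", {
    c1 <- countSubstitutions(list(pairBlock("AA", "AA", "f1")), c(f1 = 1))
    expect_equal(c1@f["A", "A"], 2)
    expect_equal(sum(c1@f), 2)
    expect_equal(c1@total, 2)

    c2 <- countSubstitutions(list(pairBlock("AR", "RA", "f1")), c(f1 = 1))
    expect_equal(c2@f["A", "R"], 2)
    expect_equal(c2@f["R", "A"], 2)
    expect_equal(c2@total, 2)

    expect_error(countSubstitutions(list(pairBlock("AA", "AA", "f2")),
                                    c(f1 = 1)), "no weight")
    expect_error(pairBlock("A-", "AR"), "gap")
})

test_that("a family contributes total mass = columns regardless of size", {
    # n = 3 members, all 3 pairwise blocks of length L, weight 1/3
    L <- 10L
    blocks <- list(pairBlock(strrep("A", L), strrep("R", L), "f"),
                   pairBlock(strrep("A", L), strrep("N", L), "f"),
                   pairBlock(strrep("R", L), strrep("N", L), "f"))
    w <- c(f = familyWeight(3))
    got <- countSubstitutions(blocks, w)
    # oracle: unweighted counts divided by the pair count
    raw <- countSubstitutions(blocks, c(f = 1))
    expect_equal(got@total, L)
    expect_equal(got@f, raw@f / 3)

    # a 2-member family (one pair, w = 1) and a 3-member family (three
    # pairs, w = 1/3) with L-column blocks both deposit total mass L
    pairFam <- countSubstitutions(
        list(pairBlock(strrep("A", L), strrep("R", L), "g")),
        c(g = familyWeight(2)))
    expect_equal(pairFam@total, got@total)
})

test_that("log-odds estimation reproduces the hand-worked toy", {
    f <- matrix(0, 20, 20, dimnames = list(submatkit:::AA_ALPHABET,
                                           submatkit:::AA_ALPHABET))
    f["A", "A"] <- 9; f["R", "R"] <- 9
    f["A", "R"] <- 2; f["R", "A"] <- 2
    counts <- new("WeightedCounts", f = f, total = 20, nFamilies = 1L)
    m <- estimateLogOdds(counts, logOddsParams(pseudocount = 0))
    # q_AA = q_RR = 0.45, q_AR = 0.10, p = 0.5 each:
    # s_AA = round(2*log2(0.45/0.25)) = 2, s_AR = round(2*log2(0.1/0.5)) = -5
    expect_equal(scores(m)["A", "A"], 2)
    expect_equal(scores(m)["R", "R"], 2)
    expect_equal(scores(m)["A", "R"], -5)
    unrounded <- estimateLogOdds(counts, logOddsParams(pseudocount = 0,
                                                       rounding = "none"))
    expect_equal(scores(unrounded)["A", "A"], 2 * log2(0.45 / 0.25))
    expect_equal(scores(unrounded)["A", "R"], 2 * log2(0.10 / 0.50))
})

test_that("counts matching their own expectation give the zero matrix", {
    p <- rep(1 / 20, 20)
    e <- 2 * outer(p, p); diag(e) <- p^2
    f <- 1000 * e   # full table: off-diagonal cells hold the unordered mass
    dimnames(f) <- list(submatkit:::AA_ALPHABET, submatkit:::AA_ALPHABET)
    counts <- new("WeightedCounts", f = f, total = 1000, nFamilies = 1L)
    m <- estimateLogOdds(counts, logOddsParams(pseudocount = 0))
    expect_equal(unname(scores(m)), matrix(0, 20, 20))
})

test_that("estimation is invariant to doubling all counts", {
    set.seed(5)
    fam <- simulateFamily(3, 400, substitutionProcess(0.6), seed = 5)
    blocks <- list(pairBlock(fam$family$sequences[[1]],
                             fam$family$sequences[[2]], "f"))
    c1 <- countSubstitutions(blocks, c(f = 1))
    c2 <- countSubstitutions(c(blocks, blocks), c(f = 1))
    p <- logOddsParams()   # default pseudocount scales with the total
    expect_equal(scores(estimateLogOdds(c1, p)),
                 scores(estimateLogOdds(c2, p)))
    expect_error(estimateLogOdds(
        new("WeightedCounts",
            f = matrix(0, 20, 20,
                       dimnames = list(submatkit:::AA_ALPHABET,
                                       submatkit:::AA_ALPHABET)),
            total = 0, nFamilies = 0L), logOddsParams()), "positive")
})

test_that("zero cells are named when pseudocount is 0", {
    f <- matrix(0, 20, 20, dimnames = list(submatkit:::AA_ALPHABET,
                                           submatkit:::AA_ALPHABET))
    f["A", "A"] <- 5; f["R", "R"] <- 5   # A and R observed, pair A-R never
    counts <- new("WeightedCounts", f = f, total = 10, nFamilies = 1L)
    expect_error(estimateLogOdds(counts, logOddsParams(pseudocount = 0)),
                 "zero count.*A.*R")
})

test_that("the identity filter governs which pairs are counted", {
    same <- proteinFamily("same",
                          c(a = strrep("ACDEF", 8), b = strrep("ACDEF", 8)))
    expect_error(buildMatrix(list(same)), "empty counts")
    r <- buildMatrix(list(same), identityThreshold = 1.0)
    expect_equal(r$report$pairsFiltered, 0L)
    m <- scores(r$matrix)
    expect_true(all(diag(m)[c("A", "C", "D", "E", "F")] >
                        max(m[row(m) != col(m)])))
    # lowering the threshold never increases the retained pairs
    fam <- simulateFamily(4, 120, substitutionProcess(0.45), seed = 2,
                          familyId = "fx")$family
    kept <- vapply(c(1.0, 0.62, 0.3, 0.05), function(th) {
        rep <- try(buildMatrix(list(fam), identityThreshold = th)$report,
                   silent = TRUE)
        if (inherits(rep, "try-error")) 0L else rep$pairsAligned
    }, integer(1))
    expect_true(all(diff(kept) <= 0))
})

test_that("build is deterministic and reports its bookkeeping", {
    fams <- lapply(1:3, function(k)
        simulateFamily(3, 150, substitutionProcess(0.6), seed = k,
                       familyId = paste0("f", k))$family)
    r1 <- buildMatrix(fams)
    r2 <- buildMatrix(fams)
    expect_identical(scores(r1$matrix), scores(r2$matrix))
    expect_identical(r1$report, r2$report)
    expect_equal(r1$report$pairsGenerated, 9L)
    expect_equal(r1$report$pairsAligned +
                     r1$report$pairsFiltered, 9L)
    expect_warning(
        buildMatrix(c(fams, list(proteinFamily("solo", c(x = "ARND"))))),
        "skipped")
})

test_that("estimates converge to the generator's analytic log-odds", {
    proc <- substitutionProcess(0.55)
    target <- scores(analyticLogOdds(pairProcess(proc),
                                     logOddsParams(pseudocount = 0,
                                                   rounding = "none")))
    err <- vapply(c(4000L, 100000L), function(L) {
        fam <- simulateFamily(2, L, proc, seed = 99)$family
        blocks <- list(pairBlock(fam$sequences[[1]], fam$sequences[[2]],
                                 "f"))
        counts <- countSubstitutions(blocks, c(f = 1))
        est <- scores(estimateLogOdds(counts,
                                      logOddsParams(rounding = "none")))
        max(abs(est - target))
    }, numeric(1))
    expect_lt(err[2], err[1])   # error shrinks with data size
    expect_lt(err[2], 0.5)
})

test_that("convergence curve is zero at full size and seeded", {
    fams <- lapply(1:6, function(k)
        simulateFamily(3, 80, substitutionProcess(0.6), seed = 10 + k,
                       familyId = paste0("f", k))$family)
    cc <- convergenceCurve(fams, subsetSizes = c(2L, 6L), replicates = 3L,
                           seed = 4)
    expect_equal(cc$mean[cc$size == 6L], 0)
    expect_equal(cc$sd[cc$size == 6L], 0)
    one <- convergenceCurve(fams, subsetSizes = 3L, replicates = 1L,
                            seed = 4)
    expect_equal(one$sd, 0)
    again <- convergenceCurve(fams, subsetSizes = c(2L, 6L),
                              replicates = 3L, seed = 4)
    expect_identical(cc, again)
    expect_error(convergenceCurve(fams, subsetSizes = 0L), "1\\.\\.")
    expect_error(convergenceCurve(fams, subsetSizes = 7L), "1\\.\\.")
})
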