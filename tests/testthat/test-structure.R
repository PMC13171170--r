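write_toy_pdb <- function(file, res3, xyz, drop_ca_at = integer(0)) {
    lines <- character(0)
    serial <- 0L
    for (i in seq_along(res3)) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
            "ATOM  %5d  N   %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
            serial, res3[i], i, xyz[i, 1] + 0.5, xyz[i, 2], xyz[i, 3]))
        if (!(i %in% drop_ca_at)) {
            serial <- serial + 1L
            lines <- c(lines, sprintf(
                "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                serial, res3[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3]))
        }
    }
    writeLines(c(lines, "END"), file)
    file
}

write_toy_cif <- function(file, res3, xyz) {
    hdr <- c("data_toy", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
    rows <- sprintf(
        "ATOM %d C CA . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A CA 1",
        seq_along(res3), res3, seq_along(res3),
        xyz[, 1], xyz[, 2], xyz[, 3], seq_along(res3), res3)
    writeLines(c(hdr, rows, "#"), file)
    file
}

test_that("PDB and mmCIF chains read back with exact coordinates", {
    res1 <- strsplit("ARNDCQEGHI", "")[[1]]
    res3 <- bio3d::aa123(res1)
    xyz <- submatkit:::.helix_coords(10)
    pdb <- write_toy_pdb(tempfile(fileext = ".pdb"), res3, xyz)
    ch <- readChain(pdb, "A")
    expect_equal(length(ch), 10L)
    expect_equal(ch@residues, res1)
    expect_equal(unname(ch@coords), unname(round(xyz, 3)), tolerance = 1e-6)

    cif <- suppressWarnings(
        readChain(write_toy_cif(tempfile(fileext = ".cif"), res3, xyz)))
    expect_equal(cif@residues, ch@residues)
    expect_equal(cif@coords, ch@coords)
    expect_equal(cif@resno, ch@resno)

    nopdb <- write_toy_pdb(tempfile(fileext = ".pdb"), res3, xyz,
                           drop_ca_at = 4L)
    expect_warning(ch9 <- readChain(nopdb, "A"), "alpha-carbon")
    expect_equal(length(ch9), 9L)
    expect_false(4L %in% ch9@resno)

    expect_error(readChain(pdb, "Z"), "chain 'Z'")
})

test_that("Kabsch superposition recovers exact rigid motions", {
    set.seed(31)
    ch <- make_helix_chain(random_seq(20, submatkit:::AA_ALPHABET))
    idpairs <- new("Correspondence",
                   pairs = cbind(0:19, 0:19), distances = numeric(0))
    tf <- kabschSuperpose(ch, ch, idpairs)
    expect_equal(tf$rmsd, 0, tolerance = 1e-10)
    expect_equal(tf$rotation, diag(3), tolerance = 1e-10)

    Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
    moved <- structureChain(ch@residues,
                            sweep(ch@coords %*% t(Rz), 2, c(1, 2, 3), `+`),
                            "B")
    tf2 <- kabschSuperpose(ch, moved, idpairs)
    expect_equal(tf2$rmsd, 0, tolerance = 1e-8)
    back <- submatkit:::.apply_transform(moved@coords, tf2)
    expect_equal(back, ch@coords, tolerance = 1e-8)

    expect_error(kabschSuperpose(ch, ch,
        new("Correspondence", pairs = cbind(0:1, 0:1),
            distances = numeric(0))), "3 pairs")
})

test_that("Kabsch rmsd equals a brute-force rigid-motion minimization", {
    set.seed(8)
    ch <- make_helix_chain(random_seq(12, submatkit:::AA_ALPHABET))
    disp <- ch@coords
    disp[5, ] <- disp[5, ] + c(1.3, -0.7, 0.4)
    moved <- structureChain(ch@residues, disp, "B")
    pairs <- new("Correspondence", pairs = cbind(0:11, 0:11),
                 distances = numeric(0))
    tf <- kabschSuperpose(ch, moved, pairs)
    # oracle: numeric minimization over Euler angles + translation
    obj <- function(par) {
        a <- par[1]; b <- par[2]; g <- par[3]
        Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
        Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
        Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
        R <- Rz %*% Ry %*% Rx
        fitted <- sweep(moved@coords %*% t(R), 2, par[4:6], `+`)
        sqrt(mean(rowSums((ch@coords - fitted)^2)))
    }
    o <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    expect_equal(tf$rmsd, o$value, tolerance = 1e-6)
})

test_that("correspondence extraction recovers identical and planted cases", {
    ch <- make_helix_chain(random_seq(30, submatkit:::AA_ALPHABET))
    co <- extractCorrespondences(ch, ch)
    expect_equal(corrPairs(co), cbind(0:29, 0:29), ignore_attr = TRUE)

    sp <- simulateStructurePair(60, deletionRun = 5, coordinateNoiseSd = 0.5,
                                seed = 17)
    found <- extractCorrespondences(sp$chainA, sp$chainB)
    expect_gte(recovery_fraction(found, sp$truth), 0.95)

    # chains too far apart after any superposition pair nothing
    far <- structureChain(ch@residues, ch@coords * 25, "B")
    cofar <- extractCorrespondences(ch, far, proximityThreshold = 1e-6)
    expect_equal(length(cofar), 0L)
})

test_that("extraction is invariant to rigid motions of either chain", {
    sp <- simulateStructurePair(40, deletionRun = 3, coordinateNoiseSd = 0.3,
                                seed = 23)
    base <- extractCorrespondences(sp$chainA, sp$chainB)
    set.seed(77)
    R <- submatkit:::.random_rotation()
    movedA <- structureChain(sp$chainA@residues,
                             sweep(sp$chainA@coords %*% t(R), 2,
                                   c(-4, 9, 2), `+`), "A")
    again <- extractCorrespondences(movedA, sp$chainB)
    expect_equal(corrPairs(again), corrPairs(base))
    # output is strictly monotone in both indices
    p <- corrPairs(base)
    expect_true(all(diff(p[, 1]) > 0) && all(diff(p[, 2]) > 0))
})

test_that("pair blocks read residues off the correspondence", {
    chA <- make_helix_chain("ARND")
    chB <- make_helix_chain("GGAR")
    co <- new("Correspondence", pairs = cbind(c(0L, 1L), c(2L, 3L)),
              distances = numeric(0))
    blk <- pairBlockFromCorrespondence(chA, chB, co, "fam")
    expect_equal(blk@seqA, "AR")
    expect_equal(blk@seqB, "AR")
    expect_equal(nchar(blk@seqA), length(co))
    ident <- new("Correspondence", pairs = cbind(0:3, 0:3),
                 distances = numeric(0))
    same <- pairBlockFromCorrespondence(chA, chA, ident)
    expect_equal(same@seqA, same@seqB)
    empty <- new("Correspondence", pairs = matrix(integer(0), 0, 2),
                 distances = numeric(0))
    expect_error(pairBlockFromCorrespondence(chA, chB, empty), "empty")
})

test_that("correspondences round-trip through the TSV dialect", {
    co <- new("Correspondence", pairs = cbind(c(0L, 2L, 5L), c(1L, 3L, 6L)),
              distances = c(0.2, 0.4, 1.1))
    f <- tempfile(fileext = ".tsv")
    writeCorrespondence(co, f)
    back <- readCorrespondence(f)
    expect_equal(corrPairs(back), corrPairs(co), ignore_attr = TRUE)
    expect_equal(back@distances, co@distances)
})
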