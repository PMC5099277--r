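test_that("a minimal hand-written PDB file parses into one residue", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   7      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  GLY A   7      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   GLY A   7      10.729   6.768  -4.123  1.00  0.00           C",
    "ATOM      4  O   GLY A   7      10.934   6.631  -2.908  1.00  0.00           O",
    "END"), f)
  rs <- readStructure(f)
  rt <- residueTable(rs)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$resname, "GLY")
  expect_equal(rt$seqnum, 7L)
  ## glycine: backbone only, no side-chain atoms
  expect_setequal(atomTable(rs)$atom, c("N", "CA", "C", "O"))
})

test_that("hydrogens and waters are dropped; altlocs resolve to highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      6  H   ALA A   1       0.500   0.800   0.000  1.00  0.00           H",
    "HETATM    7  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), f)
  rs <- readStructure(f)
  a <- atomTable(rs)
  expect_equal(nrow(residueTable(rs)), 1L)
  expect_false("H" %in% a$atom)
  ca <- a[a$atom == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.5)  # altloc B, occupancy 0.60, wins
})

test_that("missing files and CA-free chains raise errors", {
  expect_error(readStructure(file.path(tempdir(), "no-such-file.pdb")),
               "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "END"), f)
  expect_error(readStructure(f), "no CA")
})

test_that("synthetic structures survive a write-then-read round trip", {
  pr <- phiPsiPreset("ALPHA")
  rs <- makeBackbone(pr["phi"], pr["psi"], 30, sequence = NULL, seqStart = 5L)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(rs, f)
  rs2 <- readStructure(f)
  a1 <- atomTable(rs); a2 <- atomTable(rs2)
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(a2$resname, a1$resname)
  expect_equal(a2$seqnum, a1$seqnum)
  ## PDB format prints 3 decimals
  expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                      as.matrix(a2[, c("x", "y", "z")]))), 1e-3)
  ## reading is idempotent
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(rs2, f2)
  expect_identical(atomTable(readStructure(f2)), atomTable(rs2))
})

test_that("explicit segment selection returns the requested residues verbatim", {
  ca <- makeParametricCA(40)
  a <- data.frame(chain = "A", seqnum = 1:40, icode = "", resname = "ALA",
                  atom = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3])
  rs <- ResidueSet(a)
  segs <- tmSegments("A", 5, 30, "TM1")
  out <- selectSegments(rs, segs)
  expect_named(out, "TM1")
  expect_equal(nrow(residueTable(out$TM1)), 26L)
  ## ranges referencing absent residues fail loudly, listing them
  expect_error(selectSegments(rs, tmSegments("A", 35, 45, "TMX")),
               "missing residues.*41")
})

test_that("slab selection keeps only membrane-spanning runs", {
  ## helix along Z through z in about [-21, 21]: 29-residue central run inside
  ## |z| <= 15 after centering
  ca <- makeParametricCA(29, rise = 1.5)
  ca[, 3] <- ca[, 3] - mean(ca[, 3])
  extra <- makeParametricCA(29, rise = 1.5)
  extra[, 3] <- extra[, 3] + 30  # fully outside the slab
  extra[, 1] <- extra[, 1] + 30
  a <- rbind(
    data.frame(chain = "A", seqnum = 1:29, icode = "", resname = "ALA",
               atom = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3]),
    data.frame(chain = "B", seqnum = 1:29, icode = "", resname = "ALA",
               atom = "CA", x = extra[, 1], y = extra[, 2], z = extra[, 3]))
  rs <- ResidueSet(a)
  out <- selectSegments(rs, zHalfWidth = 15)
  expect_length(out, 1L)
  got <- residueTable(out[[1]])
  expect_equal(got$chain[1], "A")
  expect_true(all(abs(caTrace(out[[1]])[, 3]) <= 15))
  ## a helix fully outside the slab yields nothing
  rsB <- ResidueSet(a[a$chain == "B", ])
  expect_length(selectSegments(rsB, zHalfWidth = 15), 0L)
})

test_that("chain-broken segments are rejected", {
  ca <- makeParametricCA(20)
  ca[11:20, 3] <- ca[11:20, 3] + 10  # 11.5 A jump
  a <- data.frame(chain = "A", seqnum = 1:20, icode = "", resname = "ALA",
                  atom = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3])
  rs <- ResidueSet(a)
  expect_error(selectSegments(rs, tmSegments("A", 1, 20, "TM1")),
               "chain-broken")
})

test_that("segment tables shorter than 7 residues are refused", {
  expect_error(tmSegments("A", 10, 15, "TM1"), "at least 7")
})
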