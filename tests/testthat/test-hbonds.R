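test_that("ideal helices produce their canonical exclusive H-bond ladders", {
  for (case in list(list("ALPHA", 4L, "BB_ALPHA"),
                    list("G310", 3L, "BB_310"),
                    list("PI", 5L, "BB_PI"))) {
    pr <- phiPsiPreset(case[[1]])
    rs <- makeBackbone(pr["phi"], pr["psi"], 20)
    hb <- backboneHBonds(rs)
    expect_true(all(hb$sep == case[[2]]))
    expect_true(all(hb$category == case[[3]]))
    ## every interior carbonyl accepts: donors run from sep+1 to 20
    expect_equal(sort(hb$acceptor_seq), seq_len(20L - case[[2]]) )
  }
})

test_that("proline nitrogens never donate", {
  pr <- phiPsiPreset("ALPHA")
  rs <- makeBackbone(pr["phi"], pr["psi"], 20,
                     sequence = "AAAAAAAAAPAAAAAAAAAA")  # Pro at 10
  hb <- backboneHBonds(rs)
  expect_false(10L %in% hb$donor_seq)
})

test_that("detection matches the brute-force all-pairs oracle on perturbed backbones", {
  set.seed(101)
  for (rep in 1:30) {
    b <- randomPerturbedBackbone(n = sample(18:28, 1))
    hb <- backboneHBonds(b$rs)
    or <- oracleBackboneHBonds(b$rs)
    expect_identical(bondKeys(hb), bondKeys(or))
  }
})

test_that("H-bond sets are invariant under rigid motion", {
  set.seed(5)
  pp <- perturbedPhiPsi(22, insert = "PI", at = 10, length = 3)
  rs <- makeBackbone(pp$phi, pp$psi, 22)
  hb0 <- bondKeys(backboneHBonds(rs))
  a <- atomTable(rs)
  rm <- randomRigidMotion()
  xyz <- applyRigid(as.matrix(a[, c("x", "y", "z")]), rm)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  expect_identical(bondKeys(backboneHBonds(ResidueSet(a))), hb0)
})

test_that("an ideal alpha helix has no unpaired interior carbonyls", {
  pr <- phiPsiPreset("ALPHA")
  rs <- makeBackbone(pr["phi"], pr["psi"], 20)
  up <- unpairedCarbonyls(rs)
  expect_equal(nrow(up), 0L)
})

test_that("a planted pi-bulge frees at least one carbonyl before the bulge", {
  set.seed(23)
  for (at in c(9L, 12L, 15L)) {
    pp <- perturbedPhiPsi(26, insert = "PI", at = at, length = 3L)
    rs <- makeBackbone(pp$phi, pp$psi, 26)
    up <- unpairedCarbonyls(rs)
    expect_gte(nrow(up), 1L)
    ## the freed carbonyl sits in the turn at/preceding the bulge
    expect_true(any(up$seqnum >= at - 5L & up$seqnum <= at + 2L))
  }
})

test_that("stabilisation recognises SM donors and respects distance cutoffs", {
  pr <- phiPsiPreset("ALPHA")
  rs <- makeBackbone(pr["phi"], pr["psi"], 12, chain = "A")
  a <- atomTable(rs)
  o6 <- a[a$seqnum == 6 & a$atom == "O", ]
  op <- c(o6$x, o6$y, o6$z)
  up <- data.frame(chain = "A", seqnum = 6L)
  ## lysine NZ from a neighbouring helix 2.9 A away: stabilized, inter, SM
  nz <- data.frame(chain = "B", seqnum = 100L, icode = "", resname = "LYS",
                   atom = c("CA", "NZ"),
                   x = op[1] + c(6, 2.9), y = op[2], z = op[3])
  segs <- tmSegments(c("A", "B"), c(1, 95), c(12, 105), c("TM1", "TM2"))
  st <- stabilization(up, ResidueSet(rbind(a, nz)), segs)
  expect_true(st$carbonyls$stabilized)
  sm <- st$stabilizers[st$stabilizers$category == "SM", ]
  expect_equal(sm$scope, "inter")
  expect_equal(sm$partner_atom, "NZ")
  ## nearest candidate at 5.2 A: unstabilized
  far <- nz; far$x <- op[1] + c(8, 5.2)
  st2 <- stabilization(up, ResidueSet(rbind(a, far)), segs)
  expect_false(st2$carbonyls$stabilized)
})

test_that("proline CD/CG contacts and CB-H...O contacts stabilise", {
  pr <- phiPsiPreset("ALPHA")
  rs <- makeBackbone(pr["phi"], pr["psi"], 12, chain = "A")
  a <- atomTable(rs)
  o5 <- a[a$seqnum == 5 & a$atom == "O", ]
  op <- c(o5$x, o5$y, o5$z)
  up <- data.frame(chain = "A", seqnum = 5L)
  pro <- data.frame(chain = "B", seqnum = 50L, icode = "", resname = "PRO",
                    atom = c("CA", "CD"), x = op[1] + c(7, 3.5),
                    y = op[2], z = op[3])
  st <- stabilization(up, ResidueSet(rbind(a, pro)), NULL)
  expect_true("PRO_CD_CG" %in% st$stabilizers$category)
  cb <- data.frame(chain = "C", seqnum = 60L, icode = "", resname = "VAL",
                   atom = c("CA", "CB"), x = op[1] + c(7, 3.8),
                   y = op[2], z = op[3])
  st2 <- stabilization(up, ResidueSet(rbind(a, cb)), NULL)
  expect_true("CB_H_O" %in% st2$stabilizers$category)
  ## covalently adjacent CA atoms are never counted as stabilisers
  expect_false(any(st2$stabilizers$category == "CA_H_O" &
                     abs(st2$stabilizers$partner_seq - 5) <= 1 &
                     st2$stabilizers$partner_chain == "A"))
})

test_that("planted stabilisers in a bundle are recovered exactly", {
  ## plant: carbonyls 6 and 9 of helix A unpaired... use a pi-bulge helix and
  ## place serine OG donors at two of its unpaired carbonyls
  pp <- perturbedPhiPsi(24, insert = "PI", at = 12, length = 3)
  rs <- makeBackbone(pp$phi, pp$psi, 24, chain = "A")
  up <- unpairedCarbonyls(rs)
  expect_gte(nrow(up), 1L)
  a <- atomTable(rs)
  planted <- up$seqnum[1]
  o <- a[a$seqnum == planted & a$atom == "O", ]
  don <- data.frame(chain = "B", seqnum = 200L, icode = "", resname = "SER",
                    atom = c("CA", "OG"),
                    x = o$x + c(6, 2.8), y = o$y, z = o$z)
  st <- stabilization(up, ResidueSet(rbind(a, don)), NULL)
  expect_identical(st$carbonyls$stabilized, up$seqnum == planted)
  ## stabilized count never exceeds unpaired count
  expect_lte(sum(st$carbonyls$stabilized), nrow(st$carbonyls))
})

test_that("anchor offsets are renumbering-invariant and proline-anchored", {
  rec <- new("PerturbationRecord", helixId = "TM", pertClass = "KINKED_PRO_P1",
             maxbaSeq = 803L, maxbaValue = 25, prolineSeq = 803L,
             segment = data.frame())
  up <- data.frame(chain = "A", seqnum = 799L)
  expect_equal(anchorOffsets(up, rec), -4L)
  ## +100 renumbering leaves offsets unchanged
  rec2 <- rec; rec2@prolineSeq <- 903L; rec2@maxbaSeq <- 903L
  up2 <- data.frame(chain = "A", seqnum = 899L)
  expect_equal(anchorOffsets(up2, rec2), -4L)
  ## non-proline classes anchor at MaxBA + 2
  rec3 <- new("PerturbationRecord", helixId = "TM", pertClass = "KINKED_NONPRO",
              maxbaSeq = 50L, maxbaValue = 25, prolineSeq = NA_integer_,
              segment = data.frame())
  expect_equal(anchorOffsets(data.frame(chain = "A", seqnum = 48L), rec3), -4L)
})
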