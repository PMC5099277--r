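test_that("geometry classes: linear, kinked and curved synthetic helices", {
  g <- geometryClass(stepSeries(makeParametricCA(24)))
  expect_equal(g$class, "LINEAR")
  expect_lt(g$maxbaValue, 1e-6)

  k <- geometryClass(stepSeries(insertKink(makeParametricCA(24), 12, 25)))
  expect_equal(k$class, "KINKED")
  expect_equal(k$maxbaValue, 25, tolerance = 1 / 25)
  expect_lte(abs(k$maxbaSeq - 12L), 1L)

  ## smooth 30-degree arc over 20 residues, no local break
  cv <- geometryClass(stepSeries(makeCurvedCA(20, totalBend = 30)))
  expect_equal(cv$class, "CURVED")
  expect_lt(cv$maxbaValue, 20)
})

test_that("planted hinge angles 15-40 recover within one degree at the hinge", {
  for (ang in c(15, 22, 30, 40)) {
    for (dir in c(0, 130)) {
      g <- geometryClass(stepSeries(insertKink(makeParametricCA(26,
                                                                phase = 40 * dir),
                                               13, ang, direction = dir)))
      expect_equal(g$maxbaValue, ang, tolerance = 1 / ang)
      expect_lte(abs(g$maxbaSeq - 13L), 1L)
    }
  }
})

test_that("the kink call flips exactly at the configured threshold", {
  ca <- insertKink(makeParametricCA(24), 12, 25)
  st <- stepSeries(ca)
  g <- geometryClass(st)
  m <- g$maxbaValue
  expect_equal(geometryClass(st, kinkThreshold = m - 0.5)$class, "KINKED")
  expect_false(identical(geometryClass(st, kinkThreshold = m + 0.5)$class,
                         "KINKED"))
  ## raising the threshold is monotone: KINKED can only leave, never appear
  for (thr in c(15, 20, 26, 35)) {
    cls <- geometryClass(st, kinkThreshold = thr)$class
    expect_equal(cls == "KINKED", thr <= m)
  }
})

test_that("too few windows yields UNCLASSIFIED with a reason", {
  g <- geometryClass(stepSeries(makeParametricCA(8)))
  expect_equal(g$class, "UNCLASSIFIED")
  expect_match(g$reason, "interior bend")
})

.mkGeo <- function(class, maxbaSeq = 12L, maxbaValue = 25) {
  list(class = class, maxbaSeq = maxbaSeq, maxbaValue = maxbaValue,
       meanBend = 3, axisTurn = 5)
}
.mkSegs <- function(df, region = c(1L, 24L)) {
  df$mean_twist <- 100; df$mean_rise <- 1.5; df$mean_radius <- 2.3
  new("HelixSegments", segments = df, region = as.integer(region))
}
alphaOnly <- .mkSegs(data.frame(first = 1L, last = 24L, class = "ALPHA"))
withPi <- .mkSegs(data.frame(first = c(1L, 10L, 16L), last = c(9L, 15L, 24L),
                             class = c("ALPHA", "PI", "ALPHA")))
withG310 <- .mkSegs(data.frame(first = c(1L, 18L), last = c(17L, 24L),
                               class = c("ALPHA", "G310")))

test_that("perturbation types follow the priority order pi > 3-10 > kink", {
  ## interspersed pi with proline inside -> PI_PRO even when also kinked
  r <- perturbationType(.mkGeo("KINKED"), withPi, prolines = 12L)
  expect_equal(pertClass(r), "PI_PRO")
  expect_equal(prolineSeq(r), 12L)
  ## proline within the downstream window still counts
  expect_equal(pertClass(perturbationType(.mkGeo("LINEAR"), withPi,
                                          prolines = 19L)), "PI_PRO")
  ## proline too far -> non-proline pi
  expect_equal(pertClass(perturbationType(.mkGeo("LINEAR"), withPi,
                                          prolines = 22L)), "PI_NONPRO")
  ## terminal 3-10 segment
  expect_equal(pertClass(perturbationType(.mkGeo("LINEAR"), withG310,
                                          prolines = 18L)), "G310_PRO")
  expect_equal(pertClass(perturbationType(.mkGeo("LINEAR"), withG310)),
               "G310_NONPRO")
})

test_that("kinked helices split into P1/P2/non-Pro by proline position", {
  expect_equal(pertClass(perturbationType(.mkGeo("KINKED"), alphaOnly,
                                          prolines = 12L)), "KINKED_PRO_P1")
  expect_equal(pertClass(perturbationType(.mkGeo("KINKED"), alphaOnly,
                                          prolines = 13L)), "KINKED_PRO_P1")
  expect_equal(pertClass(perturbationType(.mkGeo("KINKED"), alphaOnly,
                                          prolines = 16L)), "KINKED_PRO_P2")
  expect_equal(pertClass(perturbationType(.mkGeo("KINKED"), alphaOnly,
                                          prolines = 9L)), "KINKED_PRO_P2")
  expect_equal(pertClass(perturbationType(.mkGeo("KINKED"), alphaOnly,
                                          prolines = 20L)), "KINKED_NONPRO")
  expect_equal(pertClass(perturbationType(.mkGeo("KINKED"), alphaOnly)),
               "KINKED_NONPRO")
})

test_that("curved and linear references split only on proline presence", {
  expect_equal(pertClass(perturbationType(.mkGeo("CURVED"), alphaOnly,
                                          prolines = 5L)), "CURVED_PRO")
  expect_equal(pertClass(perturbationType(.mkGeo("CURVED"), alphaOnly)),
               "CURVED")
  expect_equal(pertClass(perturbationType(.mkGeo("LINEAR"), alphaOnly,
                                          prolines = 5L)), "LINEAR_PRO")
  expect_equal(pertClass(perturbationType(.mkGeo("LINEAR"), alphaOnly)),
               "LINEAR")
})

test_that("end-to-end classification recovers planted perturbations", {
  set.seed(31)
  plan <- list(
    list(kind = "PI", expect = "PI_NONPRO"),
    list(kind = "G310", expect = "G310_NONPRO"),
    list(kind = "KINK", expect = "KINKED_NONPRO"),
    list(kind = "NONE", expect = "LINEAR"))
  for (p in plan) {
    n <- 26L
    if (p$kind %in% c("PI", "G310")) {
      pp <- perturbedPhiPsi(n, insert = p$kind, at = 12L, length = 3L)
      rs <- makeBackbone(pp$phi, pp$psi, n)
      ca <- caTrace(rs)
    } else {
      ca <- makeParametricCA(n)
      if (p$kind == "KINK") ca <- insertKink(ca, 13L, 28)
    }
    st <- stepSeries(ca)
    labs <- classifySteps(st)
    segs <- mergeSegments(labs, st)
    geo <- geometryClass(st)
    rec <- perturbationType(geo, segs, prolines = integer(0))
    expect_equal(pertClass(rec), p$expect, label = p$kind)
  }
})

test_that("torsion reports tabulate anchor-relative phi/psi rows", {
  pr <- phiPsiPreset("ALPHA")
  rs <- makeBackbone(pr["phi"], pr["psi"], 24)
  tors <- phiPsi(rs)
  rec <- new("PerturbationRecord", helixId = "TM1", pertClass = "KINKED_NONPRO",
             maxbaSeq = 12L, maxbaValue = 25, prolineSeq = NA_integer_,
             segment = data.frame())
  rep_ <- torsionReport(rec, tors)
  expect_equal(nrow(rep_), 3L)  # offsets -4, -3, 0 all inside
  expect_equal(rep_$offset, c(-4L, -3L, 0L))
  expect_equal(rep_$phi, rep(-63, 3), tolerance = 1e-6)
  expect_equal(rep_$psi, rep(-42, 3), tolerance = 1e-6)
  ## offsets falling outside the chain are absent, not NA rows
  rec@maxbaSeq <- 2L
  expect_lt(nrow(torsionReport(rec, tors)), 3L)
  ## proline-mediated records anchor at the proline
  recP <- rec; recP@pertClass <- "PI_PRO"; recP@prolineSeq <- 15L
  recP@segment <- data.frame(first = 12L, last = 18L, class = "PI")
  rp <- torsionReport(recP, tors)
  expect_equal(rp$seqnum, 15L + rp$offset)
})
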