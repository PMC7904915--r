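test_that("chain formulas match the independent summation oracle", {
  # frozen hand-sum for the unsaturated 0S disaccharide:
  # C6H8O6 + C8H15NO6 - H2O = C14H21NO11
  f0 <- formula_of(parse_chain("dUA-GlcNAc"))
  expect_equal(unname(pkg_counts(f0)), c(14, 21, 1, 11, 0))
  expect_equal(f0$monoisotopic, 379.1115, tolerance = 1e-6)

  # fondaparinux: 5 residues + 8 sulfates + OMe -> C31H53N3O49S8
  fp <- hp_fixtures()$fondaparinux
  ff <- formula_of(fp)
  expect_equal(unname(pkg_counts(ff)), c(31, 53, 3, 49, 8))
  expect_equal(pkg_counts(ff), oracle_counts(format_chain(fp)))
  expect_equal(ff$monoisotopic, oracle_mono_mass(format_chain(fp)),
               tolerance = 1e-10)

  for (seed in 1:100) {
    ch <- random_test_chain(seed, allow_other = TRUE,
                            re_mod_choices = c("none", "OMe", "2AB"))
    s <- format_chain(ch)
    expect_equal(pkg_counts(formula_of(ch)), oracle_counts(s))
    expect_equal(formula_of(ch)$monoisotopic, oracle_mono_mass(s),
                 tolerance = 1e-10)
  }
})

test_that("each added sulfate shifts the mass by exactly SO3", {
  so3 <- 31.97207069 + 3 * 15.9949146221
  a <- formula_of(parse_chain("dUA-GlcNS"))
  b <- formula_of(parse_chain("dUA-GlcNS6S"))
  expect_equal(b$monoisotopic - a$monoisotopic, so3, tolerance = 1e-9)
  expect_equal(b$counts - a$counts, c(C = 0, H = 0, N = 0, O = 3, S = 1))
})

test_that("GlcA/IdoA epimer swaps never change a formula or mass", {
  for (seed in 1:25) {
    ch <- random_test_chain(seed)
    sw <- ch
    uro <- which(sw$residues$epimer %in% c("GlcA", "IdoA"))
    sw$residues$epimer[uro] <- ifelse(sw$residues$epimer[uro] == "GlcA",
                                      "IdoA", "GlcA")
    expect_equal(formula_of(ch)$counts, formula_of(sw)$counts)
  }
})

test_that("total sulfur equals N-sulfates plus O-sulfates", {
  for (seed in 1:25) {
    ch <- random_test_chain(seed, allow_other = TRUE)
    r <- ch$residues
    n_s <- sum(r$nsub == "S", na.rm = TRUE) + sum(r$s2) + sum(r$s3) + sum(r$s6)
    expect_equal(unname(formula_of(ch)$counts["S"]), n_s)
  }
})

test_that("epimer-erased chains refuse a formula unless sulfation-level", {
  ch <- parse_chain("HexUA2S-GlcNS6S")
  expect_error(formula_of(ch), class = "hepseq_epimer_erased")
  f <- formula_of(ch, sulfation_level = TRUE)
  expect_equal(f$counts, formula_of(parse_chain("IdoA2S-GlcNS6S"))$counts)
})

test_that("negative-mode m/z follows the deprotonation closed form", {
  expect_equal(mz(1000, 1), 1000 - 1.007276466879, tolerance = 1e-9)
  expect_equal(mz(1000, 2), (1000 - 2 * 1.007276466879) / 2, tolerance = 1e-9)
  expect_error(mz(1000, 0), class = "hepseq_bad_charge")

  p84 <- hp_fixtures()$P8_4
  m <- oracle_mono_mass(format_chain(p84))
  expect_equal(mz(formula_of(p84)$monoisotopic, 2),
               (m - 2 * 1.007276466879) / 2, tolerance = 1e-9)
})

test_that("glycosidic fragments: counts, complementarity, oracle Y1", {
  dp2 <- parse_chain("dUA2S-GlcNS6S")
  fl2 <- fragment_ladder(dp2)
  expect_equal(nrow(fl2), 4L)
  y1 <- fl2[fl2$label == "Y1", ]
  expect_equal(y1$monoisotopic, oracle_mono_mass("GlcNS6S"), tolerance = 1e-9)

  for (seed in c(3, 11, 19)) {
    ch <- random_test_chain(seed, re_mod_choices = c("none", "OMe"))
    L <- chain_dp(ch)
    fl <- fragment_ladder(ch)
    expect_equal(nrow(fl), 4L * (L - 1L))
    parent <- formula_of(ch)$monoisotopic
    h2o <- 2 * 1.0078250319 + 15.9949146221
    for (i in seq_len(L - 1L)) {
      cm <- fl$monoisotopic[fl$type == "C" & fl$index == i]
      ym <- fl$monoisotopic[fl$type == "Y" & fl$index == L - i]
      expect_equal(cm + ym, parent + h2o, tolerance = 1e-9)
      bm <- fl$monoisotopic[fl$type == "B" & fl$index == i]
      zm <- fl$monoisotopic[fl$type == "Z" & fl$index == L - i]
      expect_equal(bm + zm, parent - h2o, tolerance = 1e-9)
    }
  }
})

test_that("2-AB labelling adds one fixed formula delta", {
  ch <- hp_fixtures()$DP13
  lab <- label_2ab(ch)
  d <- formula_of(lab)$monoisotopic - formula_of(ch)$monoisotopic
  expect_equal(d, oracle_mono_mass("dUA-GlcNAc(2AB)") -
                 oracle_mono_mass("dUA-GlcNAc"), tolerance = 1e-9)
})
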