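heps <- heparinases()

test_that("linkage specificity follows uronate sulfation classes", {
  p47 <- hp_fixtures()$P4_7
  expect_equal(cleavable_linkages(p47, heps$exoHep), 2L)

  # heparinase III never touches a fully 2-O-sulfated chain
  hi <- parse_chain(paste(rep("IdoA2S-GlcNS6S", 4), collapse = "-"))
  expect_length(cleavable_linkages(hi, heps$HepIII), 0L)
  expect_gt(length(cleavable_linkages(hi, heps$HepI)), 0L)

  # a 2-AB-labelled reducing end abolishes exolytic action on any chain
  lab <- label_2ab(hp_fixtures()$DP13)
  expect_length(cleavable_linkages(lab, heps$exoHep), 0L)

  # exo ignores internal sites and chains below the DP minimum
  expect_length(cleavable_linkages(parse_chain("dUA-GlcNS6S"), heps$exoHep), 0L)
})

test_that("HepI and HepIII sites partition HepII sites on 3S-free chains", {
  for (seed in 1:40) {
    ch <- random_test_chain(seed)
    s1 <- cleavable_linkages(ch, heps$HepI)
    s3 <- cleavable_linkages(ch, heps$HepIII)
    s2 <- cleavable_linkages(ch, heps$HepII)
    expect_identical(sort(union(s1, s3)), sort(s2))
    expect_length(intersect(s1, s3), 0L)
  }
})

test_that("cleavage introduces one dUA and conserves every atom", {
  fp <- hp_fixtures()$fondaparinux
  p <- cleave(fp, 3L)
  expect_identical(format_chain(p$nre), "GlcNS6S-GlcA-GlcNS3S6S")
  expect_identical(format_chain(p$re), "dUA2S-GlcNS6S(OMe)")

  p84 <- hp_fixtures()$P8_4
  p2 <- cleave(p84, 6L)
  expect_equal(disaccharide_units(p2$re)$code, "2SNS6S")

  for (seed in 1:30) {
    ch <- random_test_chain(seed, allow_other = TRUE,
                            re_mod_choices = c("none", "OMe"))
    links <- which(ch$residues$kind == "hexosamine" &
                     c(ch$residues$kind[-1], "") == "uronate")
    set.seed(seed)
    j <- if (length(links) == 1) links else sample(links, 1)
    pr <- cleave(ch, j)
    expect_equal(formula_of(pr$nre, TRUE)$counts +
                   formula_of(pr$re, TRUE)$counts,
                 formula_of(ch, TRUE)$counts)
  }
  expect_error(cleave(p84, 1L), class = "hepseq_bad_linkage")
})

test_that("exolytic digestion releases reducing-end disaccharides in order", {
  d <- digest_exo(hp_fixtures()$P8_4)
  expect_length(d$released, 3L)
  expect_true(all(vapply(d$released, function(x)
    disaccharide_units(x)$code, character(1)) == "2SNS6S"))
  expect_identical(format_chain(d$remainder), "dUA-GlcNS6S")
  expect_equal(vapply(d$ladder, chain_dp, integer(1)), c(8L, 6L, 4L))

  one <- digest_exo(hp_fixtures()$P8_4, steps = 1)
  expect_length(one$released, 1L)
  expect_equal(chain_dp(one$remainder), 6L)
})

test_that("3-O-sulfation leaves an inert trisaccharide from fondaparinux", {
  d <- digest_exo(hp_fixtures()$fondaparinux)
  expect_length(d$released, 1L)
  expect_identical(format_chain(d$released[[1]]), "dUA2S-GlcNS6S(OMe)")
  expect_equal(chain_dp(d$remainder), 3L)
  expect_true(any(d$remainder$residues$s3))
})

test_that("2-AB labelling blocks exolysis entirely", {
  lab <- label_2ab(hp_fixtures()$DP13)
  d <- digest_exo(lab)
  expect_length(d$released, 0L)
  expect_identical(format_chain(d$remainder), format_chain(lab))
  expect_error(label_2ab(lab), class = "hepseq_re_occupied")
})

test_that("released products carry dUA only at their nonreducing end", {
  for (seed in 1:25) {
    ch <- random_test_chain(seed)
    d <- digest_exo(ch)
    for (rel in d$released) {
      expect_identical(rel$residues$epimer[1], "dUA")
      expect_false(any(rel$residues$epimer[-1] == "dUA", na.rm = TRUE))
      expect_equal(chain_dp(rel), 2L)
    }
    # remainder keeps the parent's nonreducing-end saturation state
    expect_identical(d$remainder$residues$epimer[1] == "dUA",
                     ch$residues$epimer[1] == "dUA")
  }
})

test_that("exhaustive endolytic digestion reproduces reference digests", {
  hep12 <- heps[c("HepI", "HepII")]
  fr <- digest_endo_exhaustive(hp_fixtures()$P8_4, hep12)
  expect_length(fr, 4L)
  co <- composition_of(fr)
  expect_equal(co[["NS6S"]], 1)
  expect_equal(co[["2SNS6S"]], 3)

  # ozonolysed UDP4 rung: one disaccharide plus one monosaccharide
  udp4 <- digest_exo(hp_fixtures()$P8_4)$ladder[[3]]
  fr3 <- digest_endo_exhaustive(ozone_treat(udp4), hep12)
  co3 <- composition_of(fr3)
  expect_equal(as.numeric(co3), 1)
  expect_equal(names(co3), "2SNS6S")
  side <- attr(co3, "side_channel")
  expect_length(side, 1L)
  expect_equal(chain_dp(side[[1]]), 1L)

  # an unsulfated precursor chain is fully digested by HepIII alone
  n <- 5
  prec <- parse_chain(paste(rep("GlcA-GlcNAc", n), collapse = "-"))
  fr0 <- digest_endo_exhaustive(prec, heps$HepIII)
  expect_length(fr0, n)
  expect_equal(unname(composition_of(fr0)[["0S"]]), n)
})

test_that("endolytic digestion is confluent under randomized orders", {
  hep12 <- heps[c("HepI", "HepII")]
  for (seed in 1:120) {
    ch <- random_test_chain(seed, allow_other = TRUE)
    ref <- chain_multiset(digest_endo_exhaustive(ch, hep12))
    alt <- chain_multiset(random_order_endo(ch, hep12, seed + 1000))
    expect_identical(alt, ref)
  }
})

test_that("ozonolysis removes exactly the unsaturated nonreducing residue", {
  udp4 <- digest_exo(hp_fixtures()$P8_4)$ladder[[3]]
  tr <- ozone_treat(udp4)
  expect_identical(format_chain(tr), "GlcNS6S-IdoA2S-GlcNS6S")
  expect_false(has_delta <- any(tr$residues$epimer == "dUA", na.rm = TRUE))

  dp13 <- ozone_treat(hp_fixtures()$UDP14)
  expect_equal(chain_dp(dp13), 13L)
  expect_error(ozone_treat(parse_chain("GlcA-GlcNAc")),
               class = "hepseq_no_delta")
})

test_that("activity conversion follows Beer-Lambert arithmetic", {
  expect_equal(activity_from_a232(0), 0)
  expect_equal(activity_from_a232(0.0038, path_length = 1, volume = 1e-3),
               0.001)
  expect_equal(activity_from_a232(0.0038, volume = 2e-3),
               2 * activity_from_a232(0.0038, volume = 1e-3))
  expect_error(activity_from_a232(0.1, path_length = 0),
               class = "hepseq_bad_assay")
  expect_error(activity_from_a232(-0.1), class = "hepseq_bad_assay")
})

test_that("enzyme YAML configs merge over shipped defaults", {
  path <- system.file("extdata", "enzymes.yaml", package = "hepseq")
  specs <- read_enzyme_yaml(path)
  expect_setequal(names(specs), c("HepI", "HepII", "HepIII", "exoHep"))
  expect_equal(specs$exoHep$mode, "exo")
  expect_equal(specs$HepIII$cleaves, "unsulfated-uronate")

  ov <- tempfile(fileext = ".yaml")
  writeLines(c("exoHep:", "  min_substrate_dp: 6",
               "endoMut:", "  mode: endo"), ov)
  sp2 <- read_enzyme_yaml(ov)
  expect_equal(sp2$exoHep$min_substrate_dp, 6L)
  expect_equal(sp2$endoMut$mode, "endo")
  writeLines(c("exoHep:", "  bogus_field: 1"), ov)
  expect_error(read_enzyme_yaml(ov), class = "hepseq_bad_config")
})
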