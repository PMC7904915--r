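p84_ladder <- ladder_dataset(
  compositions = list(`2` = c(NS6S = 1, `2SNS6S` = 1),
                      `3` = c(NS6S = 1, `2SNS6S` = 2),
                      `4` = c(NS6S = 1, `2SNS6S` = 3)),
  o3_udp4 = c(`2SNS6S` = 1))

test_that("molar ratios integerise to unit counts within tolerance", {
  out <- integerize(c(NS6S = 0.25, `2SNS6S` = 0.75), 4)
  expect_equal(out, setNames(c(1L, 3L), c("NS6S", "2SNS6S")),
               ignore_attr = TRUE)
  expect_equal(attr(out, "residual"), 0)

  exact <- c(NS6S = 1, `2SNS6S` = 3)
  expect_equal(unname(integerize(exact, 4)), c(1L, 3L), ignore_attr = TRUE)

  err <- tryCatch(integerize(c(NS6S = 0.40, `2SNS6S` = 0.60), 4, tol = 0.2),
                  condition = identity)
  expect_s3_class(err, "hepseq_ambiguous")
  expect_equal(err$candidates[[1]],
               setNames(c(2L, 2L), c("NS6S", "2SNS6S")))
  expect_equal(err$deviations[1], 0.4, tolerance = 1e-12)
  expect_equal(err$candidates[[2]],
               setNames(c(1L, 3L), c("NS6S", "2SNS6S")))

  expect_error(integerize(c(NS6S = -0.1, `2SNS6S` = 1.1), 1),
               class = "hepseq_bad_ladder")
})

test_that("the P8-4 ladder deduces the published sequence", {
  call <- deduce_sequence(p84_ladder)
  expect_identical(
    call$sequence,
    "dUA-GlcNS6S-HexUA2S-GlcNS6S-HexUA2S-GlcNS6S-HexUA2S-GlcNS6S")
  expect_true(all(call$units$status == "determined"))
  expect_equal(call$units$code, c("NS6S", "2SNS6S", "2SNS6S", "2SNS6S"))
  expect_equal(call$residual, 0)
})

test_that("a two-unit ladder resolves from UDP4 and its O3 digest alone", {
  lad <- ladder_dataset(list(`2` = c(NS6S = 1, `2SNS6S` = 1)),
                        o3_udp4 = c(`2SNS6S` = 1))
  call <- deduce_sequence(lad)
  expect_identical(call$sequence, "dUA-GlcNS6S-HexUA2S-GlcNS6S")
})

test_that("a code gaining amount in a smaller fragment is inconsistent", {
  bad <- ladder_dataset(
    compositions = list(`2` = c(NS6S = 1, `2SNS6S` = 1),
                        `3` = c(NS6S = 1, `2SNS6S` = 1, `2SNS` = 1),
                        `4` = c(NS6S = 1, `2SNS6S` = 3)),
    o3_udp4 = c(`2SNS6S` = 1))
  err <- tryCatch(deduce_sequence(bad), condition = identity)
  expect_s3_class(err, "hepseq_inconsistent_ladder")
  expect_equal(err$k, 4L)
})

test_that("zero-noise ladders round-trip random chains exactly", {
  for (seed in 1:60) {
    nu <- 2 + (seed %% 9)  # DP 4..20
    truth <- generate_chain(n_units = nu, seed = seed)
    lad <- simulate_ladder_experiment(truth)
    # nestedness: every successive difference is a unit vector
    if (nu >= 3) for (k in nu:3) {
      a <- lad$compositions[[as.character(k)]]
      b <- lad$compositions[[as.character(k - 1)]]
      codes <- union(names(a), names(b))
      av <- setNames(numeric(length(codes)), codes); av[names(a)] <- a
      bv <- setNames(numeric(length(codes)), codes); bv[names(b)] <- b
      expect_equal(sum(av - bv), 1)
      expect_true(all(av - bv >= 0) && max(av - bv) == 1)
    }
    call <- deduce_sequence(lad)
    expect_true(sequence_accuracy(truth, call)$exact)
  }
})

test_that("the call depends on ratios, not absolute amounts", {
  scaled <- p84_ladder
  scaled$compositions <- lapply(seq_along(scaled$compositions), function(i)
    scaled$compositions[[i]] * c(0.013, 7.7, 120)[i])
  names(scaled$compositions) <- names(p84_ladder$compositions)
  scaled$o3_udp4 <- scaled$o3_udp4 * 0.004
  expect_identical(deduce_sequence(scaled)$sequence,
                   deduce_sequence(p84_ladder)$sequence)
})

test_that("validation recomputes rungs and flags perturbed fractions", {
  call <- deduce_sequence(p84_ladder)
  rep0 <- validate_call(call, p84_ladder)
  expect_true(all(rep0$residual == 0))
  expect_false(any(rep0$flagged))

  pert <- p84_ladder
  pert$compositions[["3"]]["NS6S"] <- pert$compositions[["3"]]["NS6S"] + 0.9
  rep1 <- validate_call(call, pert)
  expect_true(rep1$flagged[rep1$fragment == "UDP6"])
  expect_false(any(rep1$flagged[rep1$fragment != "UDP6"]))
})

test_that("accuracy comparison erases epimers and spots shuffles", {
  truth <- hp_fixtures()$P8_4   # internal uronates are IdoA2S
  call <- deduce_sequence(p84_ladder)
  acc <- sequence_accuracy(truth, call)
  expect_true(acc$exact)       # HexUA2S call matches IdoA2S truth

  shuffled <- parse_chain(
    "dUA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA-GlcNS6S-IdoA2S-GlcNS6S")
  acc2 <- sequence_accuracy(shuffled, call)
  expect_false(acc2$exact)
  expect_false(acc2$matches[1])

  short <- parse_chain("dUA-GlcNS6S-IdoA2S-GlcNS6S")
  expect_true(sequence_accuracy(short, call)$length_mismatch)
})

test_that("non-standard units propagate as undetermined, not failure", {
  lad <- ladder_dataset(
    compositions = list(`2` = c(`2SNS6S` = 1, other = 1),
                        `3` = c(`2SNS6S` = 2, other = 1)),
    o3_udp4 = c(`2SNS6S` = 1))
  call <- deduce_sequence(lad)
  expect_equal(call$units$status[3], "determined")
  expect_equal(call$units$code[3], "2SNS6S")
  expect_equal(call$units$status[1], "undetermined")
  expect_true(is.na(call$sequence))
})
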