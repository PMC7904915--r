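#' Measurement noise model for simulated HPLC compositions
#'
#' Multiplicative lognormal noise on molar amounts (matching how peak areas
#' scatter) plus an optional per-code labelling-efficiency bias emulating
#' differential 2-AB derivatisation of disaccharide species.
#'
#' @param sigma standard deviation of the log-amounts (>= 0; 0 = noiseless).
#' @param labeling_bias optional named vector of efficiency factors in
#'   (0, 1], keyed by disaccharide code.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, labeling_bias = NULL) {
  if (sigma < 0) hepseq_error("sigma must be >= 0", "hepseq_bad_noise")
  if (!is.null(labeling_bias) &&
      (any(labeling_bias <= 0) || any(labeling_bias > 1)))
    hepseq_error("labelling-efficiency factors must lie in (0, 1]",
                 "hepseq_bad_noise")
  structure(list(sigma = sigma, labeling_bias = labeling_bias),
            class = "noise_model")
}

#' Random-chain distribution
#'
#' Describes a population of HP-like chains by disaccharide-unit
#' frequencies plus an epimer policy (lyase products only constrain the
#' sulfation pattern, so GlcA/IdoA are drawn per unit).  The default
#' frequencies emulate the highly sulfated, heparinase III-resistant
#' fraction of heparin that exo-heparinases prefer: dominated by the
#' trisulfated unit, with IdoA strongly favoured at 2-O-sulfated positions.
#'
#' @param unit_freqs named probability vector over the eight standard codes.
#' @param p_idoa_2S probability that a 2-O-sulfated uronate is IdoA.
#' @param p_glca_0S probability that an unsulfated uronate is GlcA.
#' @param nre `"delta"` (chain starts with dUA, as in lyase-derived UDPs)
#'   or `"saturated"`.
#' @return object of class `chain_distribution`.
#' @export
chain_distribution <- function(
    unit_freqs = c(`2SNS6S` = 0.55, NS6S = 0.20, `2SNS` = 0.10, NS = 0.08,
                   `6S` = 0.03, `2S6S` = 0.02, `2S` = 0.01, `0S` = 0.01),
    p_idoa_2S = 0.9, p_glca_0S = 0.7, nre = c("delta", "saturated")) {
  nre <- match.arg(nre)
  if (abs(sum(unit_freqs) - 1) > 1e-8)
    hepseq_error("unit frequencies must sum to 1", "hepseq_bad_dist")
  bad <- setdiff(names(unit_freqs), disaccharide_codes())
  if (length(bad))
    hepseq_error(paste("unknown codes:", paste(bad, collapse = ", ")),
                 "hepseq_bad_dist")
  structure(list(unit_freqs = unit_freqs, p_idoa_2S = p_idoa_2S,
                 p_glca_0S = p_glca_0S, nre = nre),
            class = "chain_distribution")
}

## one unit (uronate, hexosamine) residue pair for a code, epimers drawn
instantiate_unit <- function(code, dist) {
  tab <- code_flag_table()
  i <- match(code, tab$code)
  ep <- if (tab$s2[i]) {
    if (runif(1) < dist$p_idoa_2S) "IdoA" else "GlcA"
  } else {
    if (runif(1) < dist$p_glca_0S) "GlcA" else "IdoA"
  }
  rbind(residue_uronate(ep, s2 = tab$s2[i]),
        residue_hexosamine(tab$nsub[i], s6 = tab$s6[i]))
}

#' Generate a random chain
#'
#' Samples `n_units` disaccharide units from a [chain_distribution()] and
#' concatenates them into a concrete-epimer chain, reproducibly under the
#' seed.
#'
#' @param dist a [chain_distribution()].
#' @param n_units number of disaccharide units (>= 2).
#' @param seed RNG seed.
#' @return a `glycan_chain` of DP `2 * n_units`.
#' @export
generate_chain <- function(dist = chain_distribution(), n_units = 4,
                           seed = 1) {
  if (n_units < 2) hepseq_error("n_units must be >= 2", "hepseq_bad_dist")
  set.seed(as.integer(seed))
  codes <- sample(names(dist$unit_freqs), n_units, replace = TRUE,
                  prob = dist$unit_freqs)
  res <- do.call(rbind, lapply(codes, instantiate_unit, dist = dist))
  if (dist$nre == "delta") res$epimer[1L] <- "dUA"
  glycan_chain(res)
}

#' Simulate the partial-exolysis ladder experiment
#'
#' The in-silico analogue of the sequencing protocol: partial exolytic
#' digestion builds the nested UDP2k ladder; every rung is exhaustively
#' digested with heparinases I+II and its DP2 products counted; the UDP4
#' rung is additionally ozonolysed and re-digested to isolate the second
#' unit.  Counts are converted to molar amounts, multiplied by the optional
#' labelling-efficiency bias, perturbed by lognormal noise and renormalised.
#' With zero noise and no bias the output is exactly integer-valued.
#'
#' @param chain a 3-O-sulfation-free, dUA-started chain of even DP >= 4.
#' @param noise a [noise_model()].
#' @param seed RNG seed (used only when `noise$sigma > 0`).
#' @return a [ladder_dataset()] (provenance `"simulated"`).
#' @examples
#' simulate_ladder_experiment(hp_fixtures()$P8_4)
#' @export
simulate_ladder_experiment <- function(chain, noise = noise_model(),
                                       seed = 1) {
  L <- chain_dp(chain)
  if (L %% 2L != 0L || L < 4L)
    hepseq_error("ladder simulation needs an even DP >= 4", "hepseq_bad_ladder")
  if (!identical(chain$residues$epimer[1L], "dUA"))
    hepseq_error("ladder simulation needs a dUA-started (unsaturated) chain",
                 "hepseq_bad_ladder")
  if (any(chain$residues$s3))
    hepseq_error("ladder simulation needs a 3-O-sulfation-free chain",
                 "hepseq_bad_ladder")
  hep12 <- heparinases()[c("HepI", "HepII")]
  dig <- digest_exo(chain)
  rungs <- dig$ladder
  dps <- vapply(rungs, chain_dp, integer(1))
  if (!identical(dps, seq(L, 4L, by = -2L)))
    hepseq_error("chain did not digest into a complete UDP4..UDP2n ladder",
                 "hepseq_incomplete_ladder")
  set.seed(as.integer(seed))
  measure <- function(counts) {
    amounts <- as.numeric(counts)
    names(amounts) <- names(counts)
    if (!is.null(noise$labeling_bias)) {
      f <- noise$labeling_bias[names(amounts)]
      f[is.na(f)] <- 1
      amounts <- amounts * f
    }
    if (noise$sigma > 0)
      amounts <- amounts * exp(rnorm(length(amounts), 0, noise$sigma))
    amounts / sum(amounts) * sum(counts)
  }
  comps <- lapply(rungs, function(rg)
    measure(composition_of(digest_endo_exhaustive(rg, hep12))))
  names(comps) <- dps / 2L
  udp4 <- rungs[[length(rungs)]]
  o3 <- composition_of(digest_endo_exhaustive(ozone_treat(udp4), hep12))
  ladder_dataset(compositions = comps, o3_udp4 = measure(o3),
                 provenance = "simulated", nre_unsaturated = TRUE)
}

#' Reference oligosaccharide fixtures
#'
#' The structure-defined substrates used throughout: the five reference HP
#' tetrasaccharides P4-4 ... P4-8 (P4-4 and P4-5 as their two-epimer
#' mixtures), the synthetic 3-O-sulfated pentasaccharide fondaparinux
#' (methyl glycoside at the reducing end), the fully sequenced
#' octasaccharide P8-4 (internal 2-O-sulfated uronates instantiated as
#' IdoA2S, the HP-typical epimer — a choice invisible at composition
#' level), the unsaturated tetradecasaccharide UDP14 of uniform trisulfated
#' units, its ozonolysis product DP13, and a DP13 variant mixing tri- and
#' disulfated units.
#'
#' @return named list; elements are `glycan_chain`s, except `P4_4` and
#'   `P4_5` which are lists of two chains (GlcA and IdoA forms).
#' @export
hp_fixtures <- function() {
  pc <- parse_chain
  tri <- paste(rep("IdoA2S-GlcNS6S", 6L), collapse = "-")
  list(
    P4_4 = list(pc("dUA-GlcNAc6S-GlcA-GlcNS6S"),
                pc("dUA-GlcNAc6S-IdoA-GlcNS6S")),
    P4_5 = list(pc("dUA-GlcNS-GlcA-GlcNS6S"),
                pc("dUA-GlcNS-IdoA-GlcNS6S")),
    P4_6 = pc("dUA-GlcNS6S-GlcA-GlcNS6S"),
    P4_7 = pc("dUA2S-GlcNS6S-GlcA-GlcNS6S"),
    P4_8 = pc("dUA2S-GlcNS6S-IdoA2S-GlcNS6S"),
    fondaparinux = pc("GlcNS6S-GlcA-GlcNS3S6S-IdoA2S-GlcNS6S(OMe)"),
    P8_4 = pc(paste("dUA-GlcNS6S", "IdoA2S-GlcNS6S", "IdoA2S-GlcNS6S",
                    "IdoA2S-GlcNS6S", sep = "-")),
    UDP14 = pc(paste("dUA2S-GlcNS6S", tri, sep = "-")),
    DP13 = pc(paste("GlcNS6S", tri, sep = "-")),
    DP13_mixed = pc(paste("GlcNS6S",
                          paste(rep("IdoA2S-GlcNS6S", 4L), collapse = "-"),
                          "IdoA2S-GlcNS", "IdoA2S-GlcNS", sep = "-"))
  )
}

#' Sequence-recovery benchmark
#'
#' Generates random chains, simulates their ladder experiments across a
#' noise grid, runs the sequencer and scores recovery (exact call up to
#' epimer erasure).  Chains whose ladder cannot be integerised or is
#' internally inconsistent under noise count as failures.
#'
#' @param n_chains chains per noise level.
#' @param n_units units per chain (scalar or range to sample from).
#' @param dist a [chain_distribution()].
#' @param sigmas noise grid (lognormal sigma values).
#' @param seed master seed; per-chain seeds are derived from it.
#' @param tol sequencer tolerance.
#' @return data.frame with columns `sigma`, `recovered` (fraction), `n`.
#' @export
recovery_benchmark <- function(n_chains = 100, n_units = 4,
                               dist = chain_distribution(),
                               sigmas = c(0, 0.02, 0.05, 0.1),
                               seed = 1, tol = 0.2) {
  rows <- lapply(seq_along(sigmas), function(si) {
    sigma <- sigmas[si]
    ok <- vapply(seq_len(n_chains), function(i) {
      s <- (seed * 10000L + si * 1000L + i) %% .Machine$integer.max
      nu <- if (length(n_units) > 1L)
        n_units[1L + (i %% length(n_units))] else n_units
      truth <- generate_chain(dist, n_units = nu, seed = s)
      lad <- simulate_ladder_experiment(truth, noise_model(sigma),
                                        seed = s + 1L)
      call <- tryCatch(deduce_sequence(lad, tol = tol),
                       hepseq_error = function(e) NULL)
      !is.null(call) && sequence_accuracy(truth, call)$exact
    }, logical(1))
    data.frame(sigma = sigma, recovered = mean(ok), n = n_chains)
  })
  do.call(rbind, rows)
}
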