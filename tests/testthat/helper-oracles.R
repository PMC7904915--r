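# Independent oracles, written directly from textbook residue compositions
# and never calling the package's formula machinery.

# free-monosaccharide elemental compositions (C, H, N, O, S)
.ORACLE_FREE <- list(
  sat_uronate = c(C = 6, H = 10, N = 0, O = 7, S = 0),  # GlcA/IdoA/HexUA
  delta_uronate = c(C = 6, H = 8, N = 0, O = 6, S = 0), # 4,5-unsaturated
  glcn = c(C = 6, H = 13, N = 1, O = 5, S = 0)          # free amine
)
.ORACLE_ACETYL <- c(C = 2, H = 2, N = 0, O = 1, S = 0)
.ORACLE_SO3 <- c(C = 0, H = 0, N = 0, O = 3, S = 1)
.ORACLE_H2O <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
.ORACLE_OME <- c(C = 1, H = 2, N = 0, O = 0, S = 0)
.ORACLE_2AB <- c(C = 7, H = 8, N = 2, O = 0, S = 0)
.ORACLE_MONO <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)

# counts of an arbitrary chain string, by direct token counting
oracle_counts <- function(s) {
  mod <- regmatches(s, regexec("\\((OMe|2AB)\\)$", s))[[1]]
  s <- sub("\\((OMe|2AB)\\)$", "", s)
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  total <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (tok in toks) {
    n_sulf <- (nchar(tok) - nchar(gsub("2S|3S|6S", "", tok))) / 2
    core <- gsub("2S|3S|6S", "", tok)
    base <- switch(core,
                   dUA = .ORACLE_FREE$delta_uronate,
                   GlcA = , IdoA = , HexUA = .ORACLE_FREE$sat_uronate,
                   GlcNAc = .ORACLE_FREE$glcn + .ORACLE_ACETYL,
                   GlcNS = .ORACLE_FREE$glcn + .ORACLE_SO3,
                   GlcNH = .ORACLE_FREE$glcn,
                   stop("oracle: unknown token ", tok))
    # the O-sulfate suffixes are 2S/3S/6S; GlcNS' N-sulfate came in with the core
    total <- total + base + n_sulf * .ORACLE_SO3
  }
  total <- total - (length(toks) - 1) * .ORACLE_H2O
  if (length(mod))
    total <- total + (if (mod[2] == "OMe") .ORACLE_OME else .ORACLE_2AB)
  total
}

oracle_mono_mass <- function(s) sum(oracle_counts(s) * .ORACLE_MONO)

# package formula -> plain counts vector for comparison
pkg_counts <- function(f) f$counts[c("C", "H", "N", "O", "S")]

# brute-force protein property recomputation (independent of R/io.R)
oracle_protein <- function(seq) {
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  aa <- strsplit(seq, "")[[1]]
  mass <- sum(masses[aa]) + 18.01524
  nterm_pka <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                 V = 7.44, E = 7.70, G = 7.50)
  npk <- if (aa[1] %in% names(nterm_pka)) nterm_pka[[aa[1]]] else 7.5
  charge <- function(pH) {
    pos <- 1 / (1 + 10^(pH - npk)) +
      sum(aa == "K") / (1 + 10^(pH - 10)) +
      sum(aa == "R") / (1 + 10^(pH - 12)) +
      sum(aa == "H") / (1 + 10^(pH - 5.98))
    neg <- 1 / (1 + 10^(3.55 - pH)) +
      sum(aa == "D") / (1 + 10^(4.05 - pH)) +
      sum(aa == "E") / (1 + 10^(4.45 - pH)) +
      sum(aa == "C") / (1 + 10^(9.0 - pH)) +
      sum(aa == "Y") / (1 + 10^(10.0 - pH))
    pos - neg
  }
  pI <- uniroot(charge, c(0, 14), tol = 1e-10)$root
  list(length = length(aa), average_mass = mass, pI = pI)
}

# random valid chain for property tests (even DP, concrete epimers)
random_test_chain <- function(seed, n_units = NULL, allow_other = FALSE,
                              re_mod_choices = "none") {
  set.seed(seed)
  if (is.null(n_units)) n_units <- sample(2:8, 1)
  rows <- list()
  for (u in seq_len(n_units)) {
    ep <- sample(c("GlcA", "IdoA"), 1)
    s2 <- runif(1) < 0.5
    nsub <- sample(if (allow_other) c("Ac", "S", "H") else c("Ac", "S"), 1)
    s3 <- allow_other && runif(1) < 0.15
    s6 <- runif(1) < 0.5
    rows[[2 * u - 1]] <- data.frame(kind = "uronate", epimer = ep,
                                    nsub = NA_character_, s2 = s2, s3 = FALSE,
                                    s6 = FALSE, stringsAsFactors = FALSE)
    rows[[2 * u]] <- data.frame(kind = "hexosamine", epimer = NA_character_,
                                nsub = nsub, s2 = FALSE, s3 = s3, s6 = s6,
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (runif(1) < 0.5) res$epimer[1] <- "dUA"
  glycan_chain(res, re_mod = sample(re_mod_choices, 1))
}

# multiset comparison of chain lists by canonical strings
chain_multiset <- function(chains)
  sort(vapply(chains, format_chain, character(1)))

# randomized-order exhaustive endolytic digestion (confluence oracle)
random_order_endo <- function(chain, enzymes, seed) {
  set.seed(seed)
  work <- list(chain)
  final <- list()
  while (length(work)) {
    i <- sample.int(length(work), 1)
    cur <- work[[i]]
    work <- work[-i]
    sites <- unique(unlist(lapply(enzymes, function(e)
      cleavable_linkages(cur, e))))
    if (!length(sites)) {
      final[[length(final) + 1]] <- cur
    } else {
      j <- if (length(sites) == 1) sites else sample(sites, 1)
      p <- cleave(cur, j)
      work <- c(work, list(p$nre, p$re))
    }
  }
  final
}
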