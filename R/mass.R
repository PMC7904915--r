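## Fixed atomic-mass table (IUPAC 2021 monoisotopic / standard atomic
## weights).  All formula arithmetic in the package goes through this table.
ATOMS <- list(
  mono = c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069),
  avg  = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06),
  proton = 1.007276466879
)

mf <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
  counts <- c(C = C, H = H, N = N, O = O, S = S)
  structure(list(counts = counts,
                 monoisotopic = sum(counts * ATOMS$mono),
                 average = sum(counts * ATOMS$avg)),
            class = "molecular_formula")
}

mf_from_counts <- function(counts) do.call(mf, as.list(counts))

#' @export
`+.molecular_formula` <- function(e1, e2) mf_from_counts(e1$counts + e2$counts)

#' @export
`-.molecular_formula` <- function(e1, e2) {
  counts <- e1$counts - e2$counts
  if (any(counts < 0))
    hepseq_error("formula subtraction went negative", "hepseq_formula_error")
  mf_from_counts(counts)
}

#' @export
format.molecular_formula <- function(x, ...) {
  n <- x$counts
  paste0(vapply(names(n), function(el) {
    if (n[[el]] == 0) "" else if (n[[el]] == 1) el else paste0(el, n[[el]])
  }, character(1)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(sprintf("<formula> %s  mono %.4f Da  avg %.3f Da\n",
              format(x), x$monoisotopic, x$average))
  invisible(x)
}

H2O <- function() mf(H = 2, O = 1)
SO3 <- function() mf(S = 1, O = 3)

## Glycosidically linked residue formulas (free monosaccharide minus H2O):
##   saturated uronate  C6H8O6      4,5-unsaturated uronate C6H6O5
##   glucosamine (free amine) C6H11NO4;  N-acetyl +C2H2O;  each sulfate +SO3
residue_formula <- function(row) {
  f <- if (row$kind == "uronate") {
    if (row$epimer == "dUA") mf(C = 6, H = 6, O = 5) else mf(C = 6, H = 8, O = 6)
  } else {
    base <- mf(C = 6, H = 11, N = 1, O = 4)
    if (row$nsub == "Ac") base <- base + mf(C = 2, H = 2, O = 1)
    if (row$nsub == "S") base <- base + SO3()
    base
  }
  n_os <- sum(c(row$s2, row$s3, row$s6))
  if (n_os > 0) f <- f + mf_from_counts(SO3()$counts * n_os)
  f
}

re_mod_delta <- function(re_mod) {
  switch(re_mod,
         none = mf(),
         OMe = mf(C = 1, H = 2),            # methyl glycoside: +CH2
         `2AB` = mf(C = 7, H = 8, N = 2))   # reductive amination: +C7H8N2
}

#' Elemental formula and mass of a chain
#'
#' Sums residue formulas plus one water for the chain termini plus the
#' reducing-end modification delta (OMe +CH2; 2-AB label +C7H8N2 from
#' reductive amination).  GlcA and IdoA are isomers, so the epimer never
#' changes the formula; an epimer-erased (`HexUA`) chain therefore still has
#' a well-defined formula at sulfation level, but this must be requested
#' explicitly via `sulfation_level = TRUE`.
#'
#' @param chain a `glycan_chain`.
#' @param sulfation_level allow `HexUA` residues (formula defined by
#'   sulfation only).
#' @return a `molecular_formula` with element counts and monoisotopic /
#'   average masses (Da).
#' @examples
#' formula_of(parse_chain("dUA-GlcNAc"))
#' @export
formula_of <- function(chain, sulfation_level = FALSE) {
  if (!sulfation_level && !has_concrete_epimers(chain))
    hepseq_error(paste("epimer-erased chain has a defined formula only at",
                       "composition level; pass sulfation_level = TRUE"),
                 "hepseq_epimer_erased")
  f <- H2O() + re_mod_delta(chain$re_mod)
  for (i in seq_len(chain_dp(chain)))
    f <- f + residue_formula(chain$residues[i, , drop = FALSE])
  f
}

#' m/z of a deprotonated ion
#'
#' Negative-mode electrospray observes glycosaminoglycans as `[M - zH]^z-`
#' ions; this is the corresponding m/z.
#'
#' @param mass neutral mass in Da.
#' @param z positive charge count (number of protons removed).
#' @return m/z value.
#' @examples
#' mz(665.4, 2)
#' @export
mz <- function(mass, z) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z))
    hepseq_error("z must be a positive integer", "hepseq_bad_charge")
  (mass - z * ATOMS$proton) / z
}

#' Theoretical glycosidic fragment ions
#'
#' Emits the B/C (nonreducing-end side) and Y/Z (reducing-end side)
#' glycosidic fragments at every linkage of a chain, 4 per linkage, with
#' formulas and neutral masses.  C and Y fragments at one bond sum to the
#' parent formula plus one water.
#'
#' @inheritParams formula_of
#' @return data.frame with columns `label`, `type`, `index`, `formula`,
#'   `monoisotopic`, `average`.
#' @export
fragment_ladder <- function(chain, sulfation_level = FALSE) {
  if (!sulfation_level && !has_concrete_epimers(chain))
    hepseq_error("epimer-erased chain: pass sulfation_level = TRUE",
                 "hepseq_epimer_erased")
  L <- chain_dp(chain)
  res_f <- lapply(seq_len(L), function(i)
    residue_formula(chain$residues[i, , drop = FALSE]))
  out <- list()
  for (i in seq_len(L - 1L)) {
    cf <- Reduce(`+`, res_f[1:i], mf()) + H2O()
    yf <- Reduce(`+`, res_f[(i + 1L):L], mf()) + H2O() +
      re_mod_delta(chain$re_mod)
    j <- L - i
    frags <- list(B = cf - H2O(), C = cf, Y = yf, Z = yf - H2O())
    idx <- c(B = i, C = i, Y = j, Z = j)
    for (ty in names(frags)) {
      f <- frags[[ty]]
      out[[length(out) + 1L]] <- data.frame(
        label = paste0(ty, idx[[ty]]), type = ty, index = idx[[ty]],
        formula = format(f), monoisotopic = f$monoisotopic,
        average = f$average, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
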