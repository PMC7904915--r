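#' Define a heparinase specificity
#'
#' A lyase spec is the yes/no cleavage predicate used by the digestion
#' engines: its action mode (endolytic = internal sites; exolytic =
#' reducing-end disaccharide release only), the uronate sulfation classes it
#' cleaves next to (2-O-sulfated and/or unsulfated), whether 3-O-sulfation
#' of the flanking glucosamine blocks it, and the smallest substrate it
#' accepts.  Rate differences between cleavable contexts are handled
#' separately by [rate_table()].
#'
#' @param name label used in reports.
#' @param mode `"endo"` or `"exo"`.
#' @param cleaves subset of `c("2S-uronate", "unsulfated-uronate")`.
#' @param blocks_on_3S if `TRUE` (default, true of all characterised
#'   heparinases) a linkage whose released disaccharide would contain a
#'   3-O-sulfated glucosamine is uncleavable.
#' @param min_substrate_dp smallest chain DP acted on (>= 4 for exo, >= 3
#'   for endo).
#' @return an object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, mode = c("endo", "exo"),
                        cleaves = c("2S-uronate", "unsulfated-uronate"),
                        blocks_on_3S = TRUE,
                        min_substrate_dp = if (mode[1] == "exo") 4L else 3L) {
  mode <- match.arg(mode)
  cleaves <- match.arg(cleaves, several.ok = TRUE)
  min_substrate_dp <- as.integer(min_substrate_dp)
  if (mode == "exo" && min_substrate_dp < 4L)
    hepseq_error("exo specs need min_substrate_dp >= 4", "hepseq_bad_spec")
  if (mode == "endo" && min_substrate_dp < 3L)
    hepseq_error("endo specs need min_substrate_dp >= 3", "hepseq_bad_spec")
  structure(list(name = name, mode = mode, cleaves = cleaves,
                 blocks_on_3S = isTRUE(blocks_on_3S),
                 min_substrate_dp = min_substrate_dp),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s (%s): cleaves %s; 3S block %s; min DP %d\n",
              x$name, x$mode, paste(x$cleaves, collapse = " + "),
              if (x$blocks_on_3S) "on" else "off", x$min_substrate_dp))
  invisible(x)
}

#' Default heparinase specs
#'
#' The shipped defaults: heparinase I (endolytic, cleaves linkages to
#' 2-O-sulfated uronates), heparinase III (endolytic, unsulfated uronates
#' only), heparinase II (endolytic, no uronate selectivity), and the PL15_2
#' exo-heparinase (exolytic, no uronate selectivity, blocked by 2-AB
#' labelling of the reducing end).  All are blocked by 3-O-sulfation.
#'
#' @return named list of [enzyme_spec()] objects
#'   (`HepI`, `HepII`, `HepIII`, `exoHep`).
#' @export
heparinases <- function() {
  list(
    HepI   = enzyme_spec("HepI", "endo", "2S-uronate"),
    HepII  = enzyme_spec("HepII", "endo",
                         c("2S-uronate", "unsulfated-uronate")),
    HepIII = enzyme_spec("HepIII", "endo", "unsulfated-uronate"),
    exoHep = enzyme_spec("exoHep", "exo",
                         c("2S-uronate", "unsulfated-uronate"))
  )
}

uronate_class <- function(row) if (row$s2) "2S-uronate" else "unsulfated-uronate"

## Is linkage j (joining residues j and j+1) cleavable by `enzyme`?
## Requires hexosamine at j, saturated concrete uronate at j+1 of a cleavable
## class; the 3S block looks at the hexosamine at j+2 — the residue that ends
## up in the released / newly dUA-bearing disaccharide (+2 subsite).
linkage_ok <- function(r, j, enzyme) {
  L <- nrow(r)
  if (j < 1L || j + 1L > L) return(FALSE)
  if (r$kind[j] != "hexosamine" || r$kind[j + 1L] != "uronate") return(FALSE)
  if (r$epimer[j + 1L] == "dUA") return(FALSE)
  if (!uronate_class(r[j + 1L, , drop = FALSE]) %in% enzyme$cleaves)
    return(FALSE)
  if (enzyme$blocks_on_3S && j + 2L <= L && r$s3[j + 2L]) return(FALSE)
  TRUE
}

#' Cleavable linkages of a chain
#'
#' Indices `j` of the glycosidic linkages (joining residues `j` and `j+1`,
#' counted from the nonreducing end) that the given enzyme can cleave.
#' beta-elimination acts on hexosamine-to-uronate bonds, so residue `j` must
#' be a hexosamine and residue `j+1` a saturated uronate of a cleavable
#' sulfation class; for an exolytic spec only the reducing-end linkage
#' `j = L - 2` is ever eligible, the reducing-end residue must be a
#' hexosamine, the chain must reach `min_substrate_dp`, and a 2-AB-labelled
#' reducing end abolishes action entirely.
#'
#' @param chain a `glycan_chain` with concrete epimers.
#' @param enzyme an [enzyme_spec()].
#' @return integer vector of linkage indices (possibly empty).
#' @export
cleavable_linkages <- function(chain, enzyme) {
  if (!has_concrete_epimers(chain))
    hepseq_error("digestion needs concrete epimers (no HexUA)",
                 "hepseq_epimer_erased")
  r <- chain$residues
  L <- nrow(r)
  if (L < enzyme$min_substrate_dp) return(integer(0))
  if (enzyme$mode == "exo") {
    if (chain$re_mod == "2AB") return(integer(0))
    if (r$kind[L] != "hexosamine") return(integer(0))
    j <- L - 2L
    return(if (linkage_ok(r, j, enzyme)) j else integer(0))
  }
  Filter(function(j) linkage_ok(r, j, enzyme), seq_len(L - 1L))
}

#' Cleave a chain at one linkage
#'
#' beta-eliminative lyase cleavage of the hexosamine(j) -> uronate(j+1)
#' bond: the nonreducing-side product is residues `1..j` with a free
#' reducing end; the reducing-side product is residues `j+1..L` whose first
#' residue becomes the 4,5-unsaturated uronate (epimer erased, 2-O-sulfate
#' retained) and which inherits the parent's reducing-end modification.  No
#' water is consumed, so the product formulas sum exactly to the parent
#' formula.
#'
#' @param chain a `glycan_chain`.
#' @param j linkage index; residue `j` must be a hexosamine and `j+1` a
#'   uronate.
#' @return list with elements `nre` and `re`, both `glycan_chain`.
#' @export
cleave <- function(chain, j) {
  r <- chain$residues
  L <- nrow(r)
  if (!(j >= 1L && j + 1L <= L && r$kind[j] == "hexosamine" &&
        r$kind[j + 1L] == "uronate"))
    hepseq_error(sprintf("linkage %d is not hexosamine->uronate", j),
                 "hepseq_bad_linkage")
  nre <- subchain(chain, 1L, j)
  re <- subchain(chain, j + 1L, L)
  re$residues$epimer[1L] <- "dUA"
  validate_chain(re)
  list(nre = nre, re = re)
}

#' Exolytic digestion
#'
#' Repeatedly releases the reducing-end disaccharide while the exolytic
#' predicate allows it.  The ladder of substrate states encountered (the
#' parent and each shortened intermediate actually cleaved) is returned —
#' these are the nested UDP2k nonreducing-end fragments that the ladder
#' sequencing strategy isolates.
#'
#' @param chain substrate `glycan_chain` (concrete epimers).
#' @param enzyme an exolytic [enzyme_spec()]; default [heparinases()]
#'   `$exoHep`.
#' @param steps number of release events, or `"to_completion"`.
#' @return list with `released` (DP2 chains in release order), `remainder`
#'   (the final inert chain), and `ladder` (chains cleaved, largest first;
#'   just the parent if nothing was cleavable).
#' @examples
#' d <- digest_exo(hp_fixtures()$P8_4)
#' vapply(d$ladder, chain_dp, integer(1))
#' @export
digest_exo <- function(chain, enzyme = heparinases()$exoHep,
                       steps = "to_completion") {
  if (enzyme$mode != "exo")
    hepseq_error("digest_exo needs an exolytic spec", "hepseq_bad_spec")
  to_completion <- identical(steps, "to_completion")
  if (!to_completion) steps <- as.integer(steps)
  released <- list()
  ladder <- list()
  current <- chain
  while (to_completion || steps > length(released)) {
    sites <- cleavable_linkages(current, enzyme)
    if (!length(sites)) break
    pieces <- cleave(current, sites[[1L]])
    ladder[[length(ladder) + 1L]] <- current
    released[[length(released) + 1L]] <- pieces$re
    current <- pieces$nre
  }
  if (!length(ladder)) ladder <- list(chain)
  list(released = released, remainder = current, ladder = ladder)
}

#' Exhaustive endolytic digestion
#'
#' Cleaves every linkage cleavable by any enzyme of the set until none
#' remains.  Because cleavages at distinct sites commute, the final product
#' multiset is independent of the internal order (confluence).
#'
#' @param chain substrate `glycan_chain`.
#' @param enzymes list of endolytic [enzyme_spec()]s (a single spec is
#'   accepted).
#' @return list of product `glycan_chain`s, in nonreducing-to-reducing
#'   order of their origin in the parent.
#' @examples
#' fr <- digest_endo_exhaustive(hp_fixtures()$P8_4,
#'                              heparinases()[c("HepI", "HepII")])
#' composition_of(fr)
#' @export
digest_endo_exhaustive <- function(chain, enzymes) {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  work <- list(chain)
  final <- list()
  while (length(work)) {
    cur <- work[[1L]]
    work <- work[-1L]
    sites <- sort(unique(unlist(lapply(enzymes, function(e)
      cleavable_linkages(cur, e)))))
    if (!length(sites)) {
      final[[length(final) + 1L]] <- cur
    } else {
      pieces <- cleave(cur, sites[[1L]])
      work <- c(list(pieces$nre, pieces$re), work)
    }
  }
  final
}

#' Ozonolysis trimming of the unsaturated nonreducing end
#'
#' O3 treatment removes the 4,5-unsaturated uronate from the nonreducing
#' end, yielding a saturated chain one residue shorter with no 232-nm
#' chromophore — the preparation used both for saturated DP13 substrate and
#' for the B-site determination step of ladder sequencing.
#'
#' @param chain a `glycan_chain` starting with `dUA`.
#' @return the trimmed `glycan_chain`.
#' @export
ozone_treat <- function(chain) {
  if (!identical(chain$residues$epimer[1L], "dUA"))
    hepseq_error("no Δ4,5-unsaturated residue to remove",
                 "hepseq_no_delta")
  subchain(chain, 2L, chain_dp(chain))
}

#' 2-AB labelling of the reducing end
#'
#' Attaches the 2-aminobenzamide fluorophore by reductive amination.  A
#' labelled reducing end is refractory to exolytic attack.
#'
#' @param chain a `glycan_chain` with an unmodified reducing end.
#' @return the labelled chain (`re_mod = "2AB"`).
#' @export
label_2ab <- function(chain) {
  if (chain$re_mod != "none")
    hepseq_error(sprintf("reducing end already carries %s", chain$re_mod),
                 "hepseq_re_occupied")
  chain$re_mod <- "2AB"
  chain
}

#' Lyase activity from A232 slope
#'
#' Converts the rate of 232-nm absorbance increase into enzyme units via
#' Beer-Lambert, using the molar extinction coefficient of the unsaturated
#' products (3800 M^-1 cm^-1 by default).  1 U = 1 umol of dUA-containing
#' product per minute.
#'
#' @param slope dA232/dt in absorbance/min (>= 0).
#' @param epsilon_232 molar extinction coefficient, M^-1 cm^-1.
#' @param path_length cuvette path in cm.
#' @param volume reaction volume in litres.
#' @return activity in U.
#' @examples
#' activity_from_a232(0.0038, path_length = 1, volume = 1e-3)
#' @export
activity_from_a232 <- function(slope, epsilon_232 = 3800,
                               path_length = 1, volume = 1e-3) {
  if (path_length <= 0 || volume <= 0)
    hepseq_error("path length and volume must be positive",
                 "hepseq_bad_assay")
  if (slope < 0)
    hepseq_error("slope must be nonnegative", "hepseq_bad_assay")
  slope / (epsilon_232 * path_length) * volume * 1e6
}
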