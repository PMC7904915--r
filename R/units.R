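## The eight standard unsaturated HP/HS disaccharide short codes, keyed by
## (uronate 2S, hexosamine N-substituent, hexosamine 6S).  Units carrying 3S
## or a free amine (GlcNH) have no commercial standard and map to "other".

#' Standard disaccharide codes
#'
#' The eight short codes for the standard unsaturated HP/HS disaccharides,
#' spanning the combinations of uronate 2-O-sulfation, N-acetyl vs N-sulfo
#' glucosamine, and 6-O-sulfation (e.g. `0S` = dUA-GlcNAc, `2SNS6S` =
#' dUA2S-GlcNS6S).
#'
#' @return character vector of the eight codes, in conventional order.
#' @export
disaccharide_codes <- function() {
  c("0S", "6S", "2S", "NS", "2S6S", "NS6S", "2SNS", "2SNS6S")
}

code_flag_table <- function() {
  data.frame(
    code = disaccharide_codes(),
    s2  = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    nsub = c("Ac", "Ac", "Ac", "S", "Ac", "S", "S", "S"),
    s6  = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

## code of a (uronate, hexosamine) residue pair; 3S or GlcNH -> "other"
unit_code_rows <- function(uro, hex) {
  if (hex$s3 || hex$nsub == "H" || uro$s3 || uro$s6) return("other")
  tab <- code_flag_table()
  hit <- tab$s2 == uro$s2 & tab$nsub == hex$nsub & tab$s6 == hex$s6
  tab$code[hit]
}

#' Decompose a chain into disaccharide units
#'
#' Pairs residues into (uronate, hexosamine) units anchored at the reducing
#' end, consistent with exolytic release: the last two residues form the
#' RE-most unit and pairing steps back by two.  An odd-length chain (e.g.
#' after ozonolysis trimming) leaves its nonreducing-end residue unpaired.
#'
#' @param chain a `glycan_chain`.
#' @return data.frame with one row per unit, NRE to RE, columns `uronate`,
#'   `hexosamine` (residue tokens), `code` (one of the eight standard codes
#'   or `"other"`), `pos_uronate`, `pos_hexosamine`; leftover NRE residues
#'   (if any) are attached as attribute `"unpaired"` (a `glycan_chain`).
#' @examples
#' disaccharide_units(parse_chain("dUA2S-GlcNS6S"))$code
#' @export
disaccharide_units <- function(chain) {
  r <- chain$residues
  L <- nrow(r)
  hi <- L
  rows <- list()
  while (hi >= 2L &&
         r$kind[hi] == "hexosamine" && r$kind[hi - 1L] == "uronate") {
    uro <- r[hi - 1L, , drop = FALSE]
    hex <- r[hi, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      uronate = format_residue(uro), hexosamine = format_residue(hex),
      code = unit_code_rows(uro, hex),
      pos_uronate = hi - 1L, pos_hexosamine = hi,
      stringsAsFactors = FALSE)
    hi <- hi - 2L
  }
  units <- if (length(rows)) do.call(rbind, rev(rows)) else
    data.frame(uronate = character(), hexosamine = character(),
               code = character(), pos_uronate = integer(),
               pos_hexosamine = integer(), stringsAsFactors = FALSE)
  rownames(units) <- NULL
  if (hi >= 1L) attr(units, "unpaired") <- subchain(chain, 1L, hi)
  units
}

#' Composition vector of a fragment collection
#'
#' Counts the disaccharide (DP2) fragments of a digest by standard code —
#' the in-silico analogue of a disaccharide-composition HPLC run.  Fragments
#' that are not standard DP2 disaccharides (monosaccharides, DP >= 3
#' remainders, hexosamine-first DP2) are excluded from the vector and kept in
#' a side channel.
#'
#' @param fragments list of `glycan_chain` objects (or a single chain).
#' @return named numeric vector of molar counts keyed by code, with
#'   attribute `"side_channel"` holding the excluded fragments (possibly an
#'   empty list).
#' @examples
#' fr <- digest_endo_exhaustive(hp_fixtures()$P8_4,
#'                              heparinases()[c("HepI", "HepII")])
#' composition_of(fr)
#' @export
composition_of <- function(fragments) {
  if (inherits(fragments, "glycan_chain")) fragments <- list(fragments)
  counts <- numeric(0)
  side <- list()
  for (fr in fragments) {
    r <- fr$residues
    if (nrow(r) == 2L && r$kind[1] == "uronate" && r$kind[2] == "hexosamine") {
      code <- unit_code_rows(r[1, , drop = FALSE], r[2, , drop = FALSE])
      counts[code] <- (if (code %in% names(counts)) counts[[code]] else 0) + 1
    } else {
      side[[length(side) + 1L]] <- fr
    }
  }
  structure(counts, side_channel = side)
}

## code -> rendered unit string; NRE units show dUA, internal units HexUA
code_to_unit_string <- function(code, nre = FALSE) {
  tab <- code_flag_table()
  i <- match(code, tab$code)
  if (is.na(i))
    hepseq_error(sprintf("cannot render non-standard code '%s'", code),
                 "hepseq_invalid_code")
  uro <- paste0(if (nre) "dUA" else "HexUA", if (tab$s2[i]) "2S")
  hex <- paste0("GlcN", tab$nsub[i], if (tab$s6[i]) "6S")
  paste0(uro, "-", hex)
}
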