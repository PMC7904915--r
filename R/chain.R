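## Residues are rows of a data.frame with columns:
##   kind   : "uronate" | "hexosamine"
##   epimer : "GlcA" | "IdoA" | "dUA" | "HexUA"   (uronates; NA otherwise)
##   nsub   : "Ac" | "S" | "H"                    (hexosamines; NA otherwise)
##   s2, s3, s6 : logical sulfation flags
## A chain reads nonreducing end (position 1) -> reducing end (position L);
## all linkages are 1->4 and implicit.

hepseq_error <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "hepseq_error"), ...))
}

residue_uronate <- function(epimer, s2 = FALSE) {
  data.frame(kind = "uronate", epimer = epimer, nsub = NA_character_,
             s2 = s2, s3 = FALSE, s6 = FALSE, stringsAsFactors = FALSE)
}

residue_hexosamine <- function(nsub, s3 = FALSE, s6 = FALSE) {
  data.frame(kind = "hexosamine", epimer = NA_character_, nsub = nsub,
             s2 = FALSE, s3 = s3, s6 = s6, stringsAsFactors = FALSE)
}

#' Construct a glycan chain
#'
#' Builds a heparin/heparan-sulfate chain object from a residue table.  Most
#' users will call [parse_chain()] instead; this constructor is the
#' programmatic back door and runs the full set of structural invariants.
#'
#' @param residues data.frame of residues, one row per residue from the
#'   nonreducing end (NRE, position 1) to the reducing end (RE), with columns
#'   `kind`, `epimer`, `nsub`, `s2`, `s3`, `s6`.
#' @param re_mod reducing-end modification: `"none"`, `"OMe"` (methyl
#'   glycoside) or `"2AB"` (2-aminobenzamide label).
#' @return an object of class `glycan_chain`.
#' @export
glycan_chain <- function(residues, re_mod = "none") {
  re_mod <- match.arg(re_mod, c("none", "OMe", "2AB"))
  chain <- structure(list(residues = residues, re_mod = re_mod),
                     class = "glycan_chain")
  validate_chain(chain)
  chain
}

validate_chain <- function(chain) {
  r <- chain$residues
  if (nrow(r) < 1L)
    hepseq_error("a chain needs at least one residue", "hepseq_invalid_chain")
  for (i in seq_len(nrow(r))) {
    if (i > 1L && r$kind[i] == r$kind[i - 1L])
      hepseq_error(sprintf(
        "ring classes must alternate: two %ss adjacent at position %d",
        r$kind[i], i), "hepseq_invalid_chain", position = i)
    if (r$kind[i] == "uronate") {
      if (r$s3[i] || r$s6[i])
        hepseq_error(sprintf("3S/6S illegal on a uronate (position %d)", i),
                     "hepseq_invalid_chain", position = i)
      if (!r$epimer[i] %in% c("GlcA", "IdoA", "dUA", "HexUA"))
        hepseq_error(sprintf("unknown uronate epimer at position %d", i),
                     "hepseq_invalid_chain", position = i)
      if (r$epimer[i] == "dUA" && i != 1L)
        hepseq_error(sprintf(
          "dUA (4,5-unsaturated) allowed only at the nonreducing end, found at position %d",
          i), "hepseq_invalid_chain", position = i)
    } else {
      if (r$s2[i])
        hepseq_error(sprintf("2S illegal on a hexosamine (position %d)", i),
                     "hepseq_invalid_chain", position = i)
      if (!r$nsub[i] %in% c("Ac", "S", "H"))
        hepseq_error(sprintf("unknown N-substituent at position %d", i),
                     "hepseq_invalid_chain", position = i)
    }
  }
  invisible(chain)
}

#' Degree of polymerisation
#'
#' @param chain a `glycan_chain`.
#' @return integer residue count (DP).
#' @export
chain_dp <- function(chain) nrow(chain$residues)

## contiguous subchain, re_mod kept only when the reducing end is kept
subchain <- function(chain, from, to) {
  keep_re <- to == chain_dp(chain)
  structure(list(residues = chain$residues[from:to, , drop = FALSE],
                 re_mod = if (keep_re) chain$re_mod else "none"),
            class = "glycan_chain")
}

has_delta <- function(chain) any(chain$residues$epimer == "dUA", na.rm = TRUE)

n_delta <- function(chain) sum(chain$residues$epimer == "dUA", na.rm = TRUE)

has_concrete_epimers <- function(chain) {
  !any(chain$residues$epimer == "HexUA", na.rm = TRUE)
}

parse_error <- function(msg, token, position) {
  stop(errorCondition(
    sprintf("%s (token '%s', residue position %d)", msg, token, position),
    class = c("hepseq_parse_error", "hepseq_error"),
    token = token, position = position))
}

#' Parse chain notation
#'
#' Reads one chain from its text notation.  The grammar is
#' `residue ("-" residue)* [re_mod]` where a uronate token is
#' `("GlcA"|"IdoA"|"dUA"|"HexUA")["2S"]`, a hexosamine token is
#' `"GlcN"("Ac"|"S"|"H")["3S"]["6S"]`, and the optional reducing-end
#' modification is `"(OMe)"` or `"(2AB)"`.  `dUA` is the ASCII spelling of
#' the 4,5-unsaturated uronate (dUA); `HexUA` is the epimer-erased saturated
#' uronate used in sequence calls.
#'
#' @param text a single chain string, e.g. `"dUA2S-GlcNS6S"`.
#' @return a [glycan_chain()].
#' @examples
#' ch <- parse_chain("dUA2S-GlcNS6S-GlcA-GlcNS6S")
#' chain_dp(ch)
#' @export
parse_chain <- function(text) {
  if (length(text) != 1L || !is.character(text))
    hepseq_error("parse_chain expects a single string", "hepseq_parse_error")
  s <- trimws(text)
  re_mod <- "none"
  m <- regmatches(s, regexec("\\((OMe|2AB)\\)$", s))[[1]]
  if (length(m)) {
    re_mod <- m[2]
    s <- sub("\\((OMe|2AB)\\)$", "", s)
  } else if (grepl("\\(", s)) {
    parse_error("unrecognised reducing-end modification",
                sub(".*\\(", "(", s), 0L)
  }
  tokens <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (!length(tokens))
    hepseq_error("empty chain string", "hepseq_parse_error")
  rows <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    mu <- regmatches(tok, regexec("^(GlcA|IdoA|dUA|HexUA)(2S)?$", tok))[[1]]
    if (length(mu)) {
      rows[[i]] <- residue_uronate(mu[2], s2 = nzchar(mu[3]))
      next
    }
    mh <- regmatches(tok, regexec("^GlcN(Ac|S|H)(3S)?(6S)?$", tok))[[1]]
    if (length(mh)) {
      rows[[i]] <- residue_hexosamine(mh[2], s3 = nzchar(mh[3]),
                                      s6 = nzchar(mh[4]))
      next
    }
    ## classify the failure for a pointed message
    if (grepl("^(GlcA|IdoA|dUA|HexUA)", tok))
      parse_error("illegal sulfation position on a uronate", tok, i)
    if (grepl("^GlcN", tok))
      parse_error("illegal token after GlcN (expect Ac|S|H then 3S/6S)", tok, i)
    parse_error("unknown residue token", tok, i)
  }
  res <- do.call(rbind, rows)
  ## re-raise alternation/misplacement with parse-error classes
  tryCatch(glycan_chain(res, re_mod = re_mod),
           hepseq_invalid_chain = function(e) {
             pos <- if (is.null(e$position)) 0L else e$position
             parse_error(conditionMessage(e), tokens[min(pos, length(tokens))], pos)
           })
}

format_residue <- function(row) {
  if (row$kind == "uronate") {
    paste0(row$epimer, if (row$s2) "2S")
  } else {
    paste0("GlcN", row$nsub, if (row$s3) "3S", if (row$s6) "6S")
  }
}

#' Write chain notation
#'
#' Inverse of [parse_chain()]: renders a chain as its canonical string.
#'
#' @param chain a `glycan_chain`.
#' @return a single string.
#' @export
format_chain <- function(chain) {
  toks <- vapply(seq_len(chain_dp(chain)), function(i)
    format_residue(chain$residues[i, , drop = FALSE]), character(1))
  paste0(paste(toks, collapse = "-"),
         if (chain$re_mod != "none") paste0("(", chain$re_mod, ")"))
}

#' @export
format.glycan_chain <- function(x, ...) format_chain(x)

#' @export
as.character.glycan_chain <- function(x, ...) format_chain(x)

#' @export
print.glycan_chain <- function(x, ...) {
  cat("<glycan_chain> DP", chain_dp(x), "\n  ", format_chain(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.glycan_chain` <- function(e1, e2) {
  inherits(e2, "glycan_chain") && identical(format_chain(e1), format_chain(e2))
}
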