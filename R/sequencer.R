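#' Assemble a ladder dataset
#'
#' The input of the ladder sequencer: disaccharide compositions of the
#' nested nonreducing-end fragments UDP4 ... UDP2n produced by partial
#' exolysis (each measured by exhaustive heparinase I+II digestion), plus
#' the composition of the O3-trimmed, re-digested UDP4, which isolates the
#' second unit from the nonreducing end.
#'
#' @param compositions list of named numeric composition vectors (molar
#'   amounts or fractions), with names (or integer positions interpretable)
#'   `"2"` ... `"n"`: element `k` is the composition of the UDP2k fragment.
#' @param o3_udp4 named numeric composition of the ozonolysed UDP4 digest
#'   (expected to contain a single unit).
#' @param provenance `"measured"` or `"simulated"`.
#' @param nre_unsaturated whether the parent chain starts with dUA (TRUE for
#'   lyase-generated oligosaccharides); controls rendering of position 1.
#' @return object of class `ladder_dataset` with fields `n_units`,
#'   `compositions`, `o3_udp4`, `provenance`.
#' @export
ladder_dataset <- function(compositions, o3_udp4,
                           provenance = c("simulated", "measured"),
                           nre_unsaturated = TRUE) {
  provenance <- match.arg(provenance)
  ks <- suppressWarnings(as.integer(names(compositions)))
  if (any(is.na(ks)))
    hepseq_error("compositions must be named by unit count k", "hepseq_bad_ladder")
  n <- max(ks)
  if (n < 2L || !setequal(ks, 2:n))
    hepseq_error("need compositions for every k in 2..n (n >= 2)",
                 "hepseq_bad_ladder")
  compositions <- compositions[order(ks)]
  names(compositions) <- sort(ks)
  for (v in c(compositions, list(o3_udp4))) {
    if (any(v < 0)) hepseq_error("negative molar amount", "hepseq_bad_ladder")
    bad <- setdiff(names(v), c(disaccharide_codes(), "other"))
    if (length(bad))
      hepseq_error(paste("unknown code(s):", paste(bad, collapse = ", ")),
                   "hepseq_bad_ladder")
  }
  structure(list(n_units = n, compositions = compositions,
                 o3_udp4 = o3_udp4, provenance = provenance,
                 nre_unsaturated = isTRUE(nre_unsaturated)),
            class = "ladder_dataset")
}

#' @export
print.ladder_dataset <- function(x, ...) {
  cat(sprintf("<ladder_dataset> n_units %d (%s)\n", x$n_units, x$provenance))
  for (k in names(x$compositions))
    cat(sprintf("  UDP%-2s : %s\n", as.integer(k) * 2L,
                paste(names(x$compositions[[k]]),
                      signif(x$compositions[[k]], 4),
                      sep = "=", collapse = ", ")))
  cat(sprintf("  O3-UDP4: %s\n",
              paste(names(x$o3_udp4), signif(x$o3_udp4, 4),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Integerise a measured composition
#'
#' Converts molar amounts (or fractions) of a fragment known to contain `k`
#' disaccharide units into integer unit counts.  The amounts are normalised
#' to fractions, scaled by `k` and rounded; the result is accepted only if
#' the rounded counts sum to `k` and no scaled amount deviates from its
#' count by more than `tol`.  Otherwise an ambiguity error is raised
#' carrying the two best candidate count vectors (ranked by maximum
#' absolute deviation).
#'
#' @param fractions named numeric vector of amounts (codes as names).
#' @param k expected number of units.
#' @param tol maximum tolerated deviation per code, in units (> 0).
#' @return named integer vector summing to `k`, with attribute
#'   `"residual"` (the max absolute deviation).
#' @examples
#' integerize(c(NS6S = 0.25, `2SNS6S` = 0.75), 4)
#' @export
integerize <- function(fractions, k, tol = 0.2) {
  if (tol <= 0) hepseq_error("tol must be > 0", "hepseq_bad_tol")
  if (any(fractions < 0))
    hepseq_error("negative amounts", "hepseq_bad_ladder")
  if (sum(fractions) <= 0)
    hepseq_error("all-zero composition", "hepseq_bad_ladder")
  target <- fractions / sum(fractions) * k
  counts <- round(target)
  resid <- max(abs(target - counts))
  if (sum(counts) == k && resid <= tol) {
    return(structure(setNames(as.integer(counts), names(fractions)),
                     residual = resid))
  }
  ## enumerate candidate integer vectors near the target
  ranges <- lapply(target, function(t)
    seq(max(0L, floor(t) - 1L), ceiling(t) + 1L))
  grid <- as.matrix(expand.grid(ranges))
  grid <- grid[rowSums(grid) == k, , drop = FALSE]
  devs <- apply(grid, 1L, function(row) max(abs(row - target)))
  ord <- order(devs)
  top <- head(ord, 2L)
  cand <- lapply(top, function(i)
    setNames(as.integer(grid[i, ]), names(fractions)))
  stop(errorCondition(
    sprintf("composition does not integerise to %d units within tol %.3g (best deviation %.3g)",
            k, tol, devs[top[1]]),
    class = c("hepseq_ambiguous", "hepseq_error"),
    candidates = cand, deviations = devs[top], k = k))
}

## align two count vectors on the union of their codes
align_counts <- function(a, b) {
  codes <- union(names(a), names(b))
  av <- setNames(numeric(length(codes)), codes)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  list(a = av, b = bv, codes = codes)
}

inconsistent_ladder <- function(k, msg) {
  stop(errorCondition(
    sprintf("%s (at k = %d)", msg, k),
    class = c("hepseq_inconsistent_ladder", "hepseq_error"), k = k))
}

#' Deduce a disaccharide sequence from a ladder
#'
#' The compositional-differencing inference: for each rung, the unit lost
#' between UDP2k and UDP2(k-1) is the disaccharide at position k (counted
#' from the nonreducing end); the O3-trimmed UDP4 digest pins position 2;
#' and position 1 is what remains of the UDP4 composition.  Internal and
#' reducing-end uronates are reported epimer-erased (`HexUA`), because lyase
#' cleavage destroys the GlcA/IdoA distinction, while position 1 keeps its
#' dUA prefix for unsaturated parents.
#'
#' @param ladder a [ladder_dataset()].
#' @param tol integerisation tolerance per code (units).
#' @return object of class `sequence_call`: fields `units` (data.frame with
#'   `position`, `code`, `status`, `candidates`), `sequence` (chain-notation
#'   string when fully determined, else `NA`), `residual`, `n_units`.
#' @examples
#' lad <- simulate_ladder_experiment(hp_fixtures()$P8_4)
#' deduce_sequence(lad)
#' @export
deduce_sequence <- function(ladder, tol = 0.2) {
  n <- ladder$n_units
  resid <- 0
  ints <- vector("list", n)
  ambig <- vector("list", n)
  for (k in 2:n) {
    res <- tryCatch(integerize(ladder$compositions[[as.character(k)]], k, tol),
                    hepseq_ambiguous = function(e) e)
    if (inherits(res, "hepseq_ambiguous")) {
      ambig[[k]] <- res
    } else {
      ints[[k]] <- res
      resid <- max(resid, attr(res, "residual"))
    }
  }
  units <- data.frame(position = seq_len(n), code = NA_character_,
                      status = "undetermined", stringsAsFactors = FALSE)
  units$candidates <- vector("list", n)

  diff_unit <- function(k) {
    ## unit lost between rung k and rung k-1 (integer compositions)
    al <- align_counts(ints[[k]], ints[[k - 1L]])
    d <- al$a - al$b
    if (any(d < 0))
      inconsistent_ladder(k, sprintf(
        "code '%s' gains molar amount in the smaller fragment",
        al$codes[which(d < 0)[1]]))
    if (sum(d) != 1L) return(NULL)
    al$codes[d == 1L]
  }

  ## positions n .. 3 from successive differences
  for (k in (if (n >= 3) n:3 else integer(0))) {
    if (!is.null(ints[[k]]) && !is.null(ints[[k - 1L]])) {
      code <- diff_unit(k)
      if (!is.null(code)) {
        if (code == "other") {
          units$status[k] <- "undetermined"
        } else {
          units$code[k] <- code
          units$status[k] <- "determined"
        }
      }
    } else {
      ## an ambiguous rung: offer the codes whose real-valued difference is
      ## closest to one unit as candidates
      fk <- ladder$compositions[[as.character(k)]]
      fk1 <- ladder$compositions[[as.character(k - 1L)]]
      al <- align_counts(fk / sum(fk) * k, fk1 / sum(fk1) * (k - 1L))
      d <- al$a - al$b
      cand <- al$codes[d > 1 - 2 * tol - 0.25 & al$codes != "other"]
      if (length(cand)) {
        units$status[k] <- "ambiguous"
        units$candidates[[k]] <- cand
      }
    }
  }

  ## position 2 from the O3-trimmed tetrasaccharide
  pos2 <- tryCatch(integerize(ladder$o3_udp4, 1L, tol),
                   hepseq_ambiguous = function(e) e)
  if (!inherits(pos2, "hepseq_ambiguous")) {
    resid <- max(resid, attr(pos2, "residual"))
    code2 <- names(pos2)[pos2 == 1L]
    if (length(code2) == 1L && code2 != "other") {
      units$code[2L] <- code2
      units$status[2L] <- "determined"
    }
  }

  ## position 1 = UDP4 composition minus the position-2 unit
  if (!is.null(ints[[2L]]) && units$status[2L] == "determined") {
    u2 <- setNames(1L, units$code[2L])
    al <- align_counts(ints[[2L]], u2)
    d <- al$a - al$b
    if (any(d < 0))
      inconsistent_ladder(2L, sprintf(
        "O3-determined unit '%s' absent from the UDP4 composition",
        units$code[2L]))
    if (sum(d) == 1L) {
      code1 <- al$codes[d == 1L]
      if (code1 != "other") {
        units$code[1L] <- code1
        units$status[1L] <- "determined"
      }
    }
  }

  seq_str <- if (all(units$status == "determined")) {
    paste(vapply(seq_len(n), function(i)
      code_to_unit_string(units$code[i],
                          nre = i == 1L && ladder$nre_unsaturated),
      character(1)), collapse = "-")
  } else NA_character_
  structure(list(units = units, sequence = seq_str, residual = resid,
                 n_units = n, nre_unsaturated = ladder$nre_unsaturated),
            class = "sequence_call")
}

#' @export
print.sequence_call <- function(x, ...) {
  cat(sprintf("<sequence_call> %d units, residual %.3g\n", x$n_units,
              x$residual))
  if (!is.na(x$sequence)) cat("  ", x$sequence, "\n", sep = "")
  for (i in seq_len(x$n_units)) {
    extra <- if (x$units$status[i] == "ambiguous")
      paste0(" {", paste(x$units$candidates[[i]], collapse = ", "), "}") else ""
    cat(sprintf("  %d (%s): %s [%s]%s\n", i,
                if (i == 1) "NRE" else if (i == x$n_units) "RE" else "int",
                ifelse(is.na(x$units$code[i]), "?", x$units$code[i]),
                x$units$status[i], extra))
  }
  invisible(x)
}

#' @export
summary.sequence_call <- function(object, ...) object$units

#' Cross-validate a sequence call against its ladder
#'
#' Recomputes every rung composition implied by the call and reports, per
#' fragment, the maximum absolute deviation (in units) of the measured,
#' normalised composition from the prediction.  Fragments deviating by more
#' than `threshold` are flagged — the signature of a labelling-efficiency or
#' purity anomaly in the measurement.
#'
#' @param call a `sequence_call` (fully or partially determined).
#' @param ladder the [ladder_dataset()] it was derived from.
#' @param threshold flagging threshold in units.
#' @return data.frame with columns `fragment`, `residual`, `flagged`
#'   (fragments with undetermined positions get `NA` residuals).
#' @export
validate_call <- function(call, ladder, threshold = 0.2) {
  n <- call$n_units
  rows <- list()
  for (k in 2:n) {
    if (any(call$units$status[1:k] != "determined")) {
      rows[[length(rows) + 1L]] <- data.frame(
        fragment = paste0("UDP", 2L * k), residual = NA_real_,
        flagged = NA, stringsAsFactors = FALSE)
      next
    }
    pred <- table(call$units$code[1:k])
    pred <- setNames(as.numeric(pred), names(pred))
    meas <- ladder$compositions[[as.character(k)]]
    meas <- meas / sum(meas) * k
    al <- align_counts(pred, meas)
    res <- max(abs(al$a - al$b))
    rows[[length(rows) + 1L]] <- data.frame(
      fragment = paste0("UDP", 2L * k), residual = res,
      flagged = res > threshold, stringsAsFactors = FALSE)
  }
  if (call$units$status[2L] == "determined") {
    meas <- ladder$o3_udp4 / sum(ladder$o3_udp4)
    al <- align_counts(setNames(1, call$units$code[2L]), meas)
    res <- max(abs(al$a - al$b))
    rows[[length(rows) + 1L]] <- data.frame(
      fragment = "o3_udp4", residual = res, flagged = res > threshold,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Compare a sequence call with a known chain
#'
#' Benchmark comparison of a call against ground truth, after applying to
#' the truth the information loss inherent to the enzymatic method: internal
#' and reducing-end uronate epimers are erased and any unit outside the
#' eight-code table is masked to `"other"`.
#'
#' @param truth a `glycan_chain` (even DP, unsaturated nonreducing end).
#' @param call a `sequence_call`.
#' @return list with `exact` (TRUE when every position is determined and
#'   matches), `matches` (per-position logical), `length_mismatch`.
#' @export
sequence_accuracy <- function(truth, call) {
  tu <- disaccharide_units(truth)
  nt <- nrow(tu)
  nc <- call$n_units
  length_mismatch <- nt != nc
  npos <- min(nt, nc)
  matches <- vapply(seq_len(npos), function(i)
    call$units$status[i] == "determined" &&
      identical(call$units$code[i], tu$code[i]), logical(1))
  list(exact = !length_mismatch && all(matches),
       matches = matches, length_mismatch = length_mismatch)
}
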