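## ---- chain and table I/O -------------------------------------------------

#' Read a chain-notation file
#'
#' One chain per line; blank lines and `#` comments ignored.  A line may
#' carry a trailing `# name` comment, used as the element name.
#'
#' @param path file path.
#' @return named list of `glycan_chain`s.
#' @export
read_chain_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    nm <- trimws(sub("^[^#]*", "", raw))
    nm <- trimws(sub("^#+", "", nm))
    txt <- trimws(sub("#.*$", "", raw))
    if (!nzchar(txt)) next
    ch <- tryCatch(parse_chain(txt), hepseq_parse_error = function(e)
      hepseq_error(sprintf("line %d: %s", ln, conditionMessage(e)),
                   "hepseq_parse_error", line = ln))
    out[[length(out) + 1L]] <- ch
    names(out)[length(out)] <- if (nzchar(nm)) nm else paste0("chain", ln)
  }
  out
}

#' Write chains in chain notation
#'
#' @param chains list of `glycan_chain`s (names become trailing comments).
#' @param path file path.
#' @export
write_chain_file <- function(chains, path) {
  if (inherits(chains, "glycan_chain")) chains <- list(chains)
  nms <- names(chains)
  lines <- vapply(seq_along(chains), function(i) {
    paste0(format_chain(chains[[i]]),
           if (!is.null(nms) && nzchar(nms[i])) paste0("  # ", nms[i]) else "")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write composition tables as CSV
#'
#' Writes one or more composition vectors with header
#' `fragment_dp,code,molar_amount`; ladder datasets include their
#' O3-trimmed tetrasaccharide as rows with `fragment_dp = "o3_udp4"`.
#'
#' @param x a named numeric composition vector, a list of them keyed by
#'   fragment DP, or a [ladder_dataset()].
#' @param path file path.
#' @param fragment_dp DP label used when `x` is a single vector.
#' @export
write_composition_csv <- function(x, path, fragment_dp = 2) {
  rows <- list()
  add <- function(dp, v) {
    if (length(v))
      rows[[length(rows) + 1L]] <<- data.frame(
        fragment_dp = dp, code = names(v), molar_amount = as.numeric(v),
        stringsAsFactors = FALSE)
  }
  if (inherits(x, "ladder_dataset")) {
    for (k in names(x$compositions))
      add(as.integer(k) * 2L, x$compositions[[k]])
    add("o3_udp4", x$o3_udp4)
  } else if (is.list(x)) {
    for (k in names(x)) add(k, x[[k]])
  } else {
    add(fragment_dp, x)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ladder CSV
#'
#' Inverse of [write_composition_csv()] for ladder datasets: expects rows
#' with numeric `fragment_dp` (4, 6, ..., 2n) and `"o3_udp4"` rows for the
#' trimmed tetrasaccharide.
#'
#' @param path file path.
#' @param provenance recorded provenance of the measurements.
#' @return a [ladder_dataset()].
#' @export
read_ladder_csv <- function(path, provenance = "measured") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fragment_dp", "code", "molar_amount")
  if (!all(need %in% names(df)))
    hepseq_error("ladder CSV needs columns fragment_dp, code, molar_amount",
                 "hepseq_bad_ladder")
  is_o3 <- df$fragment_dp == "o3_udp4"
  o3 <- setNames(df$molar_amount[is_o3], df$code[is_o3])
  rest <- df[!is_o3, , drop = FALSE]
  dps <- suppressWarnings(as.integer(rest$fragment_dp))
  if (any(is.na(dps)) || any(dps %% 2L != 0L))
    hepseq_error("fragment_dp must be even integers or 'o3_udp4'",
                 "hepseq_bad_ladder")
  comps <- lapply(split(seq_len(nrow(rest)), dps / 2L), function(i)
    setNames(rest$molar_amount[i], rest$code[i]))
  ladder_dataset(comps, o3, provenance = provenance)
}

#' Write a JSON report
#'
#' @param x list to serialise.
#' @param path file path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- sequence-property utilities ----------------------------------------

AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

## Bjellqvist pKa values (the ExPASy convention)
PKA <- list(
  neg = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  pos = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
  nterm_by_aa = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                  V = 7.44, E = 7.70, G = 7.50))

protein_net_charge <- function(counts, first_aa, pH) {
  pos_pka <- PKA$pos
  if (first_aa %in% names(PKA$nterm_by_aa))
    pos_pka[["Nterm"]] <- PKA$nterm_by_aa[[first_aa]]
  pos_n <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
             H = unname(counts["H"]))
  neg_n <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
             C = unname(counts["C"]), Y = unname(counts["Y"]))
  pos <- sum(pos_n / (1 + 10^(pH - pos_pka[names(pos_n)])))
  neg <- sum(neg_n / (1 + 10^(PKA$neg[names(neg_n)] - pH)))
  pos - neg
}

#' Protein length, mass and isoelectric point
#'
#' Average molecular mass as the sum of average residue masses plus one
#' water, and isoelectric point by bisection on the Henderson-Hasselbalch
#' net-charge function with the Bjellqvist pKa set (the ExPASy convention,
#' including residue-specific N-terminal pKa values).
#'
#' @param seq amino-acid sequence (single string, standard 20 letters,
#'   case-insensitive).
#' @return list with `length`, `average_mass` (Da) and `pI`.
#' @examples
#' protein_properties("MKLVINLALA")
#' @export
protein_properties <- function(seq) {
  aa <- strsplit(toupper(trimws(seq)), "")[[1]]
  bad <- setdiff(unique(aa), names(AA_AVG_MASS))
  if (length(bad))
    hepseq_error(paste("non-standard letters:", paste(bad, collapse = ", ")),
                 "hepseq_bad_sequence")
  counts <- table(factor(aa, levels = names(AA_AVG_MASS)))
  counts <- setNames(as.numeric(counts), names(AA_AVG_MASS))
  mass <- sum(counts * AA_AVG_MASS) + 18.01524
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, aa[1L], mid) > 0) lo <- mid else hi <- mid
  }
  list(length = length(aa), average_mass = mass, pI = (lo + hi) / 2)
}

#' GC content of a nucleotide sequence
#'
#' @param seq nucleotide string (A/C/G/T, case-insensitive).
#' @param ambiguous `"error"` (default) to reject non-ACGT letters, or
#'   `"skip"` to drop them from both numerator and denominator.
#' @return GC percentage.
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(seq, ambiguous = c("error", "skip")) {
  ambiguous <- match.arg(ambiguous)
  nt <- strsplit(toupper(trimws(seq)), "")[[1]]
  ok <- nt %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    if (ambiguous == "error")
      hepseq_error(paste("ambiguity codes present:",
                         paste(unique(nt[!ok]), collapse = ", ")),
                   "hepseq_bad_sequence")
    nt <- nt[ok]
  }
  100 * sum(nt %in% c("G", "C")) / length(nt)
}

#' Read sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readBStringSet`.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    hepseq_error("Biostrings is required to read FASTA files",
                 "hepseq_missing_dep")
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read a GenBank/GenPept flat file
#'
#' Minimal reader for locally supplied records: extracts the accession
#' (VERSION line), definition and ORIGIN sequence.
#'
#' @param path flat-file path.
#' @return list with `accession`, `definition`, `sequence`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  version <- grep("^VERSION", lines, value = TRUE)
  accession <- if (length(version))
    trimws(sub("^VERSION\\s+", "", version[1])) else NA_character_
  defn <- grep("^DEFINITION", lines, value = TRUE)
  definition <- if (length(defn))
    trimws(sub("^DEFINITION\\s+", "", defn[1])) else NA_character_
  o <- grep("^ORIGIN", lines)
  if (!length(o))
    hepseq_error("no ORIGIN section found", "hepseq_bad_genbank")
  end <- grep("^//", lines)
  end <- if (length(end)) min(end[end > o[1]]) else length(lines) + 1L
  seq_lines <- lines[(o[1] + 1L):(end - 1L)]
  seq <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
  list(accession = accession, definition = definition, sequence = seq)
}

## ---- pipeline front-end --------------------------------------------------

check_config <- function(config, allowed) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    hepseq_error(paste("unknown config key(s):",
                       paste(unknown, collapse = ", ")),
                 "hepseq_bad_config")
  config
}

#' Run a pipeline command
#'
#' Programmatic surface behind the `hepseq` command-line script: each
#' command reads the files named in `config`, runs the corresponding
#' package functions and writes machine-readable outputs.  All randomness
#' flows through `config$seed`, making runs reproducible.
#'
#' @param command one of `"parse"`, `"digest"`, `"ozone"`, `"mass"`,
#'   `"fragments"`, `"simulate"`, `"sequence"`, `"synth"`, `"protprops"`.
#' @param config named list of options; unknown keys are rejected.  Common
#'   keys: `input`, `output`, `seed`, `tol`, `enzyme`, `steps`, `sigma`.
#' @return invisibly, a list of the computed objects per input.
#' @export
run_pipeline <- function(command = c("parse", "digest", "ozone", "mass",
                                     "fragments", "simulate", "sequence",
                                     "synth", "protprops"),
                         config = list()) {
  command <- match.arg(command)
  enz <- function() {
    name <- if (is.null(config$enzyme)) "exoHep" else config$enzyme
    specs <- heparinases()
    if (!name %in% names(specs))
      hepseq_error(paste("unknown enzyme:", name), "hepseq_bad_config")
    specs[[name]]
  }
  out <- switch(
    command,
    parse = {
      check_config(config, c("input", "output"))
      chains <- read_chain_file(config$input)
      if (!is.null(config$output)) write_chain_file(chains, config$output)
      chains
    },
    digest = {
      check_config(config, c("input", "output", "output_composition",
                             "enzyme", "steps"))
      chains <- read_chain_file(config$input)
      e <- enz()
      res <- lapply(chains, function(ch) {
        if (e$mode == "exo") {
          d <- digest_exo(ch, e, steps = if (is.null(config$steps))
            "to_completion" else config$steps)
          c(d$released, list(d$remainder))
        } else digest_endo_exhaustive(ch, e)
      })
      frags <- unlist(res, recursive = FALSE)
      if (!is.null(config$output)) write_chain_file(frags, config$output)
      if (!is.null(config$output_composition))
        write_composition_csv(composition_of(frags),
                              config$output_composition)
      res
    },
    ozone = {
      check_config(config, c("input", "output"))
      chains <- lapply(read_chain_file(config$input), ozone_treat)
      if (!is.null(config$output)) write_chain_file(chains, config$output)
      chains
    },
    mass = {
      check_config(config, c("input", "output", "sulfation_level"))
      chains <- read_chain_file(config$input)
      rep <- lapply(chains, function(ch) {
        f <- formula_of(ch, sulfation_level = isTRUE(config$sulfation_level))
        list(chain = format_chain(ch), formula = format(f),
             monoisotopic = f$monoisotopic, average = f$average,
             mz1 = mz(f$monoisotopic, 1), mz2 = mz(f$monoisotopic, 2))
      })
      if (!is.null(config$output)) write_report_json(rep, config$output)
      rep
    },
    fragments = {
      check_config(config, c("input", "output", "sulfation_level"))
      chains <- read_chain_file(config$input)
      tabs <- lapply(chains, fragment_ladder,
                     sulfation_level = isTRUE(config$sulfation_level))
      all <- do.call(rbind, Map(function(nm, tb)
        cbind(chain = nm, tb), names(tabs), tabs))
      if (!is.null(config$output))
        write.csv(all, config$output, row.names = FALSE)
      tabs
    },
    simulate = {
      check_config(config, c("input", "enzyme", "seed", "t_max", "t_step",
                             "mode", "output", "summary"))
      chains <- read_chain_file(config$input)
      t_grid <- seq(0, if (is.null(config$t_max)) 10 else config$t_max,
                    by = if (is.null(config$t_step)) 0.5 else config$t_step)
      tc <- simulate_timecourse(
        unname(chains), enzyme = enz(), t_grid = t_grid,
        mode = if (is.null(config$mode)) "stochastic" else config$mode,
        seed = if (is.null(config$seed)) 1L else config$seed)
      if (!is.null(config$output)) {
        long <- do.call(rbind, lapply(seq_len(nrow(tc$species)), function(s)
          data.frame(time = tc$time, species = tc$species$species[s],
                     amount = tc$amounts[, s], dp = tc$species$dp[s],
                     a232_visible = tc$species$n_delta[s] > 0)))
        write.csv(long, config$output, row.names = FALSE)
      }
      if (!is.null(config$summary)) {
        fin <- nrow(tc$amounts)
        done <- sum(tc$amounts[fin, tc$species$dp <= 2])
        write_report_json(list(
          exolytic_index = exolytic_index(tc),
          completion_fraction = done / sum(tc$amounts[fin, ]),
          mode = tc$mode), config$summary)
      }
      tc
    },
    sequence = {
      check_config(config, c("input", "tol", "output"))
      lad <- read_ladder_csv(config$input)
      call <- deduce_sequence(lad, tol = if (is.null(config$tol)) 0.2
                              else config$tol)
      print(call)
      report <- list(sequence = call$sequence, n_units = call$n_units,
                     residual = call$residual,
                     units = call$units[c("position", "code", "status")],
                     validation = validate_call(call, lad))
      if (!is.null(config$output)) write_report_json(report, config$output)
      call
    },
    synth = {
      check_config(config, c("n", "n_units", "seed", "sigma", "output",
                             "ladder_prefix"))
      n <- if (is.null(config$n)) 1L else config$n
      seed <- if (is.null(config$seed)) 1L else config$seed
      nu <- if (is.null(config$n_units)) 4L else config$n_units
      chains <- lapply(seq_len(n), function(i)
        generate_chain(n_units = nu, seed = seed + i))
      names(chains) <- sprintf("synthetic%d", seq_len(n))
      if (!is.null(config$output)) write_chain_file(chains, config$output)
      if (!is.null(config$ladder_prefix)) {
        for (i in seq_len(n)) {
          lad <- simulate_ladder_experiment(
            chains[[i]],
            noise_model(if (is.null(config$sigma)) 0 else config$sigma),
            seed = seed + i)
          write_composition_csv(lad, sprintf("%s%d.csv",
                                             config$ladder_prefix, i))
        }
      }
      chains
    },
    protprops = {
      check_config(config, c("input", "output"))
      seqs <- read_fasta(config$input)
      rep <- lapply(seqs, protein_properties)
      if (!is.null(config$output)) write_report_json(rep, config$output)
      rep
    })
  invisible(out)
}
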