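#' Context-dependent relative rate table
#'
#' Digestion kinetics are first-order per cleavable site (enzyme in excess).
#' Each site's relative rate is looked up by its local context: the epimer
#' and 2-O-sulfation of the cleaved uronate (`GlcA`, `IdoA`, `GlcA2S`,
#' `IdoA2S`), the N-substituent and 6-O-sulfation of the glucosamine of the
#' cleaved linkage (`NAc`, `NAc6S`, `NS`, `NS6S`), and optionally the
#' 2-O-sulfation state of the substrate's nonreducing-end uronate (`NRE2S` /
#' `NRE0S`).  Keys are `"uronate:hexosamine"` or
#' `"uronate:hexosamine:NREmod"`; lookup tries the specific key first and
#' falls back to the two-part key and then to `default`.
#'
#' @param entries named numeric vector of relative rates (>= 0).
#' @param base_rate events/min scaling applied to every relative rate.  The
#'   default normalises the table so the tetrasaccharide context
#'   `GlcA:NS6S:NRE2S` has a half-life of one time unit.
#' @param default relative rate for contexts missing from `entries`.
#' @return object of class `rate_table`.
#' @export
rate_table <- function(entries, base_rate = log(2) / 49.12, default = 10) {
  if (any(entries < 0) || any(!is.finite(entries)))
    hepseq_error("relative rates must be finite and >= 0", "hepseq_bad_rates")
  structure(list(entries = entries, base_rate = base_rate, default = default),
            class = "rate_table")
}

#' Default rate table
#'
#' Relative rates proportional to the specific activities measured on the
#' five structure-defined tetrasaccharide substrates (`<1` encoded as 0.5),
#' with the qualitative epimer preference (unsulfated GlcA more susceptible
#' than unsulfated IdoA) encoded as a modest penalty on the IdoA contexts.
#'
#' @return a [rate_table()].
#' @export
default_rate_table <- function() {
  rate_table(c(
    "GlcA:NAc6S" = 0.5,  "IdoA:NAc6S" = 0.5,
    "GlcA:NAc"   = 0.5,  "IdoA:NAc"   = 0.5,
    "GlcA:NS"    = 3.98, "IdoA:NS"    = 3.98,
    "GlcA:NS6S"  = 24.22, "IdoA:NS6S" = 20.0,
    "GlcA:NS6S:NRE2S" = 49.12, "IdoA:NS6S:NRE2S" = 40.0,
    "GlcA2S:NS6S" = 79.49, "IdoA2S:NS6S" = 79.49
  ))
}

## context key pieces for linkage j of `chain`
site_context <- function(chain, j) {
  r <- chain$residues
  uro <- paste0(r$epimer[j + 1L], if (r$s2[j + 1L]) "2S")
  hex <- paste0("N", r$nsub[j], if (r$s6[j]) "6S")
  nre <- if (r$kind[1L] == "uronate" && r$s2[1L]) "NRE2S" else "NRE0S"
  c(uro = uro, hex = hex, nre = nre)
}

## relative rate (before base_rate) of linkage j
site_relative_rate <- function(chain, j, rates) {
  ctx <- site_context(chain, j)
  keys <- c(paste(ctx[["uro"]], ctx[["hex"]], ctx[["nre"]], sep = ":"),
            paste(ctx[["uro"]], ctx[["hex"]], sep = ":"))
  for (k in keys)
    if (k %in% names(rates$entries)) return(rates$entries[[k]])
  rates$default
}

## absolute hazards (events/min) of all cleavable sites of a chain
chain_site_hazards <- function(chain, enzyme, rates) {
  sites <- cleavable_linkages(chain, enzyme)
  haz <- vapply(sites, function(j)
    site_relative_rate(chain, j, rates) * rates$base_rate, numeric(1))
  list(sites = sites, hazards = haz)
}

#' Relative hazards of tetrasaccharide substrates
#'
#' Looks up, for each substrate, the hazard of its exolytic site under a
#' rate table; epimer mixtures (given as lists of chains) are averaged.
#' Under the default table the five reference tetrasaccharides come out in
#' the measured activity order P4-8 > P4-7 > P4-6 > P4-5 > P4-4.
#'
#' @param rates a [rate_table()].
#' @param tetrasaccharides named list whose elements are `glycan_chain`s or
#'   lists of chains (epimer mixtures).
#' @param enzyme enzyme spec, default the exolytic heparinase.
#' @return named numeric vector of hazards, in input order.
#' @export
relative_rate_check <- function(rates, tetrasaccharides,
                                enzyme = heparinases()$exoHep) {
  vapply(tetrasaccharides, function(el) {
    chains <- if (inherits(el, "glycan_chain")) list(el) else el
    mean(vapply(chains, function(ch) {
      h <- chain_site_hazards(ch, enzyme, rates)
      if (!length(h$hazards)) 0 else sum(h$hazards)
    }, numeric(1)))
  }, numeric(1))
}

## ---- species graph -------------------------------------------------------

## Enumerate all species reachable from `chains` under `enzyme`, with per
## species: chain, total hazard, and per-site (rate, product indices).
build_species_graph <- function(chains, enzyme, rates) {
  key <- function(ch) format_chain(ch)
  species <- list()
  index <- new.env(parent = emptyenv())
  add <- function(ch) {
    k <- key(ch)
    if (!is.null(index[[k]])) return(index[[k]])
    species[[length(species) + 1L]] <<- list(chain = ch, key = k)
    index[[k]] <- length(species)
    length(species)
  }
  for (ch in chains) add(ch)
  i <- 1L
  while (i <= length(species)) {
    ch <- species[[i]]$chain
    h <- chain_site_hazards(ch, enzyme, rates)
    prods <- lapply(h$sites, function(j) {
      p <- cleave(ch, j)
      c(add(p$nre), add(p$re))
    })
    species[[i]]$rates <- h$hazards
    species[[i]]$products <- prods
    species[[i]]$total <- sum(h$hazards)
    i <- i + 1L
  }
  species
}

species_meta <- function(species) {
  data.frame(
    species = vapply(species, `[[`, character(1), "key"),
    dp = vapply(species, function(s) chain_dp(s$chain), integer(1)),
    n_delta = vapply(species, function(s) n_delta(s$chain), integer(1)),
    stringsAsFactors = FALSE)
}

#' Simulate a digestion time course
#'
#' Evolves a pool of chains under one enzyme with context-dependent
#' first-order site kinetics, either by exact event-driven (Gillespie)
#' simulation with exponential waiting times, or by integrating the linear
#' rate equations over the reachable species graph.  Residue counts are
#' conserved exactly (stochastic) or to integrator tolerance
#' (deterministic).
#'
#' @param pool list of `glycan_chain`s (distinct species of the pool).
#' @param counts molecule counts per pool element (default 1 each).
#' @param enzyme an [enzyme_spec()].
#' @param rates a [rate_table()].
#' @param t_grid nonnegative, increasing sampling times (min).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param seed RNG seed, required in stochastic mode.
#' @return object of class `digestion_timecourse`: list with `time`,
#'   `amounts` (time x species matrix), `species` (metadata data.frame with
#'   `dp`, `n_delta`), and `mode`.
#' @examples
#' tc <- simulate_timecourse(list(hp_fixtures()$DP13), counts = 50,
#'                           t_grid = seq(0, 5, by = 0.5), seed = 1)
#' exolytic_index(tc)
#' @export
simulate_timecourse <- function(pool, counts = NULL,
                                enzyme = heparinases()$exoHep,
                                rates = default_rate_table(),
                                t_grid = seq(0, 10, by = 0.5),
                                mode = c("stochastic", "deterministic"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (any(t_grid < 0)) hepseq_error("negative times", "hepseq_bad_grid")
  if (is.unsorted(t_grid, strictly = TRUE))
    hepseq_error("t_grid must be strictly increasing", "hepseq_bad_grid")
  if (!length(pool)) {
    return(structure(list(time = t_grid,
                          amounts = matrix(0, length(t_grid), 0),
                          species = species_meta(list()), mode = mode),
                     class = "digestion_timecourse"))
  }
  if (is.null(counts)) counts <- rep(1, length(pool))
  counts <- rep_len(counts, length(pool))
  graph <- build_species_graph(pool, enzyme, rates)
  n_sp <- length(graph)
  x0 <- numeric(n_sp)
  for (i in seq_along(pool)) {
    k <- format_chain(pool[[i]])
    idx <- match(k, vapply(graph, `[[`, character(1), "key"))
    x0[idx] <- x0[idx] + counts[i]
  }
  amounts <- if (mode == "stochastic") {
    if (is.null(seed))
      hepseq_error("stochastic mode requires a seed", "hepseq_need_seed")
    set.seed(as.integer(seed))
    gillespie(graph, x0, t_grid)
  } else {
    integrate_species_ode(graph, x0, t_grid)
  }
  colnames(amounts) <- vapply(graph, `[[`, character(1), "key")
  structure(list(time = t_grid, amounts = amounts,
                 species = species_meta(graph), mode = mode),
            class = "digestion_timecourse")
}

gillespie <- function(graph, x0, t_grid) {
  n_sp <- length(graph)
  totals <- vapply(graph, `[[`, numeric(1), "total")
  x <- x0
  t_now <- 0
  out <- matrix(NA_real_, length(t_grid), n_sp)
  gi <- 1L
  repeat {
    total_rate <- sum(x * totals)
    t_next <- if (total_rate > 0) t_now + rexp(1L, total_rate) else Inf
    while (gi <= length(t_grid) && t_grid[gi] < t_next) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
    if (gi > length(t_grid) || !is.finite(t_next)) break
    t_now <- t_next
    ## pick the reacting species, then the site within it
    w <- x * totals
    s <- sample.int(n_sp, 1L, prob = w)
    sp <- graph[[s]]
    site <- if (length(sp$rates) == 1L) 1L else
      sample.int(length(sp$rates), 1L, prob = sp$rates)
    x[s] <- x[s] - 1
    pr <- sp$products[[site]]
    x[pr[1L]] <- x[pr[1L]] + 1
    x[pr[2L]] <- x[pr[2L]] + 1
  }
  out
}

integrate_species_ode <- function(graph, x0, t_grid) {
  n_sp <- length(graph)
  totals <- vapply(graph, `[[`, numeric(1), "total")
  ## inflow lists: for each species, (source index, rate) pairs
  inflow <- vector("list", n_sp)
  for (s in seq_len(n_sp)) {
    sp <- graph[[s]]
    for (k in seq_along(sp$rates)) {
      for (p in sp$products[[k]]) {
        inflow[[p]] <- rbind(inflow[[p]], c(s, sp$rates[k]))
      }
    }
  }
  deriv <- function(t, x, parms) {
    dx <- -totals * x
    for (s in seq_len(n_sp)) {
      fl <- inflow[[s]]
      if (!is.null(fl)) dx[s] <- dx[s] + sum(fl[, 2] * x[fl[, 1]])
    }
    list(dx)
  }
  times <- t_grid
  prepend <- FALSE
  if (times[1] > 0) { times <- c(0, times); prepend <- TRUE }
  sol <- deSolve::lsoda(y = x0, times = times, func = deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-10)
  m <- unname(as.matrix(sol[, -1, drop = FALSE]))
  if (prepend) m <- m[-1, , drop = FALSE]
  m
}

#' @export
print.digestion_timecourse <- function(x, ...) {
  cat(sprintf("<digestion_timecourse> %s, %d time points, %d species\n",
              x$mode, length(x$time), nrow(x$species)))
  invisible(x)
}

#' @export
summary.digestion_timecourse <- function(object, ...) {
  res <- total_residues(object)
  du <- delta_ua_formed(object)
  data.frame(time = object$time, total_residues = res,
             delta_ua = du, a232 = a232_signal(object))
}

#' Total residue count over time
#'
#' @param tc a `digestion_timecourse`.
#' @return numeric vector along `tc$time`; constant for a mass-conserving
#'   simulation.
#' @export
total_residues <- function(tc) {
  if (!nrow(tc$species)) return(rep(0, length(tc$time)))
  drop(tc$amounts %*% tc$species$dp)
}

#' Cumulative unsaturated uronate formed
#'
#' Total dUA residues present minus those present at the first sampled
#' time — the quantity the 232-nm assay tracks.
#'
#' @param tc a `digestion_timecourse`.
#' @return numeric vector along `tc$time`.
#' @export
delta_ua_formed <- function(tc) {
  if (!nrow(tc$species)) return(rep(0, length(tc$time)))
  tot <- drop(tc$amounts %*% tc$species$n_delta)
  tot - tot[1]
}

#' Simulated A232 signal
#'
#' Beer-Lambert absorbance of the dUA chromophores:
#' `epsilon * [dUA] * path`, with the pool amounts interpreted as molar
#' concentration in M (scaling is the caller's choice of units).
#'
#' @param tc a `digestion_timecourse`.
#' @param epsilon_232 molar extinction coefficient (M^-1 cm^-1).
#' @param path_length path length in cm.
#' @return numeric vector along `tc$time`.
#' @export
a232_signal <- function(tc, epsilon_232 = 3800, path_length = 1) {
  if (!nrow(tc$species)) return(rep(0, length(tc$time)))
  epsilon_232 * path_length * drop(tc$amounts %*% tc$species$n_delta)
}

#' Exolytic index of a time course
#'
#' Discriminates exolytic from endolytic action: the maximum over time of
#' the fraction of 232-nm-visible (dUA-containing) material that sits in
#' species of DP > 2.  A pure exolytic digestion of saturated parents can
#' only place dUA in released disaccharides, so its index is exactly 0;
#' endolytic action creates larger unsaturated intermediates and gives a
#' positive index.  Returns 0 when no dUA-containing material ever exists.
#'
#' @param tc a `digestion_timecourse`.
#' @return fraction in [0, 1].
#' @export
exolytic_index <- function(tc) {
  if (!nrow(tc$species)) return(0)
  vis <- tc$species$n_delta > 0
  if (!any(vis)) return(0)
  big <- vis & tc$species$dp > 2
  denom <- drop(tc$amounts[, vis, drop = FALSE] %*% rep(1, sum(vis)))
  numer <- if (any(big))
    drop(tc$amounts[, big, drop = FALSE] %*% rep(1, sum(big))) else
    rep(0, length(tc$time))
  ok <- denom > 0
  if (!any(ok)) return(0)
  max(numer[ok] / denom[ok])
}

#' Stochastic completion times of a single substrate
#'
#' Draws the time at which a single chain becomes fully inert under
#' exact event-driven digestion, repeated `n` times.  For a
#' tetrasaccharide this is one exponential waiting time, so medians across
#' substrates order inversely to their hazards.
#'
#' @param chain substrate `glycan_chain` (or list of chains forming an
#'   epimer mixture, sampled uniformly).
#' @param enzyme an [enzyme_spec()].
#' @param rates a [rate_table()].
#' @param n number of replicate digestions.
#' @param seed RNG seed.
#' @return numeric vector of `n` completion times (min; `Inf` if the chain
#'   is inert from the start).
#' @export
simulate_completion_times <- function(chain, enzyme = heparinases()$exoHep,
                                      rates = default_rate_table(),
                                      n = 100, seed = 1) {
  chains <- if (inherits(chain, "glycan_chain")) list(chain) else chain
  set.seed(as.integer(seed))
  vapply(seq_len(n), function(i) {
    frags <- list(chains[[if (length(chains) == 1L) 1L else
      sample.int(length(chains), 1L)]])
    t_now <- 0
    repeat {
      site_list <- lapply(frags, chain_site_hazards, enzyme = enzyme,
                          rates = rates)
      per_frag <- vapply(site_list, function(h) sum(h$hazards), numeric(1))
      if (sum(per_frag) == 0) return(t_now)
      t_now <- t_now + rexp(1L, sum(per_frag))
      f <- if (length(frags) == 1L) 1L else
        sample.int(length(frags), 1L, prob = per_frag)
      h <- site_list[[f]]
      site <- if (length(h$sites) == 1L) 1L else
        sample(seq_along(h$sites), 1L, prob = h$hazards)
      p <- cleave(frags[[f]], h$sites[site])
      frags <- c(frags[-f], list(p$nre, p$re))
    }
  }, numeric(1))
}
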