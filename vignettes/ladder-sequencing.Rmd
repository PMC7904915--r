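---
title: "Modelling exolytic heparinase digestion and ladder sequencing of heparin oligosaccharides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exolytic heparinase digestion and ladder sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepseq)
```

## The problem

Heparin (HP) and heparan sulfate (HS) are linear glycosaminoglycans of
alternating uronate and glucosamine residues in 1→4 linkage, decorated by
2-O-, 3-O- and 6-O-sulfation and N-acetylation/N-sulfation. The sulfation
*sequence* along a chain — not just the bulk composition — determines
protein binding, but sequencing HP/HS oligosaccharides is notoriously hard.
Classical bacterial heparinases (Hepase I, II, III) are *endolytic* lyases:
they cleave internal glucosamine→uronate bonds by β-elimination, leaving a
4,5-unsaturated uronate (ΔUA, "dUA" in this package's ASCII notation) at
each new nonreducing end (NRE) and scrambling positional information.

An *exolytic* heparinase changes the game: it processively removes
disaccharides from the **reducing end** (RE) of a chain. Partial exolysis of
an oligosaccharide of *n* disaccharide units therefore produces a nested
ladder of NRE fragments with 2, 3, …, *n* units, all sharing the original
NRE. Differencing the disaccharide compositions of successive rungs reads
the sequence off unit by unit. `hepseq` implements this whole workflow in
silico: the symbolic chain model, the digestion chemistry of endolytic and
exolytic lyases, a kinetics simulator that reproduces the chromatographic
signature distinguishing the two modes, the ladder sequencer, and seeded
generators emulating the HPLC measurements.

## Chain model and notation

A chain is an ordered residue list from NRE (position 1) to RE (position
L). Uronates carry an epimer (`GlcA`, `IdoA`, the unsaturated `dUA`, or the
epimer-erased `HexUA`) and optionally `2S`; glucosamines carry an
N-substituent (`Ac`, `S`, or free amine `H`) and optionally `3S`/`6S`. Ring
classes strictly alternate; `dUA` may appear only at position 1; the
reducing end may carry a methyl glycoside (`OMe`) or the 2-aminobenzamide
fluorophore (`2AB`). The text notation mirrors how practitioners write
structures:

```{r}
p8 <- parse_chain("dUA-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S")
p8
disaccharide_units(p8)
```

Disaccharide units pair (uronate, hexosamine) **anchored at the reducing
end**, consistent with exolytic release; an odd chain (e.g. after
ozonolysis) leaves its NRE residue unpaired. Units map onto the eight
standard codes (`0S` … `2SNS6S`) spanned by uronate-2S × NAc/NS × 6S; any
3-O-sulfated or free-amine unit maps to `other`, mirroring the lack of a
corresponding commercial disaccharide standard.

Formula arithmetic sums glycosidically linked residue formulas (saturated
uronate C6H8O6, unsaturated C6H6O5, glucosamine C6H11NO4 + N-acetyl C2H2O
or sulfate SO3) plus one water for the termini. Because GlcA and IdoA are
isomers, epimer choices never move a mass, and an epimer-erased chain still
has a well-defined *sulfation-level* formula (requested explicitly).
Glycosidic B/C/Y/Z fragments and negative-mode [M − zH]^z− m/z values
support verifying simulated species against ESI-MS expectations. The 2-AB
label is modelled as reductive amination, a fixed +C7H8N2 delta.

## Digestion chemistry

An `enzyme_spec` is a pure yes/no cleavage predicate:

* the cleaved bond is glucosamine(j) → uronate(j+1); the uronate must be
  saturated and its class (`2S-uronate` / `unsulfated-uronate`) cleavable
  by the enzyme. Hepase I takes 2-O-sulfated uronates, Hepase III
  unsulfated ones, Hepase II and the exo-heparinase both;
* **3-O-sulfation blocking**: the linkage is uncleavable when the
  glucosamine at j+2 — the residue that would sit in the released,
  newly ΔUA-bearing disaccharide (+2 subsite) — carries 3S. This single
  rule reproduces the fondaparinux result: one exolytic cut releases
  dUA2S-GlcNS6S(OMe), then the 3S glucosamine (and, independently, the DP
  minimum) leaves an inert trisaccharide;
* mode: `endo` considers every eligible internal site; `exo` considers
  only j = L−2, requires a hexosamine RE, a substrate of at least
  `min_substrate_dp` (4; the smallest demonstrated substrate is a
  tetrasaccharide), and is abolished by a 2-AB-labelled reducing end.
  `OMe` does *not* block (fondaparinux is cut once); the endolytic DP
  minimum is 3 (a DP3 is digestible by Hepases I+II).

Cleavage converts residue j+1 to ΔUA (2S retained, epimer erased) without
consuming water, so product formulas sum exactly to the parent formula —
an invariant the test-suite asserts for every cleavage it performs.
Exhaustive endolytic digestion is confluent (cleavages at distinct sites
commute), so product multisets are order-independent. Whether an exolytic
remainder of DP3 can be cut once more is not decidable from the available
evidence; with `min_substrate_dp = 4` DP3 remainders are inert, and they
are visible as such in digestion outputs.

```{r}
digest_exo(hp_fixtures()$fondaparinux)$remainder
```

## Kinetics

Site kinetics are first order with the enzyme in excess — the data behind
the defaults are specific activities, not K_m/k_cat, so no saturation law
is fitted. Each site's hazard is looked up in a `rate_table` by local
context: (cleaved uronate epimer+2S) × (linkage glucosamine N-substituent +
6S), with an optional NRE-2S modifier. This is the finest granularity the
five reference tetrasaccharides can support: they differ precisely in the
linkage glucosamine (NAc6S / NS / NS6S), the cleaved uronate (GlcA /
IdoA2S) and the NRE 2S state. The default relative rates are proportional
to the measured activities (0.5, 3.98, 24.22, 49.12, 79.49; "<1" encoded
as 0.5), with unsulfated-IdoA contexts mildly penalised relative to GlcA
to encode the observed qualitative epimer preference. `base_rate`
normalises the `GlcA:NS6S:NRE2S` context to a half-life of one time unit
(minutes by convention) — an arbitrary, documented scale. The printed
single-timepoint conversion efficiencies are mutually inconsistent with
any single-rate first-order model scaled by those activities; they ship as
reference data (`reference_metadata("tetrasaccharide_activities")`) and
are never fitted.

`simulate_timecourse` first enumerates the finite species graph reachable
from the pool (exolytic chains are linear; endolytic digestion discovers
species on the fly), then either runs an exact Gillespie simulation over
it (exponential waiting times, seeded, residue counts conserved exactly)
or integrates the linear rate equations with `deSolve::lsoda`
(rtol 1e-9). The `exolytic_index` — the peak fraction of ΔUA-containing
material residing in species of DP > 2 — operationalises the
chromatographic contrast between the wild-type exolytic mode (index
exactly 0 on saturated parents, a structural theorem under the exo rule)
and the endolytic behaviour of the exit-tunnel charge mutants, which the
package emulates qualitatively as an endo spec with the same specificity
classes.

## The ladder sequencer

`simulate_ladder_experiment` reproduces the wet protocol: partial exolysis
yields the UDP4…UDP2n rungs; each rung is exhaustively digested with
Hepases I+II and its DP2 products counted; the UDP4 rung is additionally
ozonolysed (removing the ΔUA, hence position 1) and re-digested to isolate
position 2. `deduce_sequence` then:

1. integerises each rung composition (`integerize`: normalise, scale by k,
   round; accept iff the counts sum to k and no code deviates by more than
   `tol`, else raise an ambiguity carrying the two best candidate count
   vectors);
2. assigns position k (k = n … 3) as the unique unit in C(2k) − C(2k−2);
   a negative difference is an inconsistent ladder, reported with its k;
3. reads position 2 from the O3-trimmed UDP4 digest and position 1 as the
   UDP4 composition minus position 2.

Internal and RE uronates are reported as `HexUA` because β-elimination
erases the epimer — the method cannot do better without NMR/MS, and the
accuracy scorer (`sequence_accuracy`) therefore compares truth and call
after epimer erasure and masking of non-standard units. Non-unit
differences or `other` codes demote single positions to
`ambiguous`/`undetermined` rather than failing the call.

```{r}
lad <- simulate_ladder_experiment(hp_fixtures()$P8_4)
deduce_sequence(lad)
```

The default `tol = 0.2` units per code separates the clean measured ratios
from labelling-efficiency anomalies without pretending to a noise model
the data do not support; `validate_call` recomputes every rung from the
call and flags fragments deviating by more than a threshold (default 0.2
units) — the observed anomaly pattern in one measured octasaccharide
fraction, attributed to differential 2-AB labelling efficiency or sample
purity, is flagged, never corrected.

## What the synthetic data emulate — and what they do not

`chain_distribution` draws unit codes i.i.d. with configurable
frequencies. The defaults emulate the heparinase III-resistant, highly
sulfated heparin fraction that is the preferred exo-heparinase substrate:
55% trisulfated units, 20% NS6S, smaller shares of the remaining codes,
IdoA at 90% of 2-O-sulfated positions and GlcA at 70% of unsulfated ones —
values chosen once as field-typical for porcine-mucosa heparin.
Measurement noise is multiplicative lognormal on molar *amounts* (then
renormalised), matching how peak areas scatter, with an optional per-code
labelling-efficiency factor reproducing the anomaly mechanism above.

Real data differ in ways the generator deliberately ignores: unit codes
along real chains are correlated (domain structure), chromatographic noise
is not exactly lognormal, co-eluting species and baseline drift are not
modelled, and no retention-time or spectral simulation is attempted.
Passing the recovery benchmarks therefore demonstrates the *inference* is
sound under the stated measurement model, not that any instrument will
achieve those recovery rates.

## Numerical choices and problem sizes

Seeds parameterise every stochastic path (`generate_chain`,
`simulate_ladder_experiment`, `simulate_timecourse`,
`recovery_benchmark`); equal seeds give bit-identical results. The
benchmark derives per-chain seeds from the master seed arithmetically.
Integerisation ties (exact .5 deviations) surface as ambiguities rather
than being broken silently. The test-suite exercises the invariants at
sizes a laptop handles in seconds: 100–120 random chains for
formula/confluence properties, pools of 10^3–10^4 chains for the kinetic
signature and stochastic/deterministic agreement (compared within three
Monte-Carlo standard errors), 500 zero-noise octasaccharides plus a
120-chain noise curve for recovery, and 500 seeded completion-time draws
per tetrasaccharide — sizes chosen to make the statistical assertions
stable, not marginal.

## Known limitations

* Internal uronate epimers are irrecoverable by design; calls are
  epimer-erased.
* Rate contexts beyond the five measured tetrasaccharide contexts fall
  back to a single documented default; the table is an ordering model,
  not a fitted kinetic law.
* The endolytic-mutant emulation is qualitative (site choice only); no
  claim is made about mutant rate constants.
* The sequencer assumes the ladder is complete (every rung present) and
  generalises the O3 step always to the UDP4 rung, for any n ≥ 2.
* Protein utilities (Bjellqvist-pKa pI, average mass, GC content) serve
  record bookkeeping; they are not a proteomics toolkit.
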