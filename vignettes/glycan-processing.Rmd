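---
title: "Modelling ER N-glycan processing and site-specific glycoform quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ER N-glycan processing and site-specific glycoform quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotrim)
library(dplyr)
```

## The analytical problem

N-glycoproteins in the endoplasmic reticulum carry oligomannosidic glycans
derived from a single precursor, Glc3Man9GlcNAc2. A cascade of processing
enzymes edits this structure, and the editing state encodes the protein's
fate: a single α1,3-glucose on the A-branch is the binding determinant of
the calnexin/calreticulin (CNX/CRT) folding cycle, while removal of the
C-branch tip mannose exposes an α1,6-mannose that the lectin OS9 reads as
the commitment signal for ER-associated degradation (ERAD).

Mass spectrometry, the only practical way to read these glycans off a
specific glycosylation site, sees *compositions*, not structures: glucose
and mannose are both hexoses, so Man8GlcNAc2 and Glc1Man7GlcNAc2 are the
same Hex8HexNAc2 peak. Whether a misfolded protein still carries its
CNX-binding glucose is exactly the question such a peak cannot answer by
itself. glycotrim resolves it the way a glycobiologist does at the bench:
by simulating diagnostic digestions on explicit structures and keeping only
the structures consistent with the observed digestion products.

## The glycan model

A glycan is a rooted residue tree stored as a tibble, one row per
monosaccharide with its sugar, linkage (α1,2 / α1,3 / α1,6 / β1,4), branch
label and parent. The Glc3Man9GlcNAc2 topology is hardcoded once: a
chitobiose core and β1,4-mannose; the α1,3 arm carrying branch A
(Man-α1,2-Man-α1,2) capped by Glc-α1,2-Glc-α1,3-Glc-α1,3; the α1,6 arm
carrying branch B (Man-α1,2-Man-α1,3) and branch C (Man-α1,2-Man-α1,6).
Branch labels are fixed by position in this topology and never recomputed —
they are biological identities, not graph properties. Residue identifiers
are the linkage paths from the reducing end, which makes identifiers stable
across enzyme edits and makes the canonical serialisation
(`format_structure()`, children ordered α1,2 < α1,3 < α1,6 < β1,4) a
usable equality key.

Every other registry structure (`glycan_registry()`) is *derived* from the
precursor by the rule engine rather than hardcoded, so the registry cannot
drift out of sync with the rules. Man8 isomers are named by the branch
whose tip is missing (`Man8GlcNAc2-A/-B/-C`) because composition alone
cannot distinguish them.

## Enzyme rules and their assumptions

Each enzyme is a deterministic rewrite rule with an explicit substrate
requirement; a non-substrate raises a typed condition rather than silently
doing nothing (except JBM, whose no-substrate case is a legitimate
fixpoint).

* **GCSI** removes the single terminal α1,2-glucose; **GCSII** removes one
  terminal α1,3-glucose per application.
* **UGGT** adds one α1,3-glucose onto the A-branch tip mannose, and only
  onto a glucose-free glycan whose A-tip is present and terminal. This
  captures why endomannosidase action is irreversible: it removes the
  acceptor itself.
* **MNS4/MNS5** removes the C-branch tip α1,2-mannose. The literature
  attributes the C-branch trim to these EDEM homologues, while the fully
  processed glycan observed on ERAD substrates (Glc1Man7GlcNAc2) also lacks
  the B-tip; whether MNS4/MNS5 or another ER mannosidase removes the B-tip
  is genuinely open. We therefore model two ordered sub-rules — C-tip
  always, B-tip only with `extended = TRUE` — and assert neither. When the
  B-tip is already gone, the extended call degrades gracefully to the
  C-only trim, since the substrate requirement is on the C-branch.
* **EndoM** (endomannosidase) removes the Glcα1,3Man disaccharide from a
  glycan carrying *exactly one* glucose. Its action on di- and
  triglucosylated glycans is disputed, so those are rejected as
  non-substrates rather than guessed at.
* **JBM** (jack bean α-mannosidase) removes terminal α-linked mannoses.
  Glucose is never a substrate, so a glucose cap protects the whole A-arm
  beneath it; the β1,4 core mannose survives every digest. One iteration
  removes *all* currently terminal α-mannoses simultaneously. Real partial
  digests are asynchronous; the synchronous model was chosen because it
  makes the iteration-k product well defined and reproduces the observed
  Hex5–Hex8 intermediate band of partially digested monoglucosylated
  glycans, which is what the partial-digestion simulator needs. The limit
  digest is a fixpoint and idempotent.

`os9_signal_exposed()` reports the degradation-signal state: true iff the
C-stem α1,6-mannose is present and terminal.

### Isomer inference

`infer_isomer()` enumerates the closure of the rule set from
Glc3Man9GlcNAc2 (breadth-first, deduplicated on the canonical
serialisation — `reachable_structures()`), keeps candidates matching the
observed composition, and filters by evidence: the limit-JBM product
composition and/or EndoM sensitivity. Distinct chromatographic elution from
glucose-free standards is recorded as supporting evidence on glucosylated
candidates rather than used as a hard filter, since retention behaviour is
not modelled. Candidates are restricted to at most one glucose by default
(`max_glc`), reflecting co-translational GCSI/GCSII action; ordering is
glucose count descending, then name — a fixed tie-break so reports are
reproducible. An inference with no surviving candidate returns an empty
tibble with a warning instead of failing, because in a pipeline one
unassignable composition should not abort the site.

## Mass arithmetic and matching

All masses are monoisotopic and derived from atomic masses (C 12, H
1.007825, N 14.003074, O 15.994915, S 31.972071) through residue formulas:
Hex C6H10O5, HexNAc C8H13NO5, dHex C6H10O4, Pent C5H8O4, and the standard
amino-acid residue formulas. Matching tolerances are ppm-scale on kDa
masses, so ≥6 decimal places matter. Cysteines carry the fixed
carbamidomethyl modification (+57.021464 Da); variable modifications are
out of scope. A released glycan (PNGase product) gains one water relative
to its peptide-bound residue masses.

Peak lists are deconvoluted neutral masses — charge-state deconvolution is
assumed done upstream. `match_peaks()` assigns each peak to its nearest
candidate within tolerance (default 10 ppm, the Orbitrap-class setting);
each candidate keeps only its best peak, ties breaking to the lower mass.
These defaults are declared, not inferred: the enumeration bounds (HexNAc
1–2, Hex 0–12, dHex 0–1, Pent 0–1) cover the oligomannosidic series and
plant-typical fucose/xylose without generating isobaric collisions at
ppm-scale tolerance.

Quantification normalises summed assigned intensities per composition to
100% of *identified* glycoforms — unassigned and decoy peaks never enter
the denominator. This makes columns scale-invariant and decoy-robust by
construction, both of which are asserted as properties in the test suite.
Report TSVs print one decimal place, mirroring conventional glycoform
tables; full precision is kept internally.

## The synthetic-data generator

`simulate_spectrum()` emulates exactly the features of a deconvoluted
LC-ESI-MS glycopeptide spectrum that the pipeline consumes: one peak per
glycoform at its theoretical mass perturbed by Normal ppm error, intensity
proportional to the glycoform fraction times unit-mean lognormal noise
(lognormal because intensities are strictly positive), and uniform decoy
peaks rejected within a minimum ppm offset of every theoretical candidate.
Each spectrum has one private random stream with a fixed draw order
(masses, intensities, decoys), so a seed fully determines the output and
the session RNG is untouched.

What it does *not* emulate — chromatographic elution, isotope envelopes,
charge states, in-source fragmentation, co-eluting interferences — bounds
what passing tests show: recovery results demonstrate the correctness of
the annotation/quantification arithmetic under the stated noise model, not
robustness to every artefact of real spectra. Default study conditions for
recovery experiments are 3 ppm mass error against a 10 ppm tolerance
(P(|ε| > 10 ppm) ≈ 8.6×10⁻⁴ per peak), 10% intensity CV, and reference
glycoform proportions taken from the measured SUBEX-C57Y table.

`simulate_digestion_series()` converts the product composition of each JBM
iteration into a released-glycan peak with intensity proportional to a
supplied weight vector, collapsing iterations past the fixpoint onto the
limit peak.

## Reference data

`subex_c57y_glycoforms()` ships the measured relative glycoform abundances
of the ERAD substrate SUBEX-C57Y from the *Arabidopsis* `os9` and
`mns4 mns5` mutants at its three sequons (NIT, NLS, NTS), and
`subex_c57y_monoglucosylated()` records which isobaric composition carries
the monoglucosylated structure in each genotype (Hex8HexNAc2 =
Glc1Man7GlcNAc2 in `os9`; Hex9HexNAc2 = Glc1Man8GlcNAc2 in `mns4 mns5`).
Averaged over sites 1–2 of both genotypes the monoglucosylated fraction is
60%:

```{r}
monoglucosylated_fraction(subex_c57y_glycoforms(),
                          subex_c57y_monoglucosylated(),
                          sites = c("site1", "site2"))
```

One open point is deliberately left open: the Hex7HexNAc2 peaks of
`mns4 mns5` cannot be unambiguously assigned (low signal in the source
measurements), so no canonical Hex7 structure is registered for that
genotype and inference simply lists the reachable Hex7 candidates.

## Numerical choices and degenerate inputs

* Tree equality is string equality of the canonical serialisation; no
  general isomorphism test is needed because child linkage order is a
  total order.
* Composition masses are exact sums of double-precision residue masses;
  additivity holds to 1e-9 Da and agreement with an independent
  residue-table oracle to 1e-5 Da per residue.
* Column sums of `quantify_site()` are exact to accumulation error
  (asserted at 1e-9); report readers warn at ±0.5 to accommodate printed
  one-decimal tables.
* Degenerate inputs fail loudly with typed conditions: empty peptides,
  non-standard residues, malformed structure strings (the error names the
  offending token), empty assignment sets, infeasible decoy placement.
* Peptides carrying more than one sequon are annotated with a warning —
  composition assignment still works, site-resolution does not.

## Problem sizes in the test suite

The property suites run at sizes chosen to give comfortable statistical
resolution while keeping the full check fast on a laptop: 200 random
sequences for the sequon oracle, 300 + 1000 random peptides for the mass
oracle, 200 + 1000 random spectra for the matching oracle, 100 seeded
replicates for noisy-recovery Monte Carlo, and exhaustive loops over the
full structure registry for the conservation, idempotence, protection and
closure properties.

## Known limitations

* No enzyme kinetics or competition: rules are untimed rewrites, so the
  "mannosidase timer" hypothesis is out of scope by design.
* No MS/MS evidence: identification rests on intact masses and mass-shift
  patterns, not fragment ions; no FDR model.
* One glycan per peptide; O-glycans, phosphorylated/sulfated glycans and
  Golgi-type processing beyond EndoM are not modelled.
* PGC retention behaviour is reduced to a boolean evidence flag.
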