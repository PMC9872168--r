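---
title: "Modeling the DNA-probe RNase protection assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the DNA-probe RNase protection assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaseprotect)
```

## The assay model

The package simulates a protection assay in which an antisense DNA
oligonucleotide hybridizes to a segment of a single-stranded mRNA and
single-strand-specific ribonucleases degrade the rest. Three modeling
assumptions define the core:

1. **All-or-nothing hybridization.** A probe binds wherever the target
   subsequence is the probe's exact reverse complement, and nowhere
   else. No mismatch tolerance, melting temperature or secondary
   structure enters the model: the assay's own readout logic is binary
   (perfect complement ⇒ protected fragment; otherwise complete
   digestion), and that is the behavior reproduced here.
2. **Binary salt switch.** Under `high_salt` (the bench condition is
   700 mM NaCl) the DNA–RNA hybrid is fully nuclease-resistant; under
   `low_salt` protection is void and the whole molecule is substrate.
   No intermediate kinetics are modeled.
3. **Complete digestion.** Every cleavable bond is cut (saturating
   enzyme, unlimited time), which is how assay lanes are interpreted.
   RNase A recognizes C and U, RNase T1 recognizes G; both leave
   5'-hydroxyl / 3'-phosphate products (the 2',3'-cyclic intermediate
   is selectable per enzyme and matters only for masses).

### The boundary-cleavage convention

Whether the nuclease can cut the bond immediately 3' of the hybrid is
not resolvable at gel resolution (±1 nt), so both conventions are
implemented and every result records which was used:

* `edge_permissive` (default): the bond after a recognition base is cut
  whenever the *downstream* residue is free. The protected fragment
  then ends exactly at the hybrid boundary whenever the boundary base
  is cleavable, giving the canonical fragment-length = probe-length
  readout; this is why it is the default.
* `free_base_required`: both residues flanking the bond must be free;
  the protected fragment then extends to the next cleavable base
  downstream.

Note the rule is deliberately asymmetric: at the hybrid's 5' edge the
downstream residue is protected, so under either convention the
upstream free run attaches to the protected fragment. For 5'-end
probes (the cap assay) this is moot, since the protected fragment
starts at position 0.

## Gel model

Denaturing urea-PAGE separates single strands by length, and within a
window of oligo lengths it resolves single nucleotides. Only ordering
and resolvability carry information, so mobility is modeled ordinally
through an *apparent length* in DNA-length equivalents:

| species | apparent length |
|---|---|
| DNA, length L | L |
| RNA, length L | L + `rna_offset` |
| cap 0 RNA, length L | L + `rna_offset` + `cap0_offset` |

mapped monotonically to a relative mobility `1 / (1 + apparent/100)`.
Defaults: `rna_offset = 1.0` nt-equivalents (RNA runs visibly slower
than DNA of equal length, resolvable on a single-nt gel) and
`cap0_offset = 1.0`. The true electrophoretic increment of the cap 0
structure is not established; 1.0 is the minimal value that a
single-nucleotide gel resolves, it is a configurable placeholder, and
assay printouts flag it as such.

Band formation merges species whose apparent lengths differ by less
than the applicable resolution: 1 nt-equivalent when either member of
the pair has nominal length inside the `resolution_window` (default
16–24 nt, the range where such gels are single-nucleotide sharp), 3
otherwise. Merging compares *apparent* lengths, which is what lets a
24-nt DNA probe and a 24-nt RNA fragment resolve while two RNAs half a
step apart co-migrate. Species shorter than `min_detectable` (default
8 nt — safely below the resolution window; the bench observation is
only that small fragments vanish, without a number) are invisible.
Intensity is molar abundance; staining differences between DNA and RNA
are ignored, and intensity is conserved through merging.

Capping efficiency is the capped band's share of the protected-fragment
doublet. The estimator refuses to quantify when the two species
co-migrate (e.g. a sub-resolution `cap0_offset`) rather than returning
a silently meaningless number, and treats an absent band as zero
intensity so fully capped or fully uncapped pools report 1 or 0.

## The synthetic fixture generator

Real assay substrates are transcripts with known 5' sequence; none are
printed in full anywhere, so test material is generated, not stored.
`generate_fixture()` builds targets with exactly the structural
features the assay logic relies on, and nothing else:

* the first `probe_length` residues are (optionally) the probe's
  perfect complement, and the residue at the probe's 3' boundary is
  forced to a pyrimidine so that the protected fragment length equals
  the probe length under either RNase A or the mixture — the readout
  the assay is built on;
* everywhere else, no run of `max_free_run` (default 7) residues lacks
  a pyrimidine. This guarantees every unprotected fragment stays below
  the 8-nt detection threshold under RNase A *alone*, and a fortiori
  under the A + T1 mixture — so clean two-band lanes are a provable
  property of the fixture, not luck. Pyrimidines rather than C/U/G are
  used because the single-enzyme scenario must also be clean;
* an optional 3' poly(A) tail, which has no cleavage sites and
  therefore survives as its own band (this is the poly(A)-tail
  readout, not an artifact);
* a capped/uncapped pool split at an exact molar `cap_fraction`, which
  is what makes capping-efficiency recovery a machine-precision
  parameter-recovery test.

What the generator does **not** emulate: real base composition bias,
RNA secondary structure, abortive/heterogeneous IVT products, DNA
template contamination, partial digestion and staining noise. Passing
tests therefore validate the assay *logic* (protection geometry,
specificity arithmetic, mobility bookkeeping), not robustness to real
gel artifacts. Default scenario sizes mirror the bench constructs:
86-nt and 2191-nt targets with 16–26-nt probes.

## Mass mapping

Fragment masses are summed from elemental compositions (monoisotopic
and average). The convention: residue mass = nucleoside
5'-monophosphate − water, so Σresidues + water is the
5'-monophosphate/3'-OH chain, with end-chemistry adjustments relative
to that baseline (5'-OH −HPO₃; 5'-triphosphate +2 HPO₃; cap 0
+2 HPO₃ + 7-methylguanosine − H₂O, applied to 5'-terminal fragments
only; 3'-phosphate +HPO₃; 2',3'-cyclic +HPO₃ − H₂O). Two algebraic
identities fall out and are enforced as test invariants: cyclic =
linear − water, and Σ fragment masses = parent + cuts × water.

`design_tiling()` implements the probe-tiling extension of the assay
for mass spectrometry: one probe per digestion round (the bench
format; a multiplex single-pot mode exists but is off by default), and
a round contributes its protected fragment's positions to coverage only
if that fragment is detectable (`min_frag_len` default 3 nt — mono- and
dinucleotides are assumed lost in the low-mass region; an upper limit
is available and unbounded by default) and mass-unique within
`tolerance_da` (default 0.01 Da monoisotopic; raise for lower-resolution
instruments) against every other fragment of that round's digest.
Selection is greedy set cover with deterministic tie-breaks (leftmost
start, then shortest probe), and probe intervals never overlap across
rounds. The unprobed digest is always counted as round 0 — a
practitioner runs it anyway — which makes tiling coverage ≥ baseline
coverage an invariant on every input; a target too short for any probe
simply reports the baseline coverage with an empty probe list.
Uniqueness of identical-sequence fragments is decided by mass, so two
copies of the same interior fragment disqualify each other exactly.

## Buffer integration

The buffer module turns tables of published recipes into per-component
statistics and applies three integration rules. Choices a user should
know:

* **Medians over containing recipes.** A recipe that omits a component
  contributes absence to the frequency, not a zero to the median; an
  even count of values averages the two central ones.
* **Essential ⇔ 100% frequency** within a reaction type, exactly.
* **Rule precedence.** A component present on both sides goes through
  rule 3 (take the larger median) even if it is essential on only one
  side; rule 1 (include at its own median) applies to components
  absent from the other side; rule 2 excludes the rest. The rule-3
  exceptions — `detrimental` (the winning concentration would harm the
  other reaction) and `lowest_equivalent` (evidence the lower dose
  suffices) — both resolve to the smaller median; they carry distinct
  provenance tags because they encode different kinds of evidence, and
  neither can be inferred from the table itself, so they are explicit
  user flags.
* Substrates (SAM, extra GTP) are consumables, not buffer chemistry;
  they are appended at stock emission with `substrate_added`
  provenance rather than passed through the rules.
* Component names are canonicalized through a user-extensible synonym
  table; unknown names pass through verbatim with a warning.

The bundled `buffer_recipes_synthetic.tsv` is a synthetic stand-in
shaped like a literature survey (11 IVT sources, 3 identical capping
sources) and constructed so its IVT medians take round reference
values; it exercises every rule branch, including a 1-in-11 KCl and
excluded detergents.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; IRanges does interval
  arithmetic behind the scenes.
* When two enzymes recognize the same base, the first listed claims the
  cut (affects only the recorded 3' chemistry, and only if the enzymes
  differ in their product setting).
* An empty enzyme list returns the intact parent as one fragment; a
  single-residue RNA has no bonds and is never cut; an empty species
  list predicts an empty lane; zero-abundance species are dropped
  before banding.
* Probes with zero or multiple binding sites are reported, never
  fatal; a probe longer than its target is an error.
* Mass comparisons use absolute tolerances in Da; sequence-identical
  fragments with identical end chemistry are exactly equal, so the
  uniqueness rule needs no special casing.

## Limitations

Thermodynamics (Tm, ΔG, secondary structure), partial-digest kinetics,
RNase H-style cleavage, dsRNA-specific nucleases, densitometry of real
gel images, isotope distributions, adducts and spectrum simulation are
all out of scope. The cap 0 mobility increment is a placeholder until
measured. Probe uniqueness is checked against the provided target
only, not a transcriptome — appropriate for defined IVT material, not
for probing complex samples.
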