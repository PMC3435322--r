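---
title: "Simulating and scoring mock amplicon communities"
author: "mockamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring mock amplicon communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockamp)
```

## The experiment this package puts in software

A mock (*in vitro*-simulated) community is the one setting in which an
amplicon workflow can be graded absolutely: the templates and their input
proportions are known, so every recovered OTU is either a real community
member or a nameable artifact. `mockamp` simulates that experiment end to
end — reference panel, abundance profile, PCR, chimeras, contamination,
reads — and then runs the standard recovery workflow against the simulated
truth. Because the simulator emits a per-read truth table, the downstream
classifier can partition OTUs into six categories without heuristics:

* **true** — some member unique sequence exactly equals a reference
  amplified region (or a sanctioned unambiguous prefix of one);
* **miscalled** — no member unique is exact, but the OTU holds raw reads
  that are error-free copies of a reference (the workflow de-noised clean
  reads into an erroneous representative);
* **chimeric** — the representative's reads are chimeric molecules;
* **contamination** — the representative lies within the near-match cutoff
  of the contaminant set;
* **near-match** — the representative is within the cutoff of a reference
  that no true or miscalled OTU accounts for;
* **false-derived** — none of the above: pure error products.

Categories are assigned in two passes (true/miscalled first) so that
"a reference not found in any true or miscalled OTU" is well defined, and
in the stated precedence order, so every OTU receives exactly one label.

## The generative model

**Reference panel.** All templates descend from one random ancestor
amplified region. Similar-group members receive a fixed number of private
substitutions (default 5 on a 250-nt amplicon), so two of them differ at
roughly 10 sites (~4 %) — close enough that the most aggressive clustering
settings occasionally merge a pair, as happens with real congeneric clone
panels. Divergent templates (default 1 of 20) receive enough substitutions
to guarantee ≥40 differences from every similar template. Priming regions
flank the amplicon; degenerate primer positions are concretized, and
per-template mismatches can be injected at chosen primer positions to drive
amplification bias.

**Abundance profiles.** `make_profile()` provides the equal design (1/n
each) and the canonical tiered design over 20 templates — tiers 0.18,
0.15, 0.10, 0.05, 0.01, 0.001, 0.0001, 0.00001 in multiplicities
2/2/2/2/3/3/3/3. The raw tiers sum to 0.99333 and are renormalized; the
max/min ratio of 18,000 is preserved. Custom tier vectors are accepted.

**PCR.** Endpoint (not per-molecule) amplification: template *i* gets a
per-cycle efficiency
`e_i = e0 · p^m5 · (p·q)^m3`, with `e0` the base efficiency (default 0.9),
`p` the per-mismatch penalty (0.85), `q` the extra 3′-half penalty (0.7,
because extension proceeds from the primer's 3′ end), and `m5`/`m3` the
mismatch counts in the 5′/3′ halves (split at ⌈len/2⌉) of both priming
regions. After `C` cycles (default 30, a deliberately low-cycle protocol)
frequencies are proportional to `p_i (1+e_i)^C`. The literature offers no
quantitative mapping from mismatch position to efficiency, so the penalty
parameters are exposed in the config rather than calibrated; the model's
job is to reproduce the *phenomenology* — a perfectly matched rare template
overwhelming the pool — which it does with room to spare (a 1 % input can
exceed 99 % of the endpoint pool under the defaults).

**Chimeras.** Formed post-PCR from the biased pool: parents drawn with
probability proportional to pool frequency, one breakpoint uniform over
interior positions, sequence = parent A's prefix + parent B's suffix.
Total chimera mass equals `chimera_rate` (default 0.005, matching the
sub-1 % share seen in real mock data); the experimental design fixes that
total but not per-species weights, so each of `n_chimera_species`
(default 5) gets an equal share. Chimeras colliding with an existing
template sequence are redrawn.

**Contamination.** A packaged synthetic "cloning-vector" sequence set
(random, hence >10 % divergent from every template) stands in for host
contamination; a `contamination_rate` fraction of reads (default 0.005) is
drawn from it and flagged.

**Reads and errors.** Each read is MID + forward primer + amplified region.
Per base: substitution with `substitution_rate` (default 0.003), ambiguous
call (N, quality 0) with `ambiguous_call_rate` (0.0005); per homopolymer
run of length L ≥ 2, an insertion or deletion of the run base with
probability `homopolymer_indel_base_rate · (L−1)` (0.001) — the dominant
pyrosequencing error mode, with a linear length dependence because no
functional form is established. The defaults sum to a per-base error rate
just under 0.5 %, i.e. per-base accuracy above 99.5 %, which still leaves
~60 % of 250-nt reads carrying at least one error. Qualities are 35–40 at
correct positions, 5–15 at errored positions, 0 at N calls. Errors are
applied to the amplified region only: the truth table's `n_errors` then
counts exactly the events that can defeat error-free identification, and
demultiplexing failure is exercised separately with deliberately corrupted
prefixes. An optional `truncation_rate` produces prematurely terminated
reads for testing prefix matching.

**Determinism.** All randomness flows from one root seed through named
substreams (`stage_seed()`), so any stage can be re-run in isolation and
whole runs are byte-identical under a fixed config.

## The recovery workflow

**Demultiplexing** requires a perfect MID match followed by an exact
IUPAC-aware primer match (N in the primer matches any base; an N *in the
read* matches nothing); everything else is discarded, as in the original
perfect-match protocol. Reads shorter than MID+primer cannot match.

**Error-free identification** is exact string matching over the amplified
region. With `allow_premature`, a read may instead equal a reference prefix
of length ≥ `min_prefix`; `min_prefix` must be at least the minimum
unambiguous length of the panel (the smallest k at which all reference
prefixes are pairwise distinct), and we additionally require the prefix to
identify a single reference — the published rule does not state whether
longer shared prefixes can occur, so global unambiguity is enforced and
documented as an interpretation. Full matches win over prefix matches.

**Quality filters.** The SLP-style filter removes reads with any ambiguous
base, mean quality < 30 (a read at exactly 30.0 survives; the rule is
strictly "less than"), or length < 50. The fixed-length filter truncates to
a target length (60 nt for short, 216 nt for long amplicons) and removes
reads with ≥ 3 % of bases at quality ≤ 27. Both are idempotent.

**Distances.** Global alignment with fixed scoring (match +1, mismatch −1,
gap open 2, gap extend 1 — not exposed, so distances are bit-reproducible);
distance = (mismatches + internal gap columns) / alignment columns,
ignoring terminal-gap columns, so a clean prefix is at distance 0 from its
full-length reference. Two numerical choices matter:

* equal-length pairs with ≤ 3 differences short-circuit to Hamming/length —
  under this scoring a gapped alignment of equal-length strings costs at
  least 6 more than the gap-free one, so the short-circuit is provably
  exact, and it makes preclustering thousands of near-identical uniques
  tractable;
* alignments are always computed with the lexicographically smaller
  sequence as the pattern, so ties between equal-score alignments resolve
  identically in both argument orders and the distance is symmetric by
  construction.

**Clustering.** Dereplication sorts by abundance (descending, then
sequence, then insertion order — the tie-break used everywhere).
Single-linkage preclustering absorbs each unique into the most abundant
earlier unique within a width of 0.02; passes repeat until either a pass
makes no merge or every survivor has abundance ≥ 10. The published
description of the iterative rule is loose, and this repeat-until-stable
reading is flagged as an interpretation. Greedy clustering assigns each
unique to the first centroid within 1 − identity (default 97 %), else
seeds a new OTU. Average-neighbor clustering is agglomerative
average-linkage cut at 0.03, maintained with the UPGMA Lance–Williams
update and a deterministic lowest-pair-index tie-break (which is why it is
implemented directly rather than via `hclust`, whose tie order is not
guaranteed). The clustering control reruns the chosen procedure on the
reference amplicons alone, giving the OTU count an error-free dataset
would produce.

**Classifier details.** The near-match cutoff defaults to 0.03 — the
clustering cutoff — because "matching closely" is never quantified in the
underlying scheme; it is exposed in the config. With a truth table, an
OTU's chimera/contaminant call uses the majority provenance of the
representative unique's member reads (ties prefer chimera, then
contaminant): identical sequences can in principle arise from different
sources, so a vote is the well-defined reading of "the representative is
labelled chimeric". Without a truth table (scoring mode), chimeras are
detected by two-parent reconstruction: a representative is chimeric when
some prefix+suffix combination of two references reaches near-identity
while no single reference does. For every false-derived OTU the ratio of
its abundance to its most similar true OTU is reported, since that is the
natural measure of how large error-derived OTUs grow relative to their
sources.

## Statistics

Spearman ρ uses mid-ranks; log-log Pearson uses base-10 logs (the
correlation is base-invariant) over strictly positive pairs, with the
exclusion count attached. Bootstrap resampling draws `target_size` reads
with replacement from the pool of error-free read labels — implemented as a
multinomial draw over pool frequencies, which is the same distribution —
and summarizes each coefficient by mean and 2.5/97.5 percentiles; the
one-sided p value uses the add-one rule `(1+k)/(B+1)` so Monte-Carlo p
values are never zero. Chao1 uses the bias-corrected form
`S_obs + F1(F1−1)/(2(F2+1))`, the variant under which fractional values
like 48.75 are representable. Mismatch-effect tests delegate to
`cor.test`/`wilcox.test` with exact small-sample p values where tie-free;
template exclusions are an explicit argument, never automatic.

## What the simulation does and does not establish

The generator reproduces the *mechanisms* (sampling depth, PCR bias,
chimeras, contamination, per-base error) but not everything in real
pyrosequencing data: no flowgram-level signal or position-dependent error
profile, no heteroduplexes, no per-molecule PCR stochasticity, no
cycle-by-cycle temperature effects, and taxon labels are cosmetic. Passing
tests therefore demonstrate that the workflow's bookkeeping, statistics
and classifications are correct and that the pipeline responds correctly
to each simulated mechanism — not that any particular real dataset will
show the same OTU counts. Correspondingly, the test suite works at sizes
chosen for tight feedback: pipelines of 500–10,000 reads, panels of 2–20
templates, 20-seed classifier sweeps, 50-seed detection-limit sweeps and
B = 2,000 bootstraps; the defaults (20 templates, 10,000 reads, B = 10,000
available in config) are the canonical experiment scale.

## Degenerate inputs and edge rules

Constant frequency vectors make rank correlation undefined; it is reported
as NA rather than forced. Fewer than three positive pairs make the log-log
correlation NA. An empty OTU set has Chao1 0; no singletons reduce Chao1
to observed richness. A chimera rate with fewer than two pool species, a
contamination rate without a contaminant set, mismatch positions outside
the primer, duplicate MIDs, and unknown config keys are all hard errors —
the config schema is frozen so drift fails loudly.
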