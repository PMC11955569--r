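---
title: "satcomp: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{satcomp: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What satcomp does

Satellite DNAs (satDNAs) are tandemly repeated, non-coding sequences organized
in head-to-tail monomer arrays. The complete catalog of satDNA families of a
genome — its *satellitome* — can be characterized directly from unassembled
short reads, because a high-copy tandem repeat is over-represented in any
read sample regardless of assembly. satcomp implements that workflow end to
end for comparative, multi-species studies:

1. **synthesis** — a generator of multi-species, two-sex genomes and paired
   reads with a *known* planted satellitome (the "library" of shared ancestral
   families, differentially amplified per lineage) plus exact truth tables;
2. **discovery** — iterative mining of a read sample: k-mer clustering,
   tandemness detection by de Bruijn cycle, consensus monomer reconstruction,
   masking of discovered families and re-iteration until exhaustion;
3. **quantification** — masking-based abundance (% of sampled bp) and
   per-read Kimura two-parameter (K2P) divergence, repeat landscapes,
   sex-bias (F/M) classification, composite-satellite sub-region
   quantification, catalog summaries, ORF scans;
4. **comparison** — cross-species homologous-family detection with a
   shuffle null, consensus K2P distances, consensus turnover rates
   (CTR = K / 2T), and paired t-tests between landscape profiles.

Because real sequencing libraries for any particular study system are not
shipped with the package, every claim a test makes is measured against the
synthetic generator's truth: the generator's defaults *are* the stated world,
and a green test establishes recovery of planted quantities under that world,
not performance on any particular real library.

# The models

## K2P mutation and distance

All divergence in the package is governed by Kimura's two-parameter model.
The generator (`mutate_monomer`) draws a Poisson(`rate * t`) number of
substitution events per site; each event is a transition (A↔G, C↔T) with odds
`kappa : 1` against the two transversion targets jointly. The estimator
(`kimura2p`) inverts the model from observed proportions of transitions `P`
and transversions `Q` over aligned non-indel columns:

```
K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))
```

The expected `K` between a sequence and its mutated copy is exactly
`rate * t` (multiple hits are corrected, not avoided). Saturated inputs
(`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) return `NA`, the sentinel used to
exclude a hit from landscapes, with a counted warning. `K >= P + Q` always,
with equality only at zero distance; property tests assert both.

## Masking and abundance

A read is assigned to a family by local alignment (+1 match, −1 mismatch,
−2 per gap column) against the *dimerized* consensus — the monomer
concatenated with itself (or tiled past the read length for short monomers) —
so reads crossing the array junction, and any rotation of the consensus,
align contiguously. Abundance is `100 * masked bp / total sampled bp`;
with a catalog, each read goes to its best-scoring family (ties broken by
abundance rank) so related families never double-count.

A hit must pass three floors: identity ≥ 70% (indel columns count against
identity but are excluded from `P`/`Q`), aligned span ≥ 30 bp, and alignment
score ≥ 25. The score floor is the repeat-masking cutoff tradition: without
it, reads sharing two random 12-mers with a multi-kilobase consensus
accumulate ~30–40 bp chance alignments that inflate abundances by ~0.01–0.03%
at genome scale — material when quantifying families at 0.05% of the genome.
A 150 bp read at the 40% divergence ceiling of the landscape domain still
scores ≈ 30, so the floor does not truncate landscapes.

Sensitivity note: the k-mer prescreen (two shared 12-mers, either strand)
bounds the masker's reach at roughly 30% read-to-consensus divergence;
beyond that, hits are increasingly missed before alignment. The fixtures
plant divergence clouds within the detectable range, which matches the
biology the pipeline targets (recent amplification peaks near 0%).

## Repeat landscapes

A landscape is the histogram of masked bp over 41 one-percent K2P bins
`[i, i+1)`, `i = 0..40`, expressed as % of sampled bp. Bin sums equal the
family's abundance (minus the counted discards beyond 41% and saturated
hits), and profiles normalized to the family's own mass make species with
different absolute abundances comparable. Landscape pairs are compared by a
paired t-test across bins — hence `df = 40` for every default comparison —
computed on the *normalized* profiles, with `t` oriented as
`mean(b − a) / se`. Identical profiles yield a "degenerate" sentinel rather
than `t = 0`. Whether absolute or normalized bins should be compared is
genuinely open; normalization was chosen so that the test asks "same shape?"
rather than "same amount?".

## Sex bias

The F/M ratio is the quotient of a family's female and male abundances; a
family is called sex-biased strictly above 1.2 (a proxy for X-linked
enrichment under male heterogamety, where the X is present in two female
doses). At exactly 1.2 the call is negative — the boundary test pins that.
`abund_M = 0 < abund_F` yields a "female_specific" sentinel; a missing
female library skips classification with a log note (as in studies that
sequence females for only a subset of species).

## Discovery

The discovery stage re-implements, in deliberately simplified and fully
offline form, the cluster-and-filter approach of satellite-mining pipelines
built on read clustering + tandem detection:

* **Sampling.** Discovery operates on a low-coverage sample (~1× genomic;
  200,000 pairs is the fixture default, 5,000,000 the documented full-scale
  default). At ~1×, single-copy sequence rarely overlaps between reads, so
  only repeats form large k-mer-sharing components; the satellite stays deep
  because of its copy number, not the sampling.
* **Clustering.** Reads sharing canonical 21-mers form a graph; clusters are
  connected components with ≥ 25 members. Components are linked by chaining
  adjacent reads in each k-mer's posting list (equivalent connectivity at the
  default `min_shared_kmers = 1`; a documented approximation above it).
* **Tandemness.** A cluster is tandem-positive when the heaviest simple cycle
  of its de Bruijn graph (greedy maximum-multiplicity walk, ties broken by
  lexicographic k-mer order, both strands counted jointly) carries ≥ 0.8 of
  the cluster's k-mer mass. Reads tiling a dispersed single-copy decoy spell
  a path, not a cycle, and are rejected.
* **Consensus.** The cycle-spelled candidate is polished by a gapless
  majority-vote pileup of cluster reads anchored on the dimerized candidate —
  gapless is principled here because both the mutation model and the
  sequencing-error model are substitution-only — and reported in canonical
  rotation: the lexicographically smallest string over all rotations of both
  strands, making consensuses comparable across runs, phases and strands.
* **Short monomers.** Monomers shorter than about the k-mer size cannot be
  represented robustly by the k = 21 graph, so reads whose minimal internal
  period is ≤ k + 1 (exact autocorrelation with 10% mismatch tolerance) are
  routed to a fallback: group by period, fold each read modulo its period
  (per-position majority), canonicalize, cluster by Hamming distance, then
  the same pileup polish. This recovers e.g. a 19 bp monomer exactly.
* **Iteration.** After each round, sampled reads matching any discovered
  consensus at ≥ 70% identity are filtered out and the remainder
  re-clustered, until a round adds nothing (or `max_rounds`). Families are
  then quantified on the male library (the sex sequenced for all species in
  the motivating design), ranked by descending male abundance and named
  `<Prefix>Sat<NN>-<RUL>`; the name's suffix always equals the consensus
  length, asserted on every catalog.
* **Grouping.** Single-linkage on rotation/strand-aware local identity over
  ≥ 50% of the shorter monomer: ≥ 95% variants, ≥ 80% families, ≥ 50%
  superfamilies. The thresholds follow the conventional nested tiers; they
  are configuration, not claims.

The cycle-mass criterion bounds discovery sensitivity: a family whose copies
have already diverged by more than ~1–2% spreads its k-mer mass over variant
branches and can drop below the 0.8 threshold. That is consistent with the
stage's job — discovering families via their (young, homogeneous) amplified
fraction — while the *quantify* stage, at 70% identity masking, captures the
divergent tail up to the landscape ceiling.

## Cross-species homology and distances

All-to-all cross-species consensus pairs are tested by best local alignment
over both strands. A link is called when (a) the score exceeds the maximum
over 100 composition-preserving shuffles of the shorter sequence, (b) the
alignment spans ≥ 30% of the shorter monomer, and (c) an absolute floor of
`min(25 bp, shorter monomer)` is met — (c) exists because 30% of a ~50 bp
monomer is a meaninglessly small alignment. A k-mer prescreen skips pairs
sharing no 12-mer; such pairs cannot realistically beat the null and skipping
them keeps the quadratic stage tractable. Pairs whose shorter monomer is
below four prescreen k-mer lengths bypass the prescreen entirely: two or
three substitutions can erase every 12-mer of a ~30 bp monomer, and aligning
such small pairs outright costs nothing. Homology groups are connected
components, so grouping is symmetric and transitive by construction; a family
in no multi-species group is lineage-specific.

Distances between a group's homologs use the most abundant member when a
species contributes several (the choice is otherwise under-determined; a
long-format table of all member pairs is also emitted by the runner). The
second consensus is phase-oriented (rotation/strand from a local anchor
against the dimerized sequence) before global alignment, because two
canonical rotations of diverged circular monomers need not be in phase.
`K` comes from the aligned `P`, `Q`; saturation yields a sentinel flagged in
tables. `CTR = K/(2T)` with `T` the species divergence time in My — `T` is an
*input* (as when taken from published timetrees), not something the package
infers. `K = 2 * T * ctr` holds to within one ulp by construction.

A deliberately documented discrepancy: a published peak-dating argument in
the motivating literature ("a 2% peak corresponds to ~8 My") is not
reproducible from any printed CTR by an obvious formula; `peak_age()`
reports the plain reading `age = divergence / ctr` and this paragraph is the
documentation of the mismatch rather than a fudge to match it.

## Shared segments

Two families may share a short ancestral segment without being homologous
over their lengths (e.g. two sex-chromosome-linked families sharing ~6% of
the shorter monomer at ~84% identity). `shared_segment` reports the best
local alignment between dimerized consensuses when it beats the shuffle null
while covering < 50% of the shorter monomer; overlap fraction and identity
are returned. Segment identity is a substitution-level statistic, so this
detector aligns with a stiffer gap penalty (−4) than read masking: at −2 a
local alignment will occasionally chain chance flank matches through indels
onto a short segment and dilute its identity by several points. Local
alignment optimizes score, not the planted boundary, so recovered identity
remains an estimate (the planted 84% case is recovered within ~3 points,
terminal-mismatch trimming being the residual error source).

# The synthetic world

`build_species_genomes` plants satellite arrays into i.i.d. uniform ACGT
background (no isochores — only the repeat/non-repeat contrast matters to
the pipeline). Arrays are perfect head-to-tail copies, each copy
independently mutated by its amplification event's age (`rate * t` expected
divergence — the landscape peak position); array length can be specified in
bp, in which case a trailing partial monomer is emitted, as in real arrays,
letting a family hit an exact genome proportion. Sex bias is a copy-number
difference only; the female genome is otherwise the same draw. Reads are
uniform fragments with Normal insert sizes, mate 2 reverse-complemented,
substitution-only errors (default 0.002/bp — K2P counts substitutions only,
and indel sequencing error is out of scope by design). Truth tables record
exact planted bp, proportions, coordinates and expected peak positions;
satellite bp + background bp equals genome length exactly.

Defaults that are free choices, documented once: fixture genome size 20 Mb
(real genome sizes for the motivating genus are unknown); substitution rate
0.005/site/My and `kappa = 2` (typical vertebrate-satellite ballpark);
insert 350 ± 35 bp; amplification ages of 0.5–1 My for "recent" planted
families (recent amplification is the regime the discovery stage targets).
What the generator does **not** emulate: positional coverage bias, GC bias,
quality-dependent errors, PCR duplicates, higher-order repeat structure,
or chromosome-scale organization. Green tests therefore establish
algorithmic recovery, not robustness to real-library artifacts.

# Numerical and engineering choices

* All randomness flows from one integer seed per entry point; stage seeds
  derive from the root seed plus labels via a stable polynomial hash, so a
  fixed config reruns byte-identically (`run_all` hashes its outputs).
  Chunked genome-scale quantification derives one seed per chunk, making the
  streaming estimator deterministic too.
* Alignment is exact dynamic programming in C++ (global / local / overlap
  modes share one implementation); no heuristic aligner is called, and tests
  check score equality against an independent alignment oracle.
* Shuffle nulls are score-only two-row DP; observed alignments get full
  traceback.
* Ties: heaviest-cycle walk breaks ties lexicographically; read assignment
  ties break by family rank; `table()`-based majority votes break ties
  alphabetically. All deterministic.
* Degenerate inputs: empty read sets, empty catalogs, satellite-free
  libraries, zero-variance landscape differences, saturated distances and
  monomers at the length extremes (19 bp, >4 kb) are all exercised in tests.
* Config files are JSON (no YAML parser in the supported dependency set);
  tables are UTF-8 TSV with `# ` unit comments; FASTA wraps at 60 columns;
  FASTQ is strict 4-line with constant Phred-33 qualities.

# Known limitations

* Discovery assumes the sampled coverage is low enough (~1×) that background
  read overlap stays below the cluster-size threshold; the runner's defaults
  arrange this, but a user pointing `iterate_satminer` at a deep sample will
  get one giant component (the classic failure mode of read-overlap
  clustering).
* Monomers with long internal duplications (a repeated ≥ 21-mer inside one
  monomer) can shortcut the de Bruijn cycle; the polish step does not recover
  from a wrong cycle length.
* The masker's divergence reach (~30%) is below the 41% landscape ceiling;
  deeply diverged relic variants are under-counted relative to a full
  Smith-Waterman masker.
* Homology calling on monomers much shorter than the prescreen k-mer
  (≈ 12 bp) relies on near-identity; truly ancient short homologs would be
  missed.
* `abundance` at genome scale trims boundary reads at array edges
  (score/span floors), a ≲ 1% relative downward bias at the fixture scales —
  well inside the 3-SE acceptance bands.
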