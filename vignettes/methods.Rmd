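---
title: "Measuring sequence convergence between therapeutic antibodies and natural repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sequence convergence between therapeutic antibodies and natural repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmine)
```

## The question

Next-generation sequencing (NGS) of B-cell receptor repertoires now yields
hundreds of millions of natural antibody sequences. How similar are the
antibodies developed as therapeutics to what the immune system produces on
its own? `abmine` implements the machinery needed to ask that question at
repertoire scale: a positional identity metric defined on the IMGT
numbering, length-matched CDR comparisons, best-match search over numbered
repertoires, classification of therapeutic antibodies by their
international nonproprietary names (INN), and threshold summarization. It
ships a transcription of the published table of best identities for 242
clinical-stage therapeutic (CST) antibodies, so the headline summary counts
are reproducible without any external download, and a seeded repertoire
simulator so every pipeline stage is testable end to end.

## The identity metric

All comparisons live in IMGT coordinates: a variable domain is an ordered
map from IMGT positions (1–128, with lettered insertions) to residues, and
the numbering *is* the alignment — no gapped alignment is ever computed. A
match is a position occupied in both chains with the same residue. With
$m$ matches, query occupancy $L_q$ and template occupancy $L_t$, the
full-chain identity is the symmetric average

$$\mathrm{ID} = \frac{1}{2}\left(\frac{m}{L_q} + \frac{m}{L_t}\right),$$

which penalises length discrepancy: if the query's positions are a strict
subset of the template's and all shared residues agree, the score is
$(1 + L_q/L_t)/2 < 1$, never a spurious 100%. "Length" here is the count
of occupied IMGT positions, not the raw sequence length — the match rule
is defined on positions, so the denominators must be too. The unknown
residue `X` is admitted on input and counts as a mismatch against
everything, including another `X`: identity means identity, and no
similarity matrix is involved.

Two further modes restrict the comparison to the hypervariable loops. The
*CDR-triplet* mode concatenates CDR1+CDR2+CDR3 of one chain and is defined
only when all three loop lengths match between query and template (a
length mismatch is reported as "not comparable", which is distinct from a
low score and from a no-match). The *CDR-H3* mode compares the heavy
chain's third loop alone under the same length gate; a value of 1 is a
perfect match. Under equal lengths the positional count reduces to a
character-wise count, and the package exploits that.

Scores are kept as exact rational fractions internally; display values are
integer percents rounded half-up (`percent_display`), with a $10^{-9}$
guard so that exact halves such as $39/40 = 97.5\%$ round up despite
binary floating point. Threshold predicates are evaluated on the raw
fractions when they are available (with a $10^{-12}$ tolerance so that
$114/120 \ge 0.95$ holds exactly) and on the displayed integers when the
input is already integer-valued, as in the shipped table.

## IMGT positions, insertions, and the junction

Positions order by number, and insertion letters sort ascending after the
bare position everywhere except 112, where they sort descending *before*
it, so a long CDR3 junction reads

```
105 ... 111, 111A, 111B, ..., 112B, 112A, 112, ... 117
```

`imgt_cdr3_positions(n)` implements the fill: loops of up to 13 residues
occupy 105–117 minus a central gap, longer loops insert at 111/112 with
the 112 side taking the extra position when the overhang is odd. A
property test checks that the generated labels are strictly increasing
under the package's comparator for every length. Because the ordering is
global and total, equal-length loops compare position-wise exactly as they
do character-wise — asserted as a test property rather than assumed.

CDR bounds default to the IMGT standard (CDR1 27–38, CDR2 56–65, CDR3
105–117) and are configurable through `region_scheme()` for sensitivity
analyses. Framework regions are the complementary ranges; every occupied
position belongs to exactly one region.

## Reading repertoires and filtering unproductive sequences

`read_oas_jsonl()` consumes the OAS-style layout: one study-metadata line,
then one JSON object per sequence whose region keys map IMGT position
labels to residues. The reader is streaming (chunked, with an optional
callback) so repertoires never need to be memory-resident; malformed lines
are counted and skipped rather than fatal, because repertoire files are
machine-generated and huge, whereas query inputs fail hard.

Numbering of raw query sequences is delegated to a pluggable numberer
(ANARCI in practice); the package does not reimplement the numbering HMM
and ships only a sequential stub for pre-aligned input.

The productivity filter applies explicit rules on ingest, each
toggleable, reporting the first failure: a stop codon anywhere; conserved
position 104 not cysteine; conserved position 118 not tryptophan or
phenylalanine; numbered coverage below 80% of the raw sequence. These are
a documented approximation of what numbering tools flag as unproductive —
the published analysis delegates that judgement to ANARCI without listing
criteria, so the rules here are explicit and tested instead.

## Search

`build_index()` partitions records by chain type, buckets them by the
three loop lengths and by CDR-H3 length, and hashes exact CDR-H3 strings.
The length buckets are a lossless prune: they exclude exactly the
templates that the length precondition already makes ineligible, which is
asserted against an unpruned scan. For the full-chain mode there is no
lossless cheap prune under this metric, so the indexed search computes the
exact match count for *every* template of the right chain type in one
vectorized pass: each chain is packed into integers coding
(position rank, residue), the repertoire's codes are flattened once, and a
query is scored with a single hashed membership test followed by a
per-record tally. This was chosen over a per-record early-exit loop
because it has the same exhaustive semantics with far less interpreter
overhead, and nothing to prove about a bound.

Ties on the best value are broken by earliest insertion order (file
order), which makes results reproducible without auxiliary keys; the tie
count is reported so the information that ties existed survives.
"No eligible template" is an explicit no-match result, never a silent 0%.

`exhaustive_best_match()` is the testing oracle: a plain scan through the
per-pair identity functions. The suite drives 200 planted queries against
a 5,000-record seeded repertoire in all three modes and requires identical
best values, retained template ids and tie counts from both routes, plus
exact recovery of planted templates at identity $(L-k)/L$.

## The synthetic repertoire

The simulator emulates what the analysis needs from OAS-style data and no
more. Each record is a random germline V scaffold (framework 1–3 plus
CDR1/CDR2), a CDR3 junction of length drawn from a configurable
distribution (default support 8–22, a discretised bell peaked at 15 for
heavy chains and 10 for light, roughly where natural loop-length
distributions sit), residues drawn from a configurable amino-acid table
(uniform by default, since no background distribution is asserted by the
analysis), and a J tail. Somatic-hypermutation-like noise is
Poisson-distributed point substitution (default mean 4 per sequence) and
sequencing error is per-residue Bernoulli substitution (default
$10^{-3}$); both are amino-acid level, because the entire analysis is —
codon realism would add nothing the tests could observe.

Two deliberate idealisations matter for interpreting test results. First,
substitutions spare the conserved 104/118 anchors: the generator models a
*productive* repertoire, and unproductive records enter only through
explicit injection (stop codon, broken 104, broken 118) at a configured
fraction — which is what makes the filter pass-rate calibrate exactly to
$1 - \texttt{unproductive\_fraction}$ under a binomial bound. Second, the
germline scaffolds are synthetic (random draws frozen as constants, five V
and three J per chain), not transcriptions of real IGHV/IGKV genes, and
records are clonally independent — no lineage structure, no paired chains,
no isotypes. Passing tests therefore demonstrate the correctness of the
metric, search and summarization machinery on data with the right
combinatorial shape; they say nothing about biological realism of any
particular repertoire.

Generation is fully deterministic given the config seed (the caller's RNG
stream is saved and restored), and a ground-truth log records each
record's germline choices, junction, substitutions and injected defects —
enough to replay every record from scratch, which a test does.

## Classification and summarization

INN suffix rules, applied case-insensitively as substring tests in
priority order: `xizumab`/`ximab` → chimeric, else `zumab` → humanized,
else `umab` → fully human; an explicit three-name mouse list (muromonab,
abagovomab, racotumomab — names that predate the modern suffix system)
overrides everything. On the shipped 242 names this yields 100 fully
human, 105 humanized, 34 chimeric and 3 mouse. Names matching no rule go
to an `unknown` stratum with a warning rather than aborting a batch.

`summary_report()` assembles the table-analogue (rows sorted by heavy
identity descending, then name), threshold counts (defaults 90, 95, 100,
with 100 evaluated as equality, plus the combined both-chains ≥ 95
predicate), per-type distributions (strata under 5 molecules flagged as
small samples — too few for a meaningful distribution), and, for live
runs, attribution of each retained best match to its source species and
study. A no-match fails every threshold predicate but remains in the
denominator. Printed percentages are one decimal, half-up; published
percentage strings are not reproduced digit-for-digit because the source
mixes truncation with rounding, and the counts are what carry information.

## Problem sizes and numerical choices

The shipped checks run at: 1,000 random pairs against a brute-force tally
oracle; 200 queries × 5,000 records × 3 modes for index/oracle
equivalence; 50,000 records for the CDR3 length-histogram calibration
(3σ multinomial bounds computed from exact standard errors) and the
filter pass-rate (binomial 3σ). These sizes give the statistical checks
real power while keeping a full run of the suite on one CPU comfortable.
Score equality between the indexed and exhaustive routes is tested as
exact floating-point equality, which holds because both compute the same
rational expression from the same integers; tolerances appear only where
decimal thresholds meet binary floats, as described above.

## Limitations

Repertoire-scale conclusions about real therapeutic antibodies require
the real inputs — the OAS download and the CST sequences — which this
package deliberately does not fetch; its shipped table covers the
published per-antibody summary values only. Paired heavy/light analysis
is out of scope (public repertoires overwhelmingly report unpaired
chains), as are nucleotide-level processing, alternative numbering
schemes, and any estimate of the probability of chance CDR-H3 matches.
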