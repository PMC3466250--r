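---
title: "Processing oligo-capped full-length cDNA libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing oligo-capped full-length cDNA libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocap)
```

## The problem

Oligo-capping replaces the 7-methylguanosine cap of intact mRNA with a known
RNA oligonucleotide before cDNA cloning.  Because only molecules that still
carried a cap can be ligated to the tag, the presence of the tag at the 5'
end of a clone is evidence that the clone spans the true transcription start
site; together with the poly(A) tail at the 3' end it identifies a
*full-length* cDNA.  A library built this way, sequenced from both ends of
each clone by Sanger chemistry, yields paired 5'/3' reads that must be
routed through a decision tree into full-length protein-coding cDNA,
full-length noncoding cDNA, truncated protein-coding ESTs, primer-walking
candidates and plain 5'/3'-ESTs.  This package implements that decision
tree end to end, together with a ground-truth library simulator that makes
every stage testable without any sequencing data or external database.

## Pipeline stages and their parameters

**Quality trimming.**  The per-base score is `q - 20` and the retained
interval is the maximal-sum contiguous window (Mott's criterion).  The
source protocol names only the PHRED threshold of 20; the windowed
formulation is the standard realisation of "trimming poor-quality bases"
and is checked in the tests against an exhaustive O(n²) best-window oracle.
Ties are resolved deterministically (earliest start, then longest window).

**Adapter and vector screening.**  Terminal approximate matches (at least
16 aligned bases, at most 10% mismatch columns) to any supplied vector
sequence are trimmed; reads covered more than 90% by vector are discarded
outright (`ALL_VECTOR`).  The constant head of the poly(T) primer is always
included in the screen, because reads regularly sequence through the
poly(A) tail into it.

**Cap-tag detection.**  The 30-base tag
(`AGCAUCGAGUCGGCCUUGUUGGCCUACUGG`, matched as DNA) is sought in the first
60 bases of a 5' read with up to 2 substitutions.  SfiI digestion during
directional cloning can leave only the tag's 3' remnant, so its terminal 7
bases (`CTACTGG`, at most 1 mismatch) are also accepted.  A 3' read that
spans the whole insert carries a tag remnant at the front of its sense
orientation; that remnant is recognised only when anchored at the very
first base (with a length-scaled mismatch budget), which keeps the false
trim rate of unrelated 3' reads around 10⁻⁴.

**Poly(A) detection and orientation.**  Raw 3' reads are antisense: they
begin with the poly(T)-primer head and a T-run.  Orientation is decided by
the primer head (≤2 mismatches) or, failing that, by finding a terminal
A-run on the reverse complement — the same tolerance as tail detection
itself, so one sequencing error at the run boundary cannot flip the
decision.  The tail is the maximal terminal run of at least 8 bases with
A-fraction ≥ 0.9 ending within 3 bases of the read end.  The operation is
idempotent on reads already in sense orientation.

**Length filter.**  Inserts shorter than 150 bases are discarded, measured
after removing the cap tag and primer head but keeping the poly(A) tail —
the tail is transcript sequence, the adapters are not.  The boundary is
inclusive: 150 is kept.

**Low-complexity filter.**  A DUST-style triplet score
(Σ c(c−1)/2 / (window − 3), windows of 64, threshold 2) flags repetitive
reads.  Runs of ten or more A's or T's are excised before scoring so that
genuine poly(A)/poly(T) stretches — which a tail-bearing read always has —
do not flag otherwise complex sequence; dinucleotide and other repeats
still score highly.  Interval masks from an external repeat masker are
honoured when they cover more than 90% of a read.

**Mitochondrial filter.**  Reads with a local alignment of at least 100
bases at ≥95% identity to either strand of the mitochondrial genome are
discarded.  A shared 12-mer seed gates the Smith–Waterman extension; by the
pigeonhole principle a qualifying alignment always contains an exact
12-mer, so the seed never loses a true hit.  This replaces a
database-dependent E-value rule with deterministic length/identity
thresholds.

Filters apply in a fixed order — quality, vector, length, low-complexity,
mitochondrial — and the first failure is the read's single recorded
disposition.

**Truncation triage.**  Before assembly, a read with a significant sense
protein hit (E < 10⁻⁷) is set aside as a truncated coding EST when the
evidence shows the transcript cannot be full length: a 5' read without a
cap, or one whose hit starts more than 20 residues into the subject while
the read is already coding near its start; a 3' read without a tail, or one
stopping more than 20 residues short of the subject's C-terminus while its
alignment runs to the read end.  The 20-residue margin formalises
"truncated", which the source protocol leaves undefined; it is configurable
(`margin_aa`).  Reads without hits are never triaged here — they proceed to
assembly, which is what lets noncoding clones through.

**Assembly.**  Each surviving clone's 5' and 3' reads are merged by overlap
dynamic programming (suffix of the 5' read against prefix of the 3' read;
match +1, mismatch −2, gap −3, linear).  The trailing end of the 5' read is
also ends-free, so a short insert whose 5' read sequences through the tail
into the primer still merges, with the read-through bases dropped.  A merge
is accepted when the overlap exceeds 50% of the *shorter* read (strict
inequality, mirroring the ">50% overlap" rule; the denominator is a
documented choice, as the original does not name one) at identity ≥ 0.95
(an added, configurable floor — the original relied on assembler defaults).
Consensus takes the higher-quality base at mismatches, the 5' base on ties.

**Full-length classification.**  Oligo-capped clones encode protein on the
sense strand, so: best hit described as "reverse transcriptase" → discarded
as a retroelement; any sense-frame hit with E < 10⁻⁷ → full-length coding;
antisense-only hits or none → full-length noncoding.

**Walking candidates.**  Unassembled clones whose 5' read hits within 20
residues of a protein's N-terminus and whose 3' read reaches within 20
residues of the same protein's C-terminus span the complete CDS and are
ranked by 5'-read length (ties by clone id); the top 800 ("top ~800" made
exact and deterministic) are selected for primer walking.  Ranking by
5'-read length rather than insert length is a documented choice; the
original states only that sequences were "sorted according to length".

**EST retention.**  Remaining reads of at least 300 bases become 5'- or
3'-ESTs; shorter ones are discarded (the boundary again inclusive).

**Clustering.**  Non-redundant sets use cd-hit-style greedy incremental
clustering: longest first (ties by identifier), each sequence joining the
first representative it matches.  Identity is matches over alignment
columns of a semi-global alignment of the shorter sequence against the
representative, end gaps on the longer free — a paraphrase of cd-hit's
"global identity".  Parameterisations: 99%/95% for unassembled read sets,
98%/90% for proteins, 98%/95% two-set for noncoding against coding (which
also removes noncoding sequences that are UTR fragments of coding
transcripts).  A k-mer count prefilter (8-mers nucleotide, 4-mers protein)
skips pairs that cannot reach the threshold; the bound is conservative
(each edit destroys at most k words, with a 1.5× slack on the edit term),
so the partition is provably identical with and without it — and a test
asserts exactly that.  Exact replication of cd-hit's word heuristics is a
non-goal.

**Polyadenylation signals.**  Fifteen hexamers are tried in a fixed
precedence order (canonical `AAUAAA` first, then `AUUAAA`, then the
alternative signals in their published usage order); for each, any
placement whose end lies between 5 and 30 bases (inclusive) upstream of the
tail start is legal, and the first hexamer with a legal placement wins —
precedence beats proximity.  Among placements of the winning hexamer the
one closest to the tail is reported.  Window endpoints being inclusive is a
documented reading of "between 5 bp and 30 bp upstream"; both bounds are
arguments.  Usage tables count per group with all transcripts in the
denominator and "not identifiable" as its own row, percentages to one
decimal.  Note one interaction with tail detection: because the tail is a
purity-tolerant *maximal* run, A-rich bases just upstream of the true tail
can be absorbed into it, shifting the detected tail start ahead of the
signal's legal window; on simulated transcripts this leaves roughly 10% of
signals unidentifiable — the same order as observed in real full-length
libraries, and the reason the "not identifiable" row exists at all.

**ORF prediction.**  The frame comes from the single best sense hit (lowest
E-value, then highest bit score, then subject id).  The CDS seeds at the
hit's query interval snapped to the codon grid, extends upstream
codon-by-codon to the *furthest* in-frame ATG not preceded in frame by a
stop (full-length clones should reach the true start; a nearest-ATG mode
would systematically shorten 5'UTR-proximal starts), and downstream to the
first in-frame stop.  If the upstream walk meets a stop before any ATG, the
CDS begins after that stop with `has_start_codon = FALSE`.  Codons
containing N translate to `X` and never count as start or stop; predicted
proteins never contain `*`.

**Gene-loss categories.**  Per-species homology presence is collapsed by OR
within the tetrapod and teleost groups; hits in one group but not the other
give `LOST_IN_TELEOSTS` / `LOST_IN_TETRAPODS`, both `SHARED`, neither
`ABSENT_IN_BONY_VERTEBRATES`.

## The simulator

`sim_config()` / `make_transcriptome()` / `simulate_library()` generate an
oligo-capped library with full ground truth.  What it emulates:

* mRNAs as 5'UTR + CDS + 3'UTR (or a random noncoding body, fraction 0.4 by
  default, reflecting the prominence of noncoding clones in short-insert
  full-length libraries), each ending with exactly one planted signal
  hexamer, a uniform 5–30 base gap, and a poly(A) tail of 15–40 bases;
* the signal composition defaults to the observed usage in non-redundant
  protein-coding transcripts, renormalised over the 15 identifiable rows
  (`default_signal_distribution()`); any composition can be supplied;
* 5'-truncation with probability 0.2: a truncated molecule loses a random
  prefix *and* its cap — modelling the dephosphorylation/decapping
  chemistry that makes cap presence informative in the first place;
* the cloned insert is cap tag + molecule + reverse complement of the
  poly(T)-primer head; inserts outside the 500–3,500 base size-selection
  window are dropped;
* Sanger reads of 550–750 bases: the 5' read is the insert prefix, the 3'
  read the reverse complement of the insert suffix (hence primer head +
  T-run at its start); qualities are Q40 with a Q10 tail over the last ~8%
  of each read, exercising the trimmer; substitution errors at 0.5% per
  base.  CDS lengths are uniform over 100–350 codons and UTRs over 20–150 /
  60–400 bases, giving inserts centred near 1 kb — a short-insert
  full-length library in which part of the clones merge directly and the
  rest follow the walking/EST branches, which is the regime the decision
  tree is built for.

Two deliberate simplifications matter for interpreting green tests.  The
error model is substitution-only (indels are rare in Sanger data and
substitutions keep truth coordinates exact, so evidence can be derived from
truth arithmetically); real chromatograms also contain indels, which the
overlap and alignment code handles but the truth bookkeeping does not.  And
the 5'UTR of every coding gene carries an in-frame stop immediately before
the start codon — an upstream-ORF-free UTR — so homology-guided extension
has a unique correct answer and protein recovery can be asserted exactly;
real 5'UTRs sometimes contain upstream ATGs, where the furthest-ATG rule
can overextend.  Evidence is emitted from the truth linkage
(`simulate_evidence()`), standing in for a protein-database search; decoy
reverse-transcriptase and antisense hits can be injected (`noise`) to
exercise the filters.  Passing tests therefore demonstrate the decision
logic, not robustness to indel error or database search artefacts.

`truth_clone_categories()` replays the same decision rules over noise-free
geometry (read spans, Q10 tails, cut points, CDS coordinates) to produce
each clone's *expected* terminal category; `simulate_and_run()` reports the
fraction of clones whose pipeline category matches it.  At the study
conditions (200 genes, truncation 0.2, error 0.005, seed 42) agreement is
~99%, with the residual misses caused by chance events the truth arithmetic
does not model (e.g. an AT-rich noncoding read tripping the DUST filter).

## Numerical choices and degenerate inputs

Alignment scoring is match +1 / mismatch −2 / gap −3 (linear) throughout,
shared by the merge, clustering and mitochondrial aligners and by the
Biostrings-based oracles in the tests; `N` never counts as a match.  All
internal coordinates are 0-based half-open on the forward strand; files use
1-based inclusive coordinates with minus-strand hits encoded as reversed
query coordinates, converted exactly once at the file boundary.  Empty
inputs yield empty outputs (never errors); an all-low-quality read trims to
the empty interval and falls to the length filter; clustering of an empty
set is an empty partition.  Determinism is end-to-end: fixed seeds make the
simulator byte-identical, sorting uses radix order on identifiers, all
tie-breaks are specified, and regenerated report bundles are
byte-identical.

## Problem sizes

The test suite and the acceptance script run the simulator at 40–200 genes
(5,000 for the signal-composition check, where only the transcriptome is
needed), 1,000-case oracle sweeps for trimming and signal scanning, 200
noisy pairs for the merge oracle and 100 sequences for the clustering
oracle — sizes at which the exhaustive oracles themselves remain exact and
fast, while every code path of the pipeline is exercised.

## Known limitations

Chimeric clones, internal priming and realistic quality profiles are not
simulated.  The low-complexity filter is a stand-in at the scale of a
single statistic and does not approach a repeat-library masker.  The
mitochondrial rule is deliberately database-free and therefore not
comparable to an E-value threshold numerically.  cd-hit's exact cluster
counts are not reproducible bit-for-bit (different word heuristics and
alignment bands); the clustering here is instead held to an all-pairs
alignment oracle.  GO/KEGG/InterPro annotation and ncRNA family assignment
require external databases and are out of scope.
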