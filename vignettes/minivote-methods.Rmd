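---
title: "Aligning reads with MinHash candidate selection and secure kmer voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning reads with MinHash candidate selection and secure kmer voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minivote)
```

## The problem

Read alignment is the first and most compute-hungry step of most sequencing
pipelines, and it is also the step institutions are most reluctant to move to
rented compute: raw reads identify people. minivote implements a two-phase
aligner designed for a *hybrid* setting — a trusted client plus an untrusted
worker ("the cloud") that is honest-but-curious: it runs the protocol
correctly but may try to infer the reads from whatever it is sent, including
by comparing against a reference genome it also has.

The design splits the work so that the part that must see sequences (phase 1,
candidate selection) stays on the client, and the part that dominates runtime
(phase 2, scoring each candidate) is transformed so the worker operates on
keyed hashes and coarse position bins only.

## Phase 1: MinHash candidate selection

Reads and reference windows are compared as *sets of canonical kmers* under
the Jaccard similarity $J(A,B) = |A \cap B| / |A \cup B|$. Each sequence is
summarized by a MinHash fingerprint: with $L$ universal hash functions
$h_i(x) = a_i x + b_i \bmod 2^{64}$ ($a_i$ odd), entry $i$ is
$f_i = \min_{s \in A} h_i(H(s))$ over the 64-bit-mixed kmer codes. Two sets
agree at entry $i$ with probability $J(A,B)$, so the fraction of equal
entries estimates $J$ with standard error $\sqrt{J(1-J)/L}$.

The reference index (MHG) stores every length-$W$ genome window in $T$ hash
tables. Table $t$ buckets windows by a multiply-shift hash of a fixed
$b$-dimensional projection of the fingerprint,
$h = \big(\sum_i A_i \, f_{P_t[i]} \bmod 2^{64}\big) \gg (64 - M)$,
so windows sharing at least the $b$ projected entries with a read collide
with it. Two engineering points matter at genome scale and are implemented
(and tested) here even though the package is typically run at desk scale:

* **Rolling fingerprints.** Consecutive windows share almost all kmers, so
  fingerprints are computed with a per-hash-function monotone queue, giving
  amortized $O(L)$ per window. The contract is strict: every streamed
  fingerprint must be *bit-identical* to the direct computation on that
  window's kmer set, and the test suite enforces it. The incremental
  structure is free — only the contract is fixed.
* **Contig compression.** Runs of consecutive windows that land in the same
  bucket are stored as a single `(start, length)` entry. Compression must be
  lossless: expanding all entries reproduces the per-window assignment
  exactly. On a random 100 kb genome with the default parameters this gives
  a ~33x size reduction.

Querying a read returns $T$ buckets of contigs; entries whose genomic
extents overlap or abut within $W$ bp (within one reference sequence) are
merged by an n-way heap merge into candidates, each counting `b_hits`, the
number of distinct tables that contained it. Candidates must reach
`b_min_hits` (default 2) and at least half of the best count seen for the
read. A read identical to a unique indexed window retrieves its own window
from all $T$ tables.

## Phase 2: kmer voting

For a read/candidate pair, every shared voting kmer (default $v = 20$ bp)
votes for the displacement $\varphi = p^C - p^R$ of its contig and read
positions. Indels split the correct votes over neighbouring displacements,
so votes are collected with a symmetric window sum of radius `n_conv`
(default 10): $\tilde V_j = \sum_{|i - j| \le n} V_i$. The best displacement
is the argmax; on a plateau of equal maxima the middle position (lower
median) is taken. Across all of a read's tasks — both orientations of the
read are tried, since kmers are canonical and fingerprints strand-blind —
the best score $r_1$ and the best score $r_2$ more than one read length away
give the mapping quality $q = \alpha (r_1 - r_2)/r_1$ (default
$\alpha = 60$, rounded and clamped). A read with a single locus of evidence
gets $q = \alpha$; a perfect repeat gets $q = 0$.

## The secure transform

The voting inputs are transformed on the client so the worker sees neither
sequence content nor repeat structure:

* **Keyed hashing, rekeyed per task.** A kmer's base hash is the first 64
  bits of SHA-1 over a 256-bit session secret $K$ concatenated with the kmer
  code; precomputing these once per run is what makes per-task rekeying
  cheap. Task $\tau$ ships $((h_K(s) \oplus k_1^\tau) \cdot k_2^\tau) \bmod
  2^{64}$ with fresh random $(k_1, k_2)$, $k_2$ odd so the map is a
  bijection. Matches survive within a task; equal kmers in different tasks
  become unrelated values (no global repeat structure, GRS).
* **Local repeat masking.** Within a read or contig, any repeated kmer is
  replaced by a random value, together with its neighbours: all kmers within
  $v - 1$ positions of a repeat occurrence are masked and every maximal
  masked run is extended to at least $v$ kmers, so the worker cannot infer a
  masked repeat from the pattern of matches around it (no local repeat
  structure, LRS). Kmers overlapping `N` are treated as masked.
* **Position binning.** Kmer positions are revealed only as membership in
  bins of $\beta$ consecutive positions (default 20), shuffled within bins.
  A match between read bin $[l^R, h^R)$ and contig bin $[l^C, h^C)$ votes
  for every displacement in $[l^C - h^R + 1,\ h^C - l^R)$ — exactly the
  displacements generated by all position pairs of the two bins. This caps
  positional resolution at $\pm\beta$, which is why evaluation uses a 20 bp
  tolerance.
* **Sampling.** Contig bins ship $s = \max(1, \lfloor n_{bin} \rho \rfloor)$
  kmers. A bin that cannot supply $s$ *unmasked* kmers is masked entirely
  (sending a partial bin would reveal which kmers were repeats); masked bins
  ship $s$ random values so every bin has the same payload shape. Reads are
  never sampled. Doubling $\rho$ from 0.5 to 1.0 doubles the contig payload.
* **Splitting and padding.** Contig length itself is a fingerprint, so
  contigs longer than `chunk_cap_mult * read length` (default 2x) are split
  into chunks of that cap, one task each, padded with random kmers to a
  uniform record count. Chunks overlap by one read length so every
  read-length window lies wholly inside some chunk — without the overlap a
  read straddling a cut would lose its alignment, and the package asserts
  splitting neutrality as a test.

What the worker receives is exactly the serialized task stream — a 40-byte
header plus 12 bytes per kmer record (hash value, bin id); masks and keys
are never serialized, and `align_reads()` routes every task through this
byte boundary so the separation holds by construction, not convention. The
observable no-leak properties are tested: unmasked values are unique within
each task list, every maximal masked run spans at least $v$ kmers, and
cross-task collisions over millions of values stay at the birthday bound for
uniform 64-bit values (in practice: zero).

In `mode = "vanilla"` the transform is switched off (fast non-cryptographic
hash, exact positions, no masking); this is the non-private baseline used
for concordance checks. Vanilla mode ignores `rho` and ships every contig
kmer; sampling is meaningful only together with binning and masking.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `W` | 150 | window length = read length (bp) |
| `k_mh` | 20 | MinHash kmer length (bp) |
| `v` | 20 | voting kmer length (bp) |
| `L` | 128 | fingerprint length |
| `T` | 78 | index hash tables |
| `b` | 2 | projection dimension |
| `M` | 18 | bucket-address bits (2^18 buckets/table) |
| `beta` | 20 | position-bin size (kmers) |
| `rho` | 1.0 | contig kmer sampling rate |
| `n_conv` | 10 | vote-collection radius |
| `b_min_hits` | 2 | minimum bucket hits per candidate |
| `alpha` | 60 | mapping-quality scale |
| `C_max` | 1000 | repetitive-kmer cutoff (genome-wide count) |

`L = 128, T = 78, b = 2, M = 18` is the published operating point for
150 bp reads; `beta` equals the kmer length and `n_conv = 10` matches the
published experiments. Values the method leaves open were fixed here as
package defaults: a fingerprint is *valid* when at least 80% of its window's
`W - k_mh + 1` kmers survive filtering (the underlying method reports
windows with "valid" fingerprints without defining validity); `C_max`
defaults to 1000 occurrences; the `b_best_hits` band keeps candidates with
at least half the best hit count; `alpha = 60` puts mapping qualities on the
familiar BWA-like scale; the `r2` exclusion distance is one read length;
buckets with more than 5000 entries are treated as repeat-region noise and
skipped. Each of these is a constructor argument of `mv_params()`.

Coordinates are 0-based half-open everywhere inside the package; SAM output
is 1-based.

## The simulator, and what passing tests do not show

`simulate_reads()` emulates the standard whole-genome-shotgun simulation
used to benchmark aligners: a uniform random genome, a mutated copy with
SNPs at rate 0.001 of which 15% are indels (length 1 plus a geometric
extension, continuation 0.3), reads drawn uniformly from both strands with
i.i.d. substitution errors, and truth positions mapped back through the
indel offsets to original coordinates. The package's accuracy claims are
made under these conditions at desk scale: a 100 kb random genome, 10,000
150 bp reads at 1% error. Under them, secure mode Q10-maps over 99% of
reads with under 1% error, and over 99% of Q10 positions agree with vanilla
mode within $\pm\beta$.

A uniform random genome has essentially no repeat structure beyond chance
20-mer collisions. Passing these tests therefore demonstrates the machinery
— losslessness, rolling equivalence, the secure transform's invariants,
voting correctness, strand handling, calibration of the estimator — but not
performance on a real genome, where segmental duplications, satellite
arrays and transposons stress `C_max`, the bucket cap, `b_min_hits` and the
$r_1/r_2$ separation in ways a random genome cannot. Mapping-quality values
on real genomes would be systematically lower and the candidate lists
longer. Base qualities are ignored (voting counts exact kmer matches), and
paired-end reads are out of scope.

## Numerical and degenerate-input choices

* 64-bit arithmetic (hash values, keys) lives entirely in compiled code; at
  the R boundary hash values travel as `(hi, lo)` 32-bit halves and kmer
  codes as exact-integer doubles, which restricts kmer lengths to 26 bp —
  comfortably above the 20 bp operating point.
* All randomness (hash families, projections, session and task keys, masks,
  shuffles, padding) derives from the single master seed via independent
  splitmix64 streams, so runs are reproducible end to end and index and
  aligner stay consistent via the shared seed.
* Empty inputs: an empty FASTQ aligns to a header-only SAM; a read whose
  fingerprint is invalid (e.g. N-rich) or that reaches no candidate is
  emitted unmapped rather than dropped.
* Ties: equal voting maxima resolve to the plateau's lower-median
  displacement; equal task scores resolve to the first task in deterministic
  candidate order (descending `b_hits`, then position, forward orientation
  first).
* Reads shorter than `W` are fingerprinted over their own kmer set with the
  80% validity rule applied to their own kmer count; candidate intervals are
  padded to the read length.

## Worked example

```{r example}
sim <- simulate_reads(genome_len = 20000, n_reads = 500, read_len = 150,
                      error_rate = 0.01, seed = 11)
p <- mv_params(W = 150, seed = 7)
idx <- build_index(sim$ref, p)
idx

al <- align_reads(sim$reads, idx, sim$ref, p)
evaluate_alignments(al, sim$truth)
bandwidth_report(al)
```

The one-line summary to read off: `pct_q10` is the fraction of reads the
aligner both places and trusts (mapq >= 10), and `err_q10` is how often that
trust is misplaced by more than 20 bp.

## Known limitations

Single-end reads only; no base-quality model; no CIGAR beyond a full-length
match (the voting estimate is a position, not an alignment path); phase 1
runs on the client by design, so fingerprinting is not outsourced; the
serialization boundary models the client/cloud split in-process — there is
no network transport or encryption-in-transit; and the secure transform
implements the stated protections with tested observable properties, which
is not a cryptographic proof of security.
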