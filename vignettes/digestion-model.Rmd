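---
title: "The protcleave digestion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The protcleave digestion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protcleave)
```

## Why simulate digestion

Bottom-up tandem mass spectrometry analyses proteins through their
enzymatic peptides, and the usable peptide mass window (roughly
600--5000 Da) is far below the size of most intact proteins. Which
protease -- or combination of proteases -- produces peptides in that window
depends entirely on the protein family at hand, and proteases are expensive
enough that trying combinations at the bench is wasteful. `protcleave`
predicts cleavage sites and simulates digestions *in silico*: it models
protease specificity as recursive sequence rules, lets users declare new
proteases in a small text grammar, and annotates every generated peptide
with its length, average molecular mass and isoelectric point (pI), the two
quantities that drive mass filtering and chromatographic fractionation.

The model is deliberately sequence-only. Solvent accessibility, pH,
temperature, protease concentration and exposure time all shape real
proteolysis; none of them is modelled here beyond a per-protease missed
cleavage probability. Post-translational modifications are excluded
throughout.

## The cleavage-rule model

Positions around a scissile bond are named in Schechter--Berger style:
`...P3-P2-P1 | P1'-P2'-P3'...`, with cleavage between P1 and P1'. A
protease is a list of *rule trees*. Each node carries

* a residue set (or a wildcard) at a signed offset from the anchor
  (offset 0 = the anchor residue, -1 one residue N-terminal, +1 one
  C-terminal),
* a cleave / do-not-cleave flag, and
* an ordered list of sub-rules refining it.

The root is anchored on the residue under scrutiny; the bond is after the
anchor for C-side cutters (`side = "after"`) and before it for N-side
cutters. Bonds falling at a sequence end are suppressed so no empty peptide
can arise.

### Decision semantics

For a candidate position, each root whose residue matches is resolved
recursively: a sub-rule *matches* when its offset falls inside the sequence
and the residue there belongs to its set (an out-of-bounds offset never
matches -- this is load-bearing for concurrent digestion, below). If no
sub-rule of a node matches, the node's own flag is the decision. If several
sub-branches match and disagree, the decision is their conjunction: a
blocking branch always wins. The enzyme cleaves if *any* of its roots
resolves to cleave.

Two design choices make this semantics reproduce published specificities
exactly:

1. **Blocking dominates.** Exceptions exist to stop cleavage; when an
   exception co-fires with a permissive sibling, the conservative reading
   is the documented one. Caspase-1 is the canonical case: its recognition
   rule needs aromatic/leucine P4 and H/A/T P2 context, yet an acidic or
   basic P1' must still veto the cut. Conjunction gives the veto priority
   regardless of how deep the matching context chain is.
2. **Shared context nodes.** When a rule's context chain is inserted, a
   chain node identical to an existing sibling (same residue set, offset
   and flag) is shared rather than duplicated. A rule that *re-enables*
   cleavage inside an exception's context therefore nests underneath that
   exception instead of fighting it as a sibling. Trypsin illustrates
   this: proline in P1' normally blocks cleavage after lysine, but a
   tryptophan in P2 overrides the block, so `w` sits below the shared
   `p`-in-P1' node and WKP cleaves while plain KP does not.

Context chains are ordered by increasing distance from the anchor, C-side
first on ties; the ordering only determines where chains can share nodes,
not what they decide.

## The protease grammar

A definition line lists parenthesized position systems with exactly one
comma marking the bond: hydroxylamine is `(n,)(g)`, bromelain
`(k or a or y,)`. `or` builds residue alternatives within one position and
is evaluated before the comma; `()` is a wildcard position (used by TEV,
`(e)()()(y)()(q,)(g or s)`); `(,x,)` abbreviates the pair `(,x)` and
`(x,)`. The bare form `n,g` is accepted only while every position is a
single residue -- any `or` requires full parenthesization, because
`ac, or d,` is genuinely ambiguous between "after c-or-d with a in P2" and
"after c (a in P2) or after d".

Definition files make the rule/exception distinction explicit, which the
expression syntax alone cannot:

```
NAME: my-protease
RULE: (e,)
EXCEPTION: (e)(e,)
```

Exceptions attach to every previously declared root matching their anchor
residue and side, so rules must precede their exceptions; an orphan
exception is a load-time error. An exception whose context contradicts a
rule's required context still attaches -- it simply never co-fires. The
engine supports arbitrarily nested refinements; the file format expresses
one level of exceptions, which covers every published definition we ship.

`format_enzyme()` prints any compiled enzyme back in grammar form, and
`equivalent()` checks two definitions for behavioral identity by exhaustive
enumeration over a small alphabet -- the package's own compact trypsin
(3 rules, 5 exceptions) and the fully expanded spelling (4 rules,
9 exceptions) are verified identical this way over all sequences of length
up to 6 on two 6-letter alphabets (111 972 sequences).

### The shipped catalog

Enzymes with fully specified public cleavage rules (trypsin,
staphylococcal peptidase I, hydroxylamine, sequencing-grade thrombin,
chymotrypsin high specificity, bromelain, a simplified pepsin,
enterokinase, TEV, Asp-N, Lys-C/N, Arg-C) form the oracle-tested core.
Further entries reproducing the ExPASy PeptideCutter tables
(caspases, proteinase K, thermolysin, neutrophil elastase, CNBr, NTCB and
others) are marked `provenance: external` in `inst/enzymes/external.txt`;
they are shipped for convenience and not covered by the hand-written
oracles. PeptideCutter's full pepsin, papain, ficin and low-specificity
chymotrypsin tables are deliberately omitted rather than approximated.

## Mass and isoelectric point

Peptide mass is the sum of average residue masses (ExPASy values, 22
residues including pyrrolysine and selenocysteine) plus the average mass of
one water molecule, 18.01528 Da, for the termini created by hydrolysis.
Masses are computed in full double precision and displayed to four
decimals. Digesting a parent into $k$ peptides therefore conserves mass up
to the $k-1$ added waters, which the tests assert to $10^{-6}$ Da.
Ambiguity codes (B, J, X, Z) are rejected with a located error rather than
silently skipped.

Net charge at a given pH follows the rearranged Henderson--Hasselbalch
equations: each positively ionizable group (N-terminus, H, K, R)
contributes $1/(1+10^{\mathrm{pH}-pK_a})$ and each negatively ionizable
group (C-terminus, C, D, E, Y) contributes $-1/(1+10^{pK_a-\mathrm{pH}})$.
The model is compositional, so mass, charge and pI are invariant under
residue permutation. Two pKa tables are built in: the peptide-calibrated
IPC values (default) and textbook values; terminal-proximity perturbation
of side-chain pKa values is intentionally not modelled.

The pI is the root of the monotone charge curve, found by binary search on
$[0, 14]$: evaluate the midpoint (first at pH 7), keep the half containing
the sign change, stop when the interval is narrower than 0.01 and return
its midpoint. Every peptide carries both termini, so a root always exists
strictly inside the interval for both tables. The search is cross-checked
against an independent 0.001-step grid search on 1000 random peptides; the
largest observed gap is well under the 0.01 accuracy target (glycine's
closed form $(pK_{a,\mathrm{C}} + pK_{a,\mathrm{N}})/2$ gives 5.97 for the
IPC table and 5.55 for the typical table).

## Digestion modes and missed cleavage

**Sequential** mode digests every intact record with every enzyme
independently -- N enzymes produce N separate result sets, exactly as if
the tool were run once per enzyme. Sites are always detected on the full
parent sequence; generating a peptide never truncates the context that
later sites may need (staphylococcal peptidase I's P2 blocker is the
classic example).

**Concurrent** mode simulates all enzymes digesting together for unlimited
time, as a fixpoint iteration over a FIFO worklist of fragments. For each
fragment the union of all enzymes' sites is computed *on the fragment*:
context beyond a fragment boundary is invisible, so cleavage by one enzyme
can expose a site of another. The worked miniature: an enzyme cleaving
before `p` unless `k` follows in P2' cannot touch `aapkaa`, but once Lys-N
splits it into `aap | kaa`, the `k` lies outside the first fragment and the
blocked site frees, giving `aa | p | kaa`. The same mechanism means a
*single* context-dependent enzyme may legitimately cut more in concurrent
mode than sequentially (fragmentation can remove a blocker); for
context-free enzymes the concurrent bonds equal the union of sequential
sites. With no missed cleavage every split strictly shortens fragments, so
termination is guaranteed; re-running the digestion on its own products
changes nothing (fixpoint).

**Missed cleavage** is a per-site Bernoulli event: each protease carries a
percentage $p$, and each detected site draws a uniform number in
$[0, 100)$, cleaving only if the draw is at least $p$. Aggressive,
specific proteases (trypsin in good conditions) warrant 0--1%; a
non-specific protease at low exposure may warrant 20%. At $p = 0$ no draws
are consumed, so deterministic digestions do not depend on RNG state. In
concurrent mode the draw happens per proposed site per fragment; a
fragment all of whose proposals fail becomes final, which keeps the
iteration terminating -- a rejected site can only be re-proposed on a new,
shorter fragment. This concurrent-plus-miscleavage behavior is a modelling
heuristic: the "infinite time" reading of concurrency is only exact at
$p = 0$.

Peptide records report the 1-based parent-coordinate position of the P1
residue of their C-terminal cleavage (`cleavage_position`), with 0 marking
the peptide that runs to the sequence end; concurrent-mode peptides are
reported sorted by start coordinate under the dash-joined enzyme name.

## Synthetic fixtures

`generate_fixtures()` builds random protein records with planted cleavage
motifs (`ng`, `wkp`, `lvprgs`, ...) and a manifest of where each motif
sits. The background alphabet excludes every letter used by any planted
motif, so the manifest is exhaustive by construction: no accidental motif
copy and no accidental extension of a planted motif can occur, and planted
counts equal expected site counts exactly. That is also the generator's
main unrealism -- real sequences contain rule residues everywhere, with
sites at rates set by composition. Passing fixture tests therefore
demonstrates engine correctness on known ground truth, not site-rate
realism on natural proteins; the catalog oracle tests (exhaustive
enumeration against prose-derived predicates) cover the engine's behavior
on arbitrary residue contexts.

## Numerical and testing choices

* pI binary search: accuracy 0.01 (interval width), first probe at pH 7;
  grid oracle step 0.001.
* Masses displayed to 4 decimals, pI to 2; all internal computation in
  full double precision.
* Missed-cleavage statistics are checked on a fixture with exactly 200
  sites at $p = 20\%$ over 10 000 seeded trials against
  Binomial(200, 0.8) (mean within 4 standard errors, spread within 20% of
  the binomial standard deviation).
* Grammar equivalence uses exhaustive enumeration up to length 6 over
  6-letter alphabets; per-enzyme oracle checks run up to length 5--6 over
  3--5-letter alphabets covering each enzyme's rule residues. These sizes
  keep the whole suite around half a minute while visiting every rule
  branch.
* The reference benchmark digests human Titin (UniProtKB A0A0A0MTS7,
  35 991 aa; per-enzyme peptide counts and a three-protease concurrent
  digestion). The sequence is not redistributed with the package --
  fetch it with `scripts/fetch_titin.R`, after which the benchmark test
  and the corresponding entries of `scripts/acceptance.R` activate.

## Known limitations

* Specificity is sequence-local; no structural accessibility, kinetics or
  concentration effects.
* Concurrent mode with nonzero miscleavage is heuristic (see above).
* External-provenance catalog entries mirror PeptideCutter's published
  tables and inherit any imprecision in them; only the core catalog is
  oracle-tested.
* FASTA/FASTQ input is parsed by Biostrings, which holds the sequence set
  in memory; records are then processed one at a time. For protein-sized
  inputs this is comfortably within ordinary memory budgets.
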