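---
title: "Discovering genome-maintenance domains by profile-HMM search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering genome-maintenance domains by profile-HMM search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmscout)
```

## The problem

Genome-maintenance (GM) proteins — the machinery of DNA repair, the DNA
damage response (DDR) and mitotic fidelity — are built from a limited set of
conserved domain families. Binding and adapter domains in particular diverge
quickly, so many family members are invisible to plain sequence search and
only emerge from profile-to-profile comparison, where both the query and the
target are summarised as profile hidden Markov models (HMMs). `gmscout`
implements such a discovery pipeline end to end: compile candidates from
ontology, interaction and co-expression evidence; mask regions that produce
spurious profile matches; build per-query profiles by iterative search;
score them against a family library; and accept only hits that validate
reciprocally. Because the real inputs are large, versioned databases, the
package pairs the pipeline with a synthetic-data module that generates every
input with complete ground truth at desk scale, which is what the test suite
and the acceptance script run on.

## Candidate compilation

Three independent streams feed the candidate list, each behind a tibble-in /
tibble-out interface.

**Ontology.** The universe is defined by four pooled GO terms — DNA repair
(GO:0006281), DNA damage response (GO:0006974), cytokinesis (GO:0000910) and
mitotic cell cycle (GO:0000278). Annotations are first propagated: a protein
directly annotated with any descendant of a term of interest gains the term
itself (`propagate_interest_terms()`; is_a edges only, a conservative
closure — part_of is deliberately not traversed). Propagation is applied to
all four terms by default (configurable): the compilation pools at term
level, and treating two of the four differently would make the candidate
set depend on which passage of the protocol one reads. Pooling across
species deduplicates by protein id within a species and keeps
species-qualified ids across species, since cross-species identity of gene
symbols is not something the input tables guarantee.

**Interactions.** From an integrated interaction table, the pipeline keeps
pairs where exactly one side carries GO:0006281 and the other carries
neither DDR term; the naive side is the candidate. Records must have
experimental evidence and at least two supporting publications (two separate
predicates, ANDed; the publication count is taken as supplied). Candidates
on the housekeeping or recurrent-contaminant lists are removed. The three
filters are pure row predicates, so the final set is order-invariant; the
fixed order (asymmetry → evidence → lists) exists to make the per-stage
attrition funnel reproducible.

**Co-expression.** Per tissue, modules are detected as connected components
of the |r| ≥ 0.6 Pearson-correlation graph with a minimum module size of 5.
The detector is pluggable because downstream steps only consume gene sets;
connected components are the simplest detector whose failure modes are fully
understood, and the planted-module benchmark measures it directly.
Within-module pairs recurring in at least two tissues (pair-level
recurrence, the literal reading of the protocol) then pass through the same
asymmetry and list filters; the evidence filter is vacuous here because
gene pairs carry no publication field. Zero-variance genes are dropped
before correlation (r undefined), and no normalisation is applied — the
expression matrix is taken as given, as upstream tooling owns that step.
Query-centred signatures (`rank_coexpressed()`) average r across tissues
arithmetically and break ties by gene id.

## Masking

Profile searches are easily fooled by coiled coils and compositionally
biased tracts, so only mask-free regions become queries.

*Coiled coils* are scored COILS-style: a position-specific propensity table
over the seven heptad positions (a–g), windowed geometric-mean scoring
maximised over the seven frames, residues inheriting the best covering
window, and a two-Gaussian posterior converting scores to probabilities.
The propensity table is a documented stand-in derived from the qualitative
residue statistics of solved coiled coils (hydrophobics L/I/V/M/A/F
dominate a/d; E/K/Q/R dominate the surface positions; proline excluded
everywhere). Early versions with a milder core/surface contrast let
compositional fluctuations of shuffled windows outscore a perfect heptad
repeat; the table was sharpened so that misplaced hydrophobics genuinely
cost, which restored the intended property (an ideal repeat beats all
shuffles of its own residues). The Gaussian score models
(coiled-coil: mean 0.68, sd 0.10; globular: mean −0.12, sd 0.17; prior
ratio 30 for globular) were estimated once from large simulated samples of
heptad tracts and background windows. A residue is masked at posterior
probability ≥ 0.5; every check on this component is relative (shuffle
oracles, planted-tract coverage, background mask rates), never tied to
absolute scores of the original published matrix.

*Low complexity* follows SEG conventions: windowed Shannon entropy
(window 12, threshold 2.2 bits), each residue taking the minimum entropy of
any covering window, adjacent masked residues merged. The full two-threshold
SEG extension is out of scope. Disordered regions have no dedicated
predictor here; the low-complexity mask is the documented approximation.

Searchable regions are the complement of the mask union, dropping fragments
shorter than 30 residues (logged). A fully masked query is reported as
skipped rather than searched.

## The profile-HMM engine

**Construction.** Alignment columns with gap fraction < 0.5 become match
states. Sequences receive Henikoff position-based weights, computed over the
match columns and deliberately *not* renormalised: two identical rows weigh
half each, so duplicated sequences count once — which gives the closed form
`e[1][A] = (1 + α·f_A)/(1 + α)` for two identical rows that the unit tests
pin down. Match emissions use background-proportional pseudocounts with
α = 1 by default; insert emissions equal the background; transitions come
from weighted state-path counts with add-one smoothing. Single-row
alignments use an equivalent closed-form constructor.

**Local architecture.** The search model begins uniformly over (match
state, sequence position) — probability 1/(n·T) — and exits uniformly over
the remaining match states, p_end(i) = 1/(n − i + 1). This keeps total path
probability at most 1, so a profile with background-equal emissions can
never score positive bits, while preserving the single-state closed form
(one match state emitting A with probability 1 scores exactly
log2(1/f_A) = 4.32 bits on sequence "A"). It is a deliberate simplification
of Plan7 — no flanking self-loop states — chosen for its testable closed
forms; the exhaustive path-enumeration oracle in the tests mirrors exactly
this architecture.

**Scoring.** The forward score (log2 odds against the i.i.d. background,
summed over all local alignments) is the search statistic; Viterbi supplies
the best alignment and hence all reported intervals. The forward recursion
runs in scaled probability space with lazy renormalisation (C++), which is
overflow-safe for sequences of 10,000+ residues without per-cell
transcendentals. The choice of forward over Viterbi for significance is
empirical and important: on this architecture the Viterbi null of i.i.d.
decoys is nearly discrete (best single-cell alignments at the free-exit
state dominate), which no continuous fit can calibrate, while the forward
null is smooth.

**Profile–profile comparison.** Two profiles are aligned locally over their
match columns with the co-emission log-odds column score
S(i,j) = log2 Σ_a e_q[i,a]·e_t[j,a]/f[a] and affine gaps (open 3 bits,
extend 0.3 bits). This keeps the column score that defines
profile-to-profile search while omitting the five-pair-state machinery and
secondary-structure terms of full HHsearch; the scorer sits behind a stable
interface so that upgrade is isolated. The score is symmetric under
symmetric gap costs (a tested property).

**E-values.** `calibrate_evd()` scores background decoys (i.i.d. residues,
lengths resampled from the target set) and fits a Gumbel by maximum
likelihood, censored to the upper tail (default fraction 0.3; 0.1 in the
calibration audit) because E-values live in the tail and the fit should be
accurate where it is used. E(s) = n_db · (1 − exp(−e^{−λ(s−μ)})), with n_db
the search database size, defaulting to the target count at search time.
One honest caveat, measured rather than assumed: the forward null is not
exactly Gumbel at these profile and sequence sizes — local decay rates
drift by roughly a third between the 5th and 0.1th percentile (the
pre-asymptotic crossover toward the universal 2^{−s} bound for proper
probabilistic models). A two-parameter fit therefore cannot be
simultaneously exact across three decades of E-values, and the strict
binomial-CI audit of calibration can fail at the deepest threshold for some
seeds even though the fit is the maximum-likelihood Gumbel. The end-to-end
error control of the pipeline does not depend on that last half-decade: the
reciprocal step re-tests every hit at a 30-fold stricter per-pair
probability (E ≤ 0.01 against a database of hundreds of query profiles).

## The search pipeline

Per query: mask; for each searchable region, build an MSA iteratively
(single-sequence profile, score the database, include hits at E ≤ 0.01,
realign included sequences to the master via their Viterbi trace, rebuild;
stop at 3 iterations or a fixpoint). Inclusion additionally requires the
alignment to cover ≥30% of the master — the role of hhblits' `-cov`
option: a hit admitted on a short strong segment enters the master-slave
alignment as a nearly empty row, and a handful of such rows measurably
washes out the profile (in one instrumented case from 78 bits against the
true family down to 7). Iteration only ever adds rows, so deeper iteration
refines, never truncates.

Forward search scores each region's profile against every library family.
Each library family is calibrated once per run against decoy
single-sequence profiles at query lengths — the database-side calibration
convention — so E(q, F) = n_families · P_F(S ≥ s). Reciprocal validation
seeds a profile from the matched family's alignment region and searches it
back against all query-region profiles: validated requires E ≤ 0.01, ≥50%
coverage of the forward query interval, and the query's best forward family
equal to the hit family. Because the reciprocal database is the full query
collection, a chance forward hit near E = 0.01 faces a much stricter
per-pair bar on the way back, which is what keeps the decoy false-positive
rate low.

Curation (`curate_and_retry()`) operationalises manual MSA inspection as a
deterministic pass: drop problem rows and thin columns, reduce to a
maximin-diverse 30 rows, remove master-gap columns, rebuild, re-search both
directions. The order differs deliberately from listing diversity first:
greedy maximin diversity *prefers* fragment rows (a fragment shares almost
no aligned columns with anything, so its maximum identity to the kept set
is near zero), and running it before the problem-row drop can empty the
alignment on poisoned inputs. Dropping problem rows first makes curation
provably recover clean candidates and rescue poisoned ones.

Descriptive outputs: percentage-identity distance trees (average-linkage on
d = 1 − identity over co-aligned columns; ultrametric by construction,
newick via `ape`) and global pairwise identity (Needleman–Wunsch under
BLOSUM62, gap open 10 / extend 0.5, identity excluding terminal-gap
overhangs).

## The synthetic worlds

`simulate_family()` draws an ancestor from a fixed background (uniform
0.05 by default — the same vector the scoring engine uses, which closes the
loop between simulation and scoring) and derives members by i.i.d. per-site
substitution with probability 1 − target identity, replacements drawn from
the background (so realised identity exceeds the target by the
back-substitution mass, about 3 points at identity 0.4), plus
geometric-length indels (mean 2, uniform placement). There is no rate
matrix, no site-rate heterogeneity and no tree-aware evolution: members are
independent draws around one ancestor. Two consequences matter for
interpreting results. First, member–member identity is roughly the square
of member–ancestor identity (≈20% at target 0.4) — the genuinely remote
regime. Second, real families have correlated substitution patterns and
conserved motifs that this model lacks, so passing benchmarks demonstrate
the machinery (calibration, recruitment, reciprocal logic), not performance
on real proteomes.

The benchmark world (`gm_benchmark_world()`) uses 8 families of 30 members
at target identity 0.4 with 100-residue domains; 5 members per family are
planted between 20-residue background linkers as positive queries, 200
background decoys of length 120 complete the query set, and the raw member
domains form the sequence database for MSA building. Sizes were chosen so a
20-seed benchmark runs in minutes on one CPU. Expression worlds plant
modules via a latent per-sample factor (x = √ρ·f + √(1−ρ)·ε), making the
expected within-module correlation exactly ρ; interaction tables carry
evidence types, publication counts and planted contaminant/housekeeping
records; GO worlds build a rooted DAG with the four terms of interest and
per-protein annotation modes (direct, child-only, unrelated). Every
generator is a pure function of its spec and seed.

## Numerical choices and edge cases

* Ties everywhere break lexicographically (hit sorting by E then target id;
  diversity filter by row order).
* Non-canonical residues (B, Z, X, U, O, J) emit the background and are
  logged, never fatal.
* Zero-variance genes, fully masked queries, empty alignments after
  curation, and pairs with no co-aligned columns are each handled with an
  explicit logged path (drop, skip, `rejected` status, distance 1).
* All 1-based inclusive coordinates internally; the BED writer converts to
  0-based half-open explicitly.
* Seeds are explicit arguments; `child_seed()` derives per-step streams and
  stays below 2^31.

## Known limitations

Beyond the synthetic-data simplifications above: the profile–profile scorer
omits HHsearch's pair-state HMM and secondary-structure term; pseudocounts
are single-component (no Dirichlet mixtures); the coiled-coil table is a
stand-in, so only relative properties are guaranteed; disorder masking is
approximated by compositional complexity; and the Gumbel calibration is
exact only to the extent the forward null is Gumbel (quantified above).
Structure-based validation of candidates is outside the package's scope.
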