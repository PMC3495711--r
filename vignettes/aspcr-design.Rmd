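---
title: "Rule-based allele-specific primer design: model, parameters and design choices"
author: "ASPrimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based allele-specific primer design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ASPrimer)
```

# The method

Allele-specific PCR discriminates the two alleles of a biallelic SNP with a
forward primer whose 3'-terminal base equals the target allele. Because a
lone terminal mismatch often still extends on the wrong allele, a second,
deliberate mismatch is introduced at the 2nd, 3rd or 4th base from the 3'
end (the terminal base is position 1). Substituting the base at one of
those three sites with any of the three alternatives gives nine candidate
primers per SNP; since the template base at a formerly matched position is
the complement of the original primer base, no substitution can recreate a
Watson-Crick pair, so all nine are true mismatches and the reachable
mismatch classes are always drawn from the eight non-complementary
pairings {AA, TT, CC, GG, CA, GA, TC, TG}.

ASPrimer chooses among the nine deterministically using empirical rule
tables: success rates ("polymorphism percent": the fraction of validated
primer pairs that amplified in only one line) of a large validated primer
panel, cross-classified two ways.

1. **Site by compressed SNP group.** The 12 ordered SNP types (written
   line-1 allele / line-2 allele; the forward primer targets line 2 and
   forms its terminal mismatch on line 1) collapse into four groups that
   share terminal-mismatch behaviour: transitions, the A/C-G/T
   transversions, {A/T, T/A} and {C/G, G/C}. `selectSite()` picks the site
   with the highest percentage in the group's column.
2. **Site by mismatch class.** Given the selected site and the primer's
   original base there, exactly three classes are reachable;
   `selectSubstitution()` picks the substitution whose class has the
   highest percentage in that site's row.

Ties (which the packaged tables never produce, but user tables can) break
toward the smaller site and then the alphabetically smaller substituted
base, so the composed rule `designRule()` is a pure function: one SNP, one
context, one table, one primer.

With the packaged tables the rule selects site 3 for transitions (30.7%),
A/C-G/T (37.4%) and A/T-T/A (45.9%), and site 2 for C/G-G/C (43.3%); at
site 3 the strongest class is CA (46.8%), reachable when the context base
is G (template C) or T (template A).

The terminal mismatch class itself is determined by the SNP type — it is
the unordered pair {complement(line-1 allele), line-2 allele} — and is
shipped with a qualitative destabilization-strength label (after the
mismatch-thermodynamics literature). The labels are informational only:
selection is driven purely by the empirical tables. We note the source
material is not internally consistent about them — the same table that
labels transition-derived terminal mismatches (TG/GT/AC/CA) "Strong" is
accompanied by discussion attributing the *low* efficiency of transition
SNPs to the *weak* destabilization of AC/GT mismatches. We carry the table
verbatim and take no side, since nothing downstream depends on it.

# Primer construction

`buildAsForward()` anchors the primer 3' end on the SNP (terminal base =
target allele), substitutes the rule-selected base, and extends the 5' end
from `primerLenMin` upward, returning the shortest length whose
nearest-neighbor Tm enters the configured window. `pickReverse()` scans
amplicon lengths from `ampMin` upward and reverse-primer lengths from
shortest upward, returning the first window strictly downstream of the SNP
whose Tm is in-window and within `tmDiffMax` of the forward Tm. Both scans
are deterministic, so identical input yields byte-identical output tables —
a property the tests assert. Every designed pair satisfies the
discriminating geometry: exactly one difference from the target-allele
template (the introduced mismatch at the chosen site) and exactly two from
the non-target template (terminus + introduced mismatch), verified with
`differencePositions()` for every pair in every test batch.

`screenUniqueness()` is a cheap repeat screen: it counts occurrences of the
primer's 3'-terminal k-mer (default k = 15) and of its reverse complement
in the reference and flags more than one hit. It is a k-mer multiplicity
check, not an alignment; genome-scale repeat annotation is out of scope.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `primerLenMin`/`primerLenMax` | 18 / 36 | nt | validated panel primers span 24–36 nt; 18 admits GC-rich contexts |
| `tmMin`/`tmMax` | 53 / 65 | °C | annealing in the validated protocol ran at 55–65 °C; 53 leaves margin below the lowest annealing temperature |
| `tmDiffMax` | 5 | °C | conventional pairing tolerance |
| `ampMin`/`ampMax` | 100 / 600 | bp | resolvable on 2.5% agarose; the validation amplicons were a few hundred bp |
| `targetAllele` | `"line2"` | — | the validated panel's forward primers were all specific for line 2; `"line1"` swaps allele roles (the SNP type reverses) |
| `uniquenessK` | 15 | nt | ~1 expected hit per 4^15 ≈ 10^9 bases of random sequence |
| `naMillimolar`, `primerConcMicromolar` | 50, 0.5 | mM, µM | standard PCR-like conditions for the Tm model |

The Tm engine is a documented substitute: the original workflow delegated
Tm optimization to an external web tool whose internal model is unstated.
We use the two-state nearest-neighbor model with the SantaLucia unified
parameter set, terminal initiation terms, the entropic salt correction
0.368·(N−1)·ln[Na+], and concentration term CT/4 (CT for
self-complementary primers). The test suite pins a 20-mer against an
independent nearest-neighbor implementation run with identical parameters,
at ±0.5 °C.

# The rule tables as data

Rule tables are data, not code: `defaultRuleTables()` loads the packaged
TSV counts, `readRuleTables()` accepts species-specific tables in the same
schema (site, key, numerator, denominator; margin rows keyed `ALL` are
optional), and `deriveRuleTables()` rebuilds a table from raw per-primer
outcome records.

One wrinkle is preserved deliberately. In the published site-by-group
counts the per-site cell numerators sum to 165, 222 and 158 for sites 2, 3
and 4, while the printed row margins are 139, 189 and 162; the per-group
column margins *are* consistent with the cells, yet the four column totals
sum to 545 while the printed grand total is 490 (which is the sum of the
printed row margins, and matches the site-by-class table's row sums almost
exactly). The published counts, in other words, cannot all be cell sums of
one underlying record set. We therefore treat printed margins as data:
tables loaded from count files keep any margin rows verbatim, while tables
derived from raw outcome records always compute margins by summation.
Percentages are reported at one decimal with half-up rounding, matching
the printed values.

Mismatch-class spelling is normalized internally: the same unordered class
appears in the source material in both letter orders (CT vs TC, AC vs CA),
so classes are stored unordered and displayed with the two-letter spelling
used in the class table (TC, GA, CA, TG for the hetero-pairs).

# The synthetic-data generator

`simulateReference()` draws i.i.d. bases at a requested GC content;
`simulateSnpPanel()` places SNPs uniformly with a minimum spacing (default
100 bp, the order of the one-SNP-per-360-bp genome-wide average of the
source cross), anchors the line-1 allele to the reference base, and draws
the ordered type from the packaged genome spectrum (56.7% transitions)
conditioned on compatibility with that base; `simulateOutcomes()` draws
independent Bernoulli outcomes at the packaged per-(site, class) rates.
All simulators require an explicit seed and restore the caller's RNG
state.

What the generator does *not* emulate: linkage between nearby SNPs,
sequencing error, local GC heterogeneity, repetitive sequence, and any
dependence of wet-lab primer success on sequence context beyond the
(site, class) cell. Passing the round-trip tests therefore shows that the
pipeline's bookkeeping (type → site → class → outcome aggregation) is
self-consistent at the published rates — not that those rates transfer to
a particular genome or chemistry.

The parameter-recovery test simulates 500 primers per (site, class) cell
and requires every recovered rate to fall inside its binomial interval.
The 24 per-cell intervals are Bonferroni-adjusted (per-cell level
1 − 0.05/24) so that the *joint* check has ~95% coverage; 24 unadjusted
95% intervals would reject the true rates with probability ≈ 0.7, which
would make the test uninformative.

# Degenerate inputs and numerical choices

* Ambiguity codes (N and other IUPAC letters) are rejected everywhere
  except reference FASTA reading (which admits N but will fail design at
  any locus whose primer footprint contains one): exact base identity at
  and near the 3' end is the whole point of the method.
* Site indexing counts from the 3' end with the terminal base = 1;
  candidate sites are exactly {2, 3, 4}. `differencePositions()` uses the
  same convention.
* Empty rule-table cells are legal in derived tables (sparse data) but any
  selection that needs an empty cell raises an `incompleteTable` error
  rather than guessing.
* No fallback is implemented when the best site's reachable classes all
  have low percentages: the rule is one argmax composition, full stop.
  A second-best fallback would need a cost model the data do not provide.
* Batch design never aborts: per-SNP failures become structured rows with
  reason codes (`flank`, `tm_unsatisfiable`, `amplicon_unsatisfiable`,
  `ref_mismatch`, ...).
* Coordinates are 0-based half-open internally and in BED, 1-based
  inclusive in user-facing tables and VCF.

# Problem sizes in the test suite

The suite exercises the full pipeline at desk scale: exhaustive checks
over all 12 SNP types and all 256 four-base contexts; design batches of
15–25 SNPs on 20–40 kb simulated references; a 10,000-SNP panel on a 3 Mb
reference for the spectrum check; and 12,000 simulated outcomes (500 per
cell) for parameter recovery. These sizes give the statistical assertions
comfortable power while keeping the default run fast.

# Known limitations

* The empirical tables are from one *Brassica oleracea* cross; rates in
  other taxa or chemistries may differ. The table-as-data design exists so
  users can substitute their own counts.
* Tm of *mismatched* duplexes is not modeled; the nearest-neighbor engine
  covers perfect duplexes only, and destabilization strengths are carried
  as labels, not thermodynamics.
* No primer-dimer/hairpin thermodynamics beyond the 3' k-mer uniqueness
  screen; no multiplexing, probe design or tetra-primer layouts.
* The reverse-primer scan prefers the smallest satisfying amplicon, which
  favors short products suited to agarose detection; users wanting size
  diversity across a marker panel should vary `ampMin`.
EOF
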