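# ASPrimer

Rule-based allele-specific PCR (AS-PCR) primer design for SNP genotyping.

## The problem

AS-PCR genotypes a biallelic SNP with a forward primer whose 3'-terminal
base matches one allele: extension should succeed only on the matching
template, so presence/absence of product on a gel reports the genotype. In
practice a single terminal mismatch often fails to block extension, and the
standard remedy is a second, *artificial* mismatch introduced within the
three bases next to the terminus. For any SNP there are nine possible
artificial mismatches — three sites (the 2nd, 3rd and 4th base from the 3'
end; the terminal base is position 1) times three alternative bases per
site — and primers designed with different choices differ widely in
allele-specificity.

ASPrimer selects the single best artificial mismatch deterministically from
empirical **rule tables**: polymorphism rates of 1,686 validated primer
pairs cross-classified by

* mismatch **site** × compressed SNP group — the 12 ordered SNP types
  `line1/line2` collapse into transitions {A/G, G/A, C/T, T/C},
  {A/C, C/A, G/T, T/G}, {A/T, T/A} and {C/G, G/C}; and
* mismatch **site** × mismatch **class** — the unordered template:primer
  pairing at the introduced position, one of the eight non-complementary
  classes {AA, TT, CC, GG, CA, GA, TC, TG}.

The rule is two nested argmaxes. For SNP type *t* with primer 3' context
*c* (bases at positions 1–4 from the 3' end):

    site*  = argmax_{s ∈ {2,3,4}}  P[ site = s | group(t) ]
    base*  = argmax_{b ≠ c_site*}  P[ class(complement(c_site*), b) | site* ]

Ties break toward the smaller site and the alphabetically smaller base, so
every SNP yields exactly one primer. With the packaged tables the selected
site is 3 for all groups except {C/G, G/C}, which prefers site 2
(43.3%); the strongest single cell is class CA at site 3 (46.8%), reached
when the context base at site 3 is G or T — for {A/T, T/A} SNPs this is the
overall best design (45.9% site rate).

Around the rule the package provides: forward-primer construction (target
allele terminal, shortest length whose nearest-neighbor Tm enters the
configured window), a deterministic reverse-primer/amplicon scan, a 3'
k-mer uniqueness screen, SNP spectrum and rule-table statistics with Wilson
intervals, auditing of annotated primer tables, a synthetic-data generator
(references, SNP panels with a realistic transition/transversion spectrum,
Bernoulli validation outcomes), FASTA/VCF/TSV/BED I/O and a CLI
(`inst/scripts/asprimer`).

## Worked example

```r
library(ASPrimer)

ref   <- simulateReference(20000, seed = 11)
panel <- simulateSnpPanel(ref, nSnps = 4, minSpacing = 2000,
                          buffer = 700, seed = 12)
panel
#>   contig position allele_line1 allele_line2 snp_type
#> 1   sim1     1971            C            T      C/T
#> 2   sim1     7141            G            A      G/A
#> 3   sim1     9244            C            A      C/A
#> 4   sim1    17796            G            A      G/A

designRule("T/A", "AGCA")   # context = last 4 primer bases, 5'->3'
#> RuleDecision: SNP T/A [AT_TA] -> site 3 (45.9%), G>A giving CA (46.8%)

pairs <- designPrimers(panel, ref)
pairs[[1]]
#> PrimerPair AS0001_sim1_1971 (sim1:1971, SNP C/T, site 3, class TG)
#>   F 5'-TCCAGTGTCGTCGATGTT-3' (Tm 53.7)
#>   R 5'-GATTCTGAGTGGAGTCTTGGC-3' (Tm 55.6)
#>   amplicon 100 bp [1953, 2053)
```

The `RuleDecision` line reads: a T/A SNP belongs to the {A/T, T/A} group,
whose best mismatch site is the 3rd base from the 3' end (45.9% of
validated primers with that placement were polymorphic); the context base
there is G, and replacing it with A forms a CA mismatch with the template
C, the best of the three reachable classes (46.8% vs 23.9% for CC and
32.1% for CT). Each designed forward primer differs from the target-allele
template at exactly the introduced site, and from the non-target template
at the terminus plus that site — the discriminating geometry.

From the shell:

```sh
Rscript inst/scripts/asprimer design --fasta ref.fa --snps panel.vcf \
    --out primers.tsv --bed amplicons.bed
Rscript inst/scripts/asprimer audit --out audit.tsv
```

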