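# splicehla

Allele-specific quantification of HLA exon utilization and transcript
isoforms from spliced long-read cDNA alignments.

## What this is for

The classical HLA genes are the most polymorphic loci in the human
genome, and their transcripts are alternatively spliced in an
allele-specific way. The motivating example is exon 5 of HLA-DQB1: an
intron-4 G>A substitution (rs28688207) immediately upstream of exon 5
destroys its splice acceptor, so A-carrying alleles always splice the
24-nt exon out, while G-acceptor alleles retain it in most — but not
all — transcripts. Nanopore-length cDNA reads span many exons at once,
so each splicing event can be phased to its allele of origin; short
reads cannot do this for genes this polymorphic.

`splicehla` takes spliced long-read alignments against donor-specific
genomic allele references and produces:

* **per-read exon calls** — each annotated exon is RETAINED, EXCLUDED,
  or UNASSESSED per read, with flanking-exon evidence required for
  EXCLUDED so that 5'/3' truncation is never mistaken for splicing;
* **allele-level exon utilization** — retention rates over assessable
  reads, with class-specific read thresholds (≥20 reads for class I
  alleles, ≥10 for class II);
* **full-length isoform quantification** — exon-presence patterns
  (e.g. `111101` = exon-5 skipping) counted over full-span reads;
* **coverage diagnostics** — breadth at depth thresholds, a binned
  gene-body profile, and a single 3'/5' coverage-bias ratio;
* **replicate concordance** — per-(allele, exon) retention-rate
  differences with 2%/4% tolerance summaries;
* a **seeded simulator** of spliced reads with known isoform mixtures,
  geometric 3'-biased truncation, cross-allele contamination, and a
  truth table, so the entire pipeline is testable end to end; and
* an optional wrapper around a minimap2-style **two-pass spliced
  alignment** (candidate selection against coding sequences, then
  realignment to the donor's genomic alleles with junction hints).

## The model in brief

Reads are reduced to their reference-coordinate aligned blocks
(0-based, half-open): CIGAR M/=/X/D extend a block, N splits it. For
read *r* and exon *e*, *e* is RETAINED if any block overlaps it by ≥1
base; EXCLUDED if it has no overlap **and** some exon 5' of it and some
exon 3' of it are retained; otherwise UNASSESSED. The allele-level
retention rate is

```
retention(e) = n_retained(e) / (n_retained(e) + n_excluded(e))
```

i.e. over assessable reads, so 3'-biased coverage does not masquerade
as loss of 5' exons (an all-reads denominator is available as an
option). Isoform proportions are pattern counts over full-span reads
(first and last exon retained), and the pattern-weighted inclusion of
each exon equals its full-span retention rate by construction — an
invariant the test suite checks exactly.

## Worked example

Simulate a DQB1 heterozygote in which the 05:03 allele (intact
acceptor) retains exon 5 in 72% of transcripts and the 05:01 allele
(lost acceptor) always skips it, with default 5'-truncation and 4%
cross-allele contamination, then quantify:

```r
library(splicehla)

cfg <- sim_config(seed = 7)
db  <- make_toy_db(cfg)
sim <- simulate_reads(cfg, db, out_dir = tempfile("ex_"))

bundle <- bundle_from_db(db, sample_id = "cDNA001")
reads  <- load_alignments(sim$sam, bundle)
calls  <- call_exons_all(reads, bundle)

usage <- aggregate_usage(calls, bundle, sample_id = "cDNA001")
subset(usage, exon_index == 5,
       c(allele, n_retained, n_excluded, n_unassessed,
         retention_rate, passes_threshold))
#>              allele n_retained n_excluded n_unassessed retention_rate
#> 5  DQB1*05:03:01:01         80         35           27     0.69565217
#> 11 DQB1*05:01:01:01          2        109           27     0.01801802
#>    passes_threshold
#> 5              TRUE
#> 11             TRUE

iso <- quantify_isoforms(select_full_span(calls), sample_id = "cDNA001")
iso[, c("allele", "pattern", "n_reads", "proportion")]
#>             allele pattern n_reads proportion
#> 1 DQB1*05:01:01:01  111101      64  1.0000000
#> 2 DQB1*05:03:01:01  111111      56  0.6829268
#> 3 DQB1*05:03:01:01  111101      26  0.3170732

prof <- compute_depth(Filter(function(r) r$allele == "DQB1*05:03:01:01",
                             reads), db[["DQB1*05:03:01:01"]])
sprintf("3' bias ratio: %.2f", three_prime_bias(prof))
#> [1] "3' bias ratio: 3.43"
```

At 140 reads per allele the 05:03 exon-5 retention estimate is 69.6%
(truth 72%), the exon-5-skipping isoform is at 31.7% of full-span
reads, the lost-acceptor allele shows a small apparent retention (1.8%)
driven entirely by the simulated cross-allele contamination, and
coverage is visibly 3'-biased (ratio 3.43) from the oligo(dT)-style
truncation model.

The same pipeline is available from the command line via
`inst/cli/splicehla` (`simulate`, `build-ref`, `align`, `run-all`,
`concordance` subcommands); `run-all` writes the usage/isoform/coverage
tables, a JSON summary, and a run log with input MD5 sums.

## Documentation

Function documentation lives as roxygen comments alongside the code in
`R/`. The methods vignette,
`vignettes/hla-isoform-quantification.Rmd`, describes the model, every
default parameter and its rationale, the simulator's scope, and the
package's deliberate resolutions of ambiguous definitions (retention
denominator, full-span reads, suffix tie-breaking, concordance units).
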