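# paircall

Read-pair concordant variant calling for short-insert PCR-amplicon
sequencing in which both reads of a pair completely overlap the amplicon
insert.

## The problem and who this is for

Highly multiplexed PCR enrichment can define library inserts shorter than
one sequencing read, so paired-end sequencing reads every insert position
twice — once per mate, from the same template molecule. For users of such
panels (germline mutation screening, gene-panel diagnostics), the dominant
false-positive source is sequencing-chemistry error. `paircall` filters it
at the source: a single nucleotide variant or small indel contributes
evidence only when it is observed with identical position and alleles in
**both** mates of a read-pair. Per site, two independent errors mirroring
each other have probability about (e/3)² for per-base error rate *e*, so
one-read-only signals are discarded outright. Primer-derived positions are
removed by *coordinates* (mapping position vs. the BED interval of the
insert), never by sequence matching, avoiding artifacts from
primer-synthesis errors.

For amplicon *a* with *N* assigned read-pairs, a variant carried
concordantly by *k* pairs is called when

    k >= absthresh   and   k / N >= proportionthresh     (both inclusive)

with an optional quality gate: every base supporting an SNV or insertion
must reach `qualthresh` in both mates. The reference sequence is recovered
from each read's CIGAR string and MD tag, so no reference FASTA is needed.
Calls are written in the 1-based inclusive chromosome/start/end/ref/alt
dialect accepted by common variant annotation tools, and a per-amplicon
read-pair coverage report flags regions needing further screening.

## Worked example

The package ships a synthetic data generator that builds complete studies
(reference, BED, sorted/indexed BAMs with MD tags) with known planted
variants:

```r
library(paircall)

planted <- data.frame(amplicon = c(1L, 2L), offset = c(40L, 70L),
                      kind = c("SNV", "DEL"), len = c(1L, 2L),
                      af = c(0.5, 1.0))   # a heterozygote and a homozygote
fx <- simulate_amplicon_run("demo", seed = 42, n_amplicons = 2,
                            pairs_per_amplicon = 20, planted = planted,
                            error_rate = 0.002, sample_names = "sampleX")

paircall_run(fx$files$regions, fx$files$bam, "demo/variant_calls.tsv",
             coverdir = "demo/coverage", qualthresh = 20)
```

`demo/variant_calls.tsv`:

```
chrom	start	end	ref	alt	sample	amplicon	pairs	pairs_total	proportion
chr1	96	96	C	G	sampleX	amplicon_01	9	20	0.4500
chr1	306	307	AC	-	sampleX	amplicon_02	20	20	1.0000
```

The heterozygous SNV was drawn by 9 of 20 read-pairs (proportion 0.45,
near the 0.5 expectation); the homozygous 2 bp deletion by all 20. The
injected 0.2% per-base errors produce no calls: none recur identically on
both mates. `demo/coverage/sampleX.coverage.tsv` lists every amplicon with
its assigned pair count:

```
amplicon	chrom	start	end	pairs
amplicon_01	chr1	55	195	20
amplicon_02	chr1	235	375	20
```

The same pipeline runs from the shell over real data — multiple BAMs
accumulate into one call file, one coverage file per sample:

```sh
exec/paircall --primers panel_primers.bed --log logfile.txt \
  --out variant_calls.tsv --proportionthresh 0.15 --absthresh 2 \
  --qualthresh 20 --coverdir coverage_dir \
  sampleX.bam sampleY.bam sampleZ.bam
```

BAMs must be coordinate-sorted, indexed, and carry MD tags (add them with
`samtools calmd` if absent).

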