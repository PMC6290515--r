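# flexscan

Screen the homologs of a query protein for **intrinsic structural
order**, to support rational expression-construct design.

Intrinsically disordered regions make recombinant proteins hard to
express, purify and crystallize — and disorder content varies widely
between orthologs of the same protein. `flexscan` finds homologs of a
query in a FASTA library, predicts per-residue intrinsic disorder for
every hit, and ranks them with a hybrid score so that hits which are both
*close* (low E-value) and *more ordered* (low disorder content) surface
at the top. A comparative trace-alignment module then shows which
disordered regions of the query its more ordered relatives do without —
candidates for truncation.

## The scores

For a protein of length *l* with per-residue disorder scores
*s<sub>r</sub>* ∈ [0, 1], the **intrinsic disorder score** is the
percentage of residues strictly above a threshold (default 0.5):

> IDS = 100 · #{r : s<sub>r</sub> > 0.5} / l

Homology strength enters through a hyperbolic transform of the search
E-value, sigmoidal in log₁₀ E and bounded in [0, 1]:

> t(E) = 1 − 0.99^((−log₁₀ E)²),  t(0) ≡ 1

and the **FLEX score** is their weighted average, with the priority
coefficient η ∈ [0, 1] (default 0.5) shifting the weight between
homology (η → 0) and structural order (η → 1):

> FLEX = (1 − η) · t(E) + η · (1 − IDS/100)

A hit whose FLEX score strictly exceeds the query's own is a *superior
homolog*: a plausible functional replacement with better expected
in-vitro behaviour.

The built-in homology search computes optimal local alignments (BLOSUM62,
affine gaps 11/1) with Karlin–Altschul E-values
(E = K·m·n·e^(−λS), λ = 0.267, K = 0.041); the disorder predictor is
pluggable — a windowed composition heuristic is built in, and per-residue
score files from a dedicated predictor (e.g. IUPred) can be injected via
`score_dir` / `read_score_file()`.

## Worked example

Generate a deterministic synthetic homolog family (a 400-residue,
35%-disordered ancestor plus five descendants) and screen the ancestor
against it:

```r
library(flexscan)

fam <- make_family(fixture_spec(seed = 5))
dir <- tempfile()
write_family(fam, dir)                               # FASTA + score files
write_fasta(fam$library[1, ], file.path(dir, "query.fasta"))

cfg <- run_config(query_path   = file.path(dir, "query.fasta"),
                  library_path = file.path(dir, "family.fasta"),
                  output_dir   = file.path(dir, "out"),
                  eta = 0.5, sort_key = "flex", score_dir = dir)
res <- run_scan(cfg)
```

`out/results.tsv` then contains:

```
identifier  gene_id  species            identity_pct  similarity_pct  evalue     ids_pct  flex
DES0001     fam1     Synthetic taxon 2  93.8          95.3            6.27E-228  34.913   0.8254
DES0004     fam1     Synthetic taxon 5  95.0          95.8            3.21E-232  34.913   0.8254
ANC0001     fam1     Synthetic taxon 1  100.0         100.0           0          35.000   0.8250
DES0003     fam1     Synthetic taxon 4  95.8          97.5            1.14E-237  35.000   0.8250
DES0002     fam1     Synthetic taxon 3  96.2          96.5            1.65E-236  35.088   0.8246
DES0005     fam1     Synthetic taxon 6  95.8          96.2            1.14E-229  35.354   0.8232
```

Reading the table: the query's own entry (`ANC0001`) carries E-value 0 by
the self-hit convention, so its FLEX is (1−η) + η·(1−IDS/100) = 0.8250.
Two descendants happen to be slightly *more* ordered than the ancestor
(IDS 34.913 vs 35.000) and edge above it in FLEX — the superior homologs
a real screen is looking for:

```r
q <- res$table[res$table$evalue == 0, ]
screen_summary(q$flex, q$ids_pct, res$table[res$table$evalue > 0, ])
#> $n_superior
#> [1] 2
#> $ids_improvements
#> [1] 0.08771930 0.08771930
```

And the published-style single-hit check — an IDS of 3.703% at E-value
1.54e-28 under a 10% priority coefficient:

```r
flex_score(3.703, 1.54e-28, flex_params(0.10))
#> [1] 0.9959186
```

For disorder-trace comparison of selected hits
(`run_compare(cfg, c("ANC0001", "DES0001", "DES0002"))` writes an aligned
FASTA, the trace matrix with gaps scored 0.0, and a segment report
flagging query disorder that homologs lack), see the methods vignette in
`vignettes/`.

A thin command-line front end with `scan`, `compare` and `fixtures`
subcommands is installed at `inst/cli/flexscan.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","flexscan.R",package="flexscan"))')" \
    scan --query query.fasta --db library.fasta --out results/ \
    --evalue-threshold 1e-10 --max-hits 100 --flex-coefficient 0.5
```

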