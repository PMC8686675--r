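# diadetect

Library-free peptide detection in data-independent acquisition (DIA)
tandem mass spectrometry, using only a protein sequence database.

## The problem

DIA instruments cycle through fixed wide isolation windows (e.g. 25 m/z)
and co-fragment every precursor in each window, so a single MS2 spectrum
mixes fragments of many peptides and the classic one-peptide-per-spectrum
database search breaks down. Spectral-library methods sidestep this but
require an expensive, lab-specific library. `diadetect` searches the raw
DIA run directly against a FASTA database: it is aimed at proteomics
analysts who have a centroided mzML run and a proteome FASTA, and want
peptide detections with defensible false-discovery-rate estimates —
including peptides whose precursor is invisible in the MS1 survey scans.

## The method

The run and the database are connected by a bipartite graph G = (U, V, E):
U are the MS2 spectra, V the charged peptides (charges 1–5, tryptic digest
with up to 2 missed cleavages, carbamidomethyl-C fixed, up to 3 oxidized
methionines), and an edge (u, v) exists when the precursor m/z of v falls
inside the isolation window of u. Edges are scored with the SEQUEST XCorr
(fast cross-correlation formulation) and only the top k = 5 per spectrum
and charge are kept. Each edge then receives complementary evidence
features:

- **w^T** — XCorr calibrated by the spectrum-specific 99th-percentile
  candidate score (Tailor calibration), plus the Tide-style charge,
  delta_cn and delta_lcn features;
- **w^P** — negative sum of log intensity ranks of the precursor's M,
  M+1 and M+2 isotopes in the survey scan (missing signal is a finite
  penalty, not a veto);
- **w^F** — fragment-matching P-value: −log of the binomial tail
  probability of matching at least the observed number of fragments by
  chance, with the chance probability taken as the interval-union
  coverage of the picked peaks (10 segments × 10 peaks);
- **w^R** — negative absolute difference of normalized observed and
  predicted retention-time ranks (hydrophobicity-sum predictor by
  default, pluggable TSV-backed predictor; fallback −0.5);
- **w^E** — precursor/fragment coelution: mean of the top 3 normalized
  dot products between the precursor's MS1 elution profile and each
  fragment's same-window MS2 profile over ±2 scan cycles.

Features are rescaled so their 1st/99th quantiles map to [0, 1], summed
as w = w^T + α^P w^P + α^F w^F + α^R w^R + α^E w^E, and edges scoring
below the top-XCorr edge of their spectrum-charge group are discarded.
Surviving edges are re-ranked by a semi-supervised linear max-margin
model (Percolator protocol: 3-fold cross-validation with target/decoy
pairs kept fold-atomic, iterative positive-set refinement against decoy
negatives). Finally each target/decoy pair keeps only its best edge
(precursor-level target-decoy competition) and q-values are computed as
FDR(τ) = min(1, #decoys > τ / max(1, #targets > τ)), monotonized.

## Worked example

Everything below is generated in code — no downloads. Simulate a small
wide-window run with known ground truth, then detect:

```r
library(diadetect)
cfg <- sim_config(n_proteins = 6, n_cycles = 16, n_windows = 10, seed = 21)
sim <- simulate_run(simulate_fasta(cfg), cfg)
sim$run
#> DIA run: 176 spectra, 16 cycles, 10 isolation windows
nrow(sim$peptides); nrow(sim$truth)
#> [1] 856   # database peptides
#> [1] 57    # truly present

det <- detect_peptides(sim$run, peptides = sim$peptides, seed = 21)
det
#> DIA detection: 216 pairs competed; 44 targets at q <= 0.01

hits <- subset(det$results, !is_decoy & q_value <= 0.01)
head(hits[, c("sequence", "charge", "mz", "scan", "tailor", "wE",
              "score", "q_value")], 5)
#>             sequence charge    mz    scan tailor wE  score q_value
#> 1   LETYGWIPPCVITDLK      3 635.7 c15_w10      1  1 0.9983       0
#> 2 NPSPGNLTEGSQVSFALK      3 616.0  c12_w9      1  1 0.9981       0
#> 3    TFIATVMPTHKGNSR      3 554.0  c11_w7      1  1 0.9980       0
#> 4      NNKETTHQTAPMK      3 500.6   c0_w5      1  1 0.9939       0
#> 5    TPDCFKYTCHGEIPR      3 627.6  c8_w10      1  1 0.9848       0
```

Each row is the winning match of one target/decoy pair: `tailor` is the
calibrated XCorr (1.0 = at the 99th-percentile candidate score), `wE` the
coelution score (1.0 = fragment chromatograms perfectly co-shaped with
the precursor's), `score` the reranker's rank-normalized output, and
`q_value` the minimal FDR at which the peptide is accepted. Of the 44
accepted targets, 40 are planted ground-truth peptides and the rest are
missed-cleavage relatives sharing their fragment ions.

For a real run:

```r
run <- read_dia_run("run.mzML")
det <- detect_peptides(run, fasta = "proteome.fasta",
                       config = dia_config(fragment_tol_ppm = 30,
                                           noise_reduction = TRUE))
write_results(det$results, "detections.tsv")
```

or from a shell, `Rscript inst/scripts/diadetect-search.R --mzml run.mzML
--fasta proteome.fasta --out detections.tsv`.

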