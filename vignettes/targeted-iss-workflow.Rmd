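---
title: "Targeted in situ sequencing with insituseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted in situ sequencing with insituseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insituseq)
```

# The assay in brief

Targeted in situ sequencing (ISS) detects hundreds of mRNA species directly
in tissue. A chimeric padlock probe hybridizes to its target mRNA with two
15-nt arms that meet head-to-tail; a ligase seals the junction only when
both arms match, and rolling circle amplification (RCA) turns the
circularized probe into a ~1 µm DNA ball (rolling circle product, RCP)
carrying hundreds of concatemer copies of a gene-specific barcode. Each RCP
is then read out over `N` imaging cycles: in every cycle it lights up in
one of `x` fluorescence channels, as dictated by the gene's barcode, so the
number of resolvable genes scales as `x^N` (256 genes for four dyes over
four cycles). `insituseq` implements the complete dry-lab side of this
assay — probe design, codebook management, image preprocessing, decoding
and cell-level quantification — plus a physics-based simulator that makes
every stage testable without a microscope.

# Probe design

Given a transcriptome grouped by gene, the design cascade per gene is:

1. **Candidate slicing.** All overlapping 30-mers (positions 1–30, 2–31, …)
   of the representative isoform that are also exact substrings of every
   other isoform, so one probe covers all described isoforms. Multiple
   sequence alignment is a common way to find such shared regions; we
   instead intersect exact 30-mer sets across isoforms. For the purpose of
   finding probe windows shared verbatim by all isoforms the two are
   equivalent, and the set intersection is deterministic and
   dependency-free. The longest isoform is the representative and all
   coordinates refer to it (0-based internally; the junction rule below is
   stated 1-based, as probe designers write it).
2. **GC filter.** Only candidates with GC fraction in [0.40, 0.60]
   (inclusive) are kept. The bounds are tunable; the default window centers
   both arms in a workable hybridization regime.
3. **Ligation junction.** The base at position 16 — the target base
   flanking the nick where the two arms are ligated — must be C or G;
   the RNA ligase joins ends efficiently only on a C/G junction.
4. **Specificity screen.** Every candidate is scanned against the sense
   strand of the whole transcriptome; windows within 6 substitutions
   (Hamming distance) are reported as hits, and one hit in any other gene
   discards the candidate. Six mismatches is deliberately conservative:
   the ligase tolerates some mismatches, so near-matches are potential
   off-targets. Matching is substitution-only by default; an edit-distance
   mode (`with_indels = TRUE`) is available for users who want indels to
   count toward the budget, but the default keeps the screen identical to
   an exhaustive Hamming scan, which the test suite verifies against an
   independent brute-force implementation.
5. **Target selection.** Up to `n = 5` non-overlapping targets are chosen,
   spread across the transcript: the candidate span is cut into `n` equal
   bins, one candidate is drawn at random per bin, overlaps are resolved
   greedily left-to-right, and remaining slots are topped up in seeded
   random order. The draw is deterministic for a seed and invariant to
   candidate ordering (candidates are sorted internally), so a panel can
   be regenerated exactly.
6. **Assembly.** The 3′ arm is the reverse complement of target nt 1–15,
   the 5′ arm of nt 16–30; backbone and barcode-anchor sequences are
   filled into a configurable template
   (`{arm5}{backbone5}{barcode}{backbone3}{arm3}`, backbones empty by
   default since they are panel-specific). All probes of a gene share the
   gene's barcode.

**Cross-species panels.** For deliberately cross-reactive probes,
`cross_species_filter()` keeps candidates that have at least one window
within a Hamming budget in the ortholog of *every* required species and
records the best per-species distance. Published descriptions of this
filter use both "fewer than six differences" and "a tolerance of six
mismatches"; since the two differ by one, the threshold is an explicit
parameter (default 5, the stricter reading) rather than a hard-coded
constant. Conversely `classify_cross_reactivity()` asks how an existing
panel behaves on another species' transcriptome and buckets each probe by
the number of distinct genes hit: exactly one (*cross-reactive and
specific*), more than one (*cross-reactive but non-specific*), or none
(*non-cross-reactive*).

# Codebooks

A codebook maps each gene to a barcode: one channel index per cycle.
`build_codebook()` draws distinct barcodes from the full `x^N` space in
seeded random order after sorting the gene list, so the assignment depends
only on the gene set and seed. An optional minimum pairwise Hamming
distance buys error tolerance at the cost of capacity; note the Singleton
bound `x^(N - d + 1)` — with four channels and two cycles only four
barcodes can be pairwise at distance ≥ 2, so spacing is practical only
with more cycles. Decoding matches color sequences *exactly* (no
nearest-barcode rescue); unmatched reads are labeled `NO_MATCH` and kept
for auditing. Codebooks serialize to JSON with sorted keys (byte-stable),
and a CSV convention (one color letter per cycle) is accepted for
interchange.

# The simulator

`simulate_dataset()` generates the data the imaging stages consume,
with per-spot ground truth:

- **Spots.** Each RCP is an isotropic Gaussian of `psf_sigma = 1.5` px
  (a ~1 µm amplicon at the 3–4 px/µm sampling of a 20× sCMOS setup), peak
  `spot_amplitude = 500` counts above a flat `background_level = 100`,
  bright in the barcode channel of each cycle with a `crosstalk = 0.05`
  fraction leaking into the other detection channels. Spot centers are
  uniform with a minimum separation of `2 * psf_sigma` (optical crowding
  is out of scope; `dense = TRUE` disables the rejection).
- **Geometry.** Tiles of 512×512 px on a 2×2 grid with 10% edge overlap;
  the mosaic spans `tile + (n-1) * (tile - round(0.1 * tile))` = 973 px
  per axis. Values are quantized to 16-bit unsigned, matching common
  camera output.
- **Cycles and z.** A global per-cycle `(dy, dx)` shift emulates stage
  repositioning between cycles. Each tile is a `z_planes = 3` stack with
  signal modulated by a Gaussian defocus profile, in focus at the middle
  plane, so maximum projection recovers the in-focus image.
- **Nuclei.** A DAPI-like extra channel contains filled disks
  (`nuclei_count = 40`, radius 15 px), present identically in every cycle —
  which is exactly why it serves as the registration channel.
- **Noise.** Additive Gaussian read noise (`noise_sd = 10` counts) per
  plane. Everything is a deterministic function of the seed.

The defaults define the reference conditions of the test suite: a 9-gene
panel over 4 channels × 2 cycles with 1000 spots in the 973² mosaic. What
the simulator does **not** emulate: optical aberrations, photobleaching,
within-cycle stage jitter, structured autofluorescence, tissue background,
and densely packed or overlapping amplicons. Passing tests therefore
demonstrate the correctness of the algorithms under the stated image
model, not performance on difficult tissue.

# Preprocessing

1. **Maximum z-projection** per tile and channel.
2. **Stitching.** Tiles are placed at their metadata grid positions;
   overlap strips are resolved deterministically — the tile with the lower
   (row, col) index wins, with no feathering, so stitching tiles cut from
   a known mosaic reproduces that mosaic pixel-exactly. With
   `refine = TRUE` each tile's position is first corrected by phase
   correlation against its left/top neighbor on the nominal overlap strip
   (search bounded by `max_refine = 5` px), recovering small stage errors.
3. **Cross-cycle registration.** One rigid translation per cycle (no
   rotation/affine — an epifluorescence stage translates), estimated by
   phase correlation on the nuclei channel. The nuclei stain is used
   because it is present in every cycle and independent of the coding
   signal. Subpixel precision comes from a local matrix-multiply DFT
   upsampling of the correlation peak (`upsample = 10` by default); images
   are shifted by the rounded estimate and the fractional estimate is
   reported. A flat registration image yields a zero shift with a warning
   rather than an error.
4. **Reslicing.** The aligned mosaic is cut into uniform non-overlapping
   tiles for memory-bounded decoding; the last row/column is zero-padded
   so decoders see constant shapes, and the index maps tile-local to
   global coordinates exactly.

Coordinates are row-major `(y, x)` 0-based internally; outward-facing
tables use `x, y` column order.

# Decoding and the quality score

**Normalization.** Each (cycle, channel) plane has its per-plane median
subtracted (the flat camera background) and is divided by the distance
from that baseline to the 99.9th percentile. The scale is pooled per
channel *across cycles* by default: gain is a property of the dye and
detector, not of the cycle, and a channel that happens to carry few
bright amplicons in one cycle would otherwise have its noise floor
amplified to signal level — flooding detection with false positives and
dragging genuine reads' quality scores toward the random floor. Fully
independent per-plane scaling is available (`per = "plane"`). Either way
the output is scale-invariant and equalizes channel gains.

**Spot detection** runs on a reference image: the per-pixel maximum over
all cycles and detection channels (every amplicon is bright somewhere in
every cycle, so it is bright in the reference; no separate anchor round
exists in this chemistry). A scale-normalized Laplacian-of-Gaussian
response over a small sigma ladder (1–3 px) is thresholded and local
maxima closer than 3 px are merged. Gaussian smoothing uses replicated
borders; circular boundary conditions would wrap content and create
spurious edge detections.

**Color calling.** Per cycle, the prominent (maximum) channel is the
called color. Its intensity is the *true signal*, the sum of the other
channels the *background*, and the per-cycle quality is
`signal / (signal + background)` — equivalently the prominent channel's
share of the total. It is 1 for perfect decoding and `1/x` when all `x`
channels are equal (0.25 in four colors), the random-assignment floor;
this is the only reading of signal/(signal+background) consistent with
that floor. Ties in the argmax break toward the lowest channel index and
flag the read; an all-zero cycle scores `1/x` and is flagged. Two spot
summaries are kept: the mean and the minimum quality across cycles.
Filtering uses the minimum by default — one ambiguous cycle is enough to
corrupt a combinatorial readout — with 0.5 as the customary threshold in
four-color decoding. `NO_MATCH` reads are retained (flagged) so users can
audit the unmatched fraction.

# Quantification

Nuclei are segmented classically (Gaussian smoothing, Otsu threshold,
hole filling, distance-transform watershed to split touching nuclei,
minimum-area filter), keeping the package free of model weights; any
external segmenter can substitute its integer label image via
`label_mask()`. Labels are expanded up to 10 px (configurable; the value
approximates a cytoplasmic rim and is admittedly arbitrary) by seeded
Voronoi growth that never reassigns an original labeled pixel and never
crosses another label. Reads take the label under their rounded pixel;
label 0 is unassigned. Whether reads should be captured by raw or
expanded nuclei is genuinely open; both are supported and expansion is
the default. The cell-by-gene matrix counts reads with a cell and a
decoded gene (`NO_MATCH` excluded) and its total equals the number of
such reads exactly, by construction and by test. Exports: MatrixMarket
MTX plus cell/gene CSVs, and a `SingleCellExperiment` when that package
is installed.

# Numerical choices and degenerate inputs

- All randomized operations take explicit seeds and restore the caller's
  RNG state.
- Quality scores guard against division by zero (all-zero cycles score
  `1/x`, flagged); normalization floors its divisor and leaves all-zero
  planes untouched with a warning.
- Phase correlation whitens the cross-power spectrum with an epsilon
  floor; flat images short-circuit to a zero shift plus warning.
- `select_targets` warns and returns fewer targets when the
  non-overlap constraint cannot be met; genes shorter than 30 nt yield an
  empty candidate list with a warning.
- Ambiguity codes in input FASTA are an error unless masking is enabled,
  in which case windows containing `N` are skipped.

# Problem sizes in the test suite

The shipped tests run entirely on simulated data generated at test time:
unit fixtures use 64–243 px mosaics with tens of spots, and the
end-to-end checks use the default conditions (973² mosaic, 2×2 tiles of
512 px, 10% overlap, 9 genes over 4 channels × 2 cycles, 1000 spots,
default noise and crosstalk). The specificity screen is verified against
a brute-force Hamming scan on a 50-gene, ~1 kb/gene random transcriptome.
These sizes were chosen so the whole suite completes in well under a
minute per file on a laptop while still exercising every stage at
realistic spot densities.

# Known limitations

- Exact-match decoding only; no error-correcting barcode rescue.
- Rigid translation registration; no rotation, scaling or non-rigid
  deformation, and no illumination/flat-field correction.
- The classical segmenter expects roughly convex, similarly sized nuclei;
  dense tissue will need an external segmenter plugged in via the label
  interface.
- The specificity screen considers the sense strand of the provided
  transcriptome only — it is a transcript-level screen, not a
  genome-level one.
- Native microscope vendor formats are out of scope; data enter through
  the documented TIFF-plus-metadata directory layout.
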