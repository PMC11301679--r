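# metalloMS

Annotation of metal and label proteoforms ("metalloforms") of
cysteine-rich proteins from native and top-down mass spectra.

## The problem

Metallothioneins and other cysteine-rich proteins bind heterogeneous
mixtures of metal ions — Cu(I), Zn(II), Cd(II) — through thiolate
clusters, and differential cysteine alkylation (N-ethylmaleimide, NEM;
iodoacetamide, IAM) converts metal-site occupancy into mass shifts that
native electrospray MS can read out. The analytical difficulty is that
the resulting species space is combinatorial and full of near-isobaric
overlaps: at 5+, swapping one NEM for two IAM moves a peak by only
11.0045/z Da, and oxidized Cu₄Zn₄ and Cu₄NEM₂ species of metallothionein-3
(MT3, 68 residues, 20 Cys) collide in the same ~1486 m/z window. metalloMS
is a toolkit for researchers doing native and top-down MS of such
metal–protein complexes. It provides:

* **Candidate enumeration** under a cysteine budget:
  n(NEM) + n(IAM) + 2·n(SS) + c·n(metals) ≤ n(Cys), with per-adduct mass
  bookkeeping (Cu(I) displaces 1 H, Zn(II)/Cd(II) displace 2 H, a
  disulfide removes 2 H).
* **Isotope-pattern fitting**: aggregated isotopologue distributions by
  per-element convolution, rendered at instrument resolving power and
  scored against observed envelopes by cosine similarity; overlapping
  candidates are deconvolved jointly by non-negative least squares.
* **Top-down b/y fragment annotation** with metal/label adduct
  partitions, ppm-tolerance matching, fragmentation maps, cysteine-level
  label localization from ladder increments, and parent-stoichiometry
  reconstruction from complementary bᵢ/yₙ₋ᵢ pairs.
* **Survival-yield (SY) analysis**: SY(V) per collision voltage on a
  center-of-mass energy axis, E_com = z·V·m_gas/(m_gas + M_ion), with a
  logistic fit SY(E) = 1/(1 + exp((E − E50)/k)) whose midpoint E50 is a
  relative gas-phase stability measure.
* **Fragmentation-spectrum comparison**: peak alignment across spectra,
  Pearson intensity correlation matrices and shared-ion (UpSet-style)
  intersection tables.
* **A deterministic simulator** of native and fragment spectra with known
  ground truth, used by every recovery test.

## Worked example

```r
library(metalloMS)

mt3 <- mt3_sequence()                       # human MT3, UniProt P25713
n_residues(mt3); n_cysteines(mt3)
#> [1] 68
#> [1] 20

# the two oxidized species that overlap near 1486 m/z at 5+
mz(mt3, metalloform(n_cu = 4, n_zn = 4, n_ss = 2, z = 5), "average")
#> [1] 1486.318
mz(mt3, metalloform(n_cu = 4, n_nem = 2, n_ss = 2, z = 5), "average")
#> [1] 1485.678

# simulate a native spectrum of that mixture and annotate it
cands <- enumerate_candidates(mt3, list(cu = c(4, 4), zn = c(0, 4),
                                        nem = c(0, 2), ss = c(2, 2)),
                              charges = 5L)
sim <- simulate_native(simulation_spec(mt3, list(
  list(mfc = metalloform(n_cu = 4, n_zn = 4, n_ss = 2, z = 5), abundance = 1),
  list(mfc = metalloform(n_cu = 4, n_nem = 2, n_ss = 2, z = 5), abundance = 0.8)),
  snr = 50, seed = 303))
res <- annotate(sim, cands)
res[res$species %in% c("Cu4Zn4SS2", "Cu4NEM2SS2"),
    c("species", "theo_mz", "score", "abundance", "group_id")]
#>      species  theo_mz     score abundance group_id
#>    Cu4Zn4SS2 1486.162 0.9625482 0.9967383        1
#>   Cu4NEM2SS2 1485.649 0.9180870 0.7973551        1
```

Both species are recovered with their mixing proportions, and the shared
`group_id` flags them as a near-isobaric pair that mass alone cannot
separate — the situation where CID follow-up decides the stoichiometry.

Label localization from a b-ion ladder (counts of NEM on b2…b8):

```r
ladder <- data.frame(type = "b", index = 2:8, n_cu = 0L, n_zn = 0L,
                     n_cd = 0L, n_nem = c(0, 0, 0, 0, 1, 1, 2), n_iam = 0L)
loc <- localize_labels(ladder, mt3)
loc[loc$state != "undetermined", ]
#>   position position_noMet       state
#> 1        6              5 labeled-NEM
#> 2        8              7 labeled-NEM
```

The +1 NEM increments at b6 and b8 each bracket exactly one cysteine,
placing NEM on Cys6 and Cys8 (Met-inclusive numbering; the alternate
numbering without the initiator Met is reported alongside).

## Command line

A thin Rscript ties the modules into reproducible runs:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","metalloms.R",package="metalloMS"))')" \
    annotate --config run.yaml
```

Subcommands: `annotate`, `fragmap`, `sy`, `compare`, `simulate`. Each
reads a YAML config, writes CSV outputs with documented schemas and a
provenance record (package version, seed, config digest).

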