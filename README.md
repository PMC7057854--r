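# macrodissect

Tools for dissecting the binding affinity of large, flexible macrocyclic
ligands into a **direct interaction** term and a **conformational** term,
plus the ensemble-surface-area machinery that links free-ligand
conformational ensembles to lipophilicity.

## The problem

Macrocyclic peptides bind flat protein surfaces that small molecules
cannot, but they remain highly flexible in solution: only a fraction of
the free-ligand ensemble resembles the bound (bioactive) conformation.
Relative free energy perturbation (FEP) calculations run under
conformational restraints converge well but capture mostly the direct
protein–ligand interaction and solvation terms; the conformational
pre-equilibrium of the free ligand is invisible to them. This package
implements the complementary analysis: classify a free-ligand conformer
ensemble into a bioactive population (population 1) and the rest
(population 2) by RMSD against a bound-state reference, and convert
population ratios into the missing conformational contribution.

The model: if a ligand binds only from its bioactive conformation,
populated with fraction *p* in the free state, the apparent dissociation
constant is

    Kd_app = Kd / p        i.e.    pKd_app = pKd + log10(p)

and the conformational contribution to the affinity difference between
two ligands A and B is

    ΔpKd_conf = log10(p_A / p_B)

The direct term comes from a restrained relative-FEP network
(ΔΔG_bind = ΔΔG_complex − ΔΔG_solvent per edge, least-squares node
estimates anchored at a reference ligand, converted through
ΔpKd = −ΔΔG / (ln 10 · R · T)). The total predicted shift is the sum of
both terms.

On the lipophilicity side, the package computes Shrake–Rupley solvent
accessible surface areas partitioned into polar (PSA) and nonpolar
(NPSA) atom contributions, averages them over the ensemble ("dynamic"
surface areas), and fits the linear model
`logD = a·NPSA + b·PSA + c`.

It is aimed at computational chemists post-processing enhanced-sampling
MD of macrocycles (or any flexible ligand with a known bound pose); a
seeded synthetic-data generator emulates such output so every stage can
be exercised and validated without trajectories.

## Worked example

```r
library(macrodissect)

## a 4-ligand synthetic study: bimodal free-ligand ensembles at the
## occupancies of the H/H, Me/H, Me/Me, Et/Me substitution series
study <- makeStudy(nFrames = 2000, seed = 42)
est <- lapply(study$ensembles, function(e)
  classifyPopulations(rmsdSeries(e, study$reference)))
for (e in est) show(e)
#> PopulationEstimate '7_HH':    p1 = 0.062 +/- 0.010 (threshold 2.60 A, 5 blocks)
#> PopulationEstimate '9_MeH':   p1 = 0.163 +/- 0.013 (threshold 2.60 A, 5 blocks)
#> PopulationEstimate '5_MeMe':  p1 = 0.287 +/- 0.015 (threshold 2.60 A, 5 blocks)
#> PopulationEstimate '11_EtMe': p1 = 0.393 +/- 0.030 (threshold 2.60 A, 5 blocks)
```

Each ensemble's RMSD distribution against the bound-state reference is
bimodal; `p1` is the fraction of frames at or below the 2.6 Å threshold
(the bioactive population), and the ±1σ error is the spread over five
contiguous trajectory blocks. The recovered occupancies match the
generating values (6%, 16%, 30%, 40%) within sampling error and
reproduce the monotone growth of the bioactive population with
substituent size.

```r
## conformational affinity gain of the Et/Me ligand over H/H
conformationalDpkd(0.40, 0.06)
#> [1] 0.8239087    # ~0.8 pKd units

## combine with a direct term of ~2 pKd units from a restrained FEP network
dissectAffinity(2.0, conformationalDpkd(0.40, 0.06))
#> $dpkdTotal              2.823909
#> $fractionConformational 0.2918    # conformational share ~ one third
```

So of a ~2.8-unit total affinity difference, roughly one third is
carried by the conformational pre-equilibrium — the part a restrained
FEP calculation cannot see.

```r
## dynamic surface areas and the lipophilicity model
sa <- ensembleSurface(study$ensembles[["5_MeMe"]],
                      framesSubset = seq(1, 2000, by = 100))
show(sa)
#> SurfaceAreas '5_MeMe': 20 frames; <PSA> = 426.6 +/- 38.8, <NPSA> = 259.9 +/- 21.2 A^2

d <- makeLipoDataset(noiseSigma = 0, n = 8, seed = 1)
show(fitLogdModel(d$psa, d$npsa, d$logd))
#> LipoModel: logD = 0.270*NPSA -0.820*PSA +2.220  (n = 8, r_fit = 1.000)
```

A full disk-based run (`runSimulate` → `runPopulations` → `runFep` →
`runDissect` → `runLipo`, or the `inst/cli/macrodissect.R` script with
subcommands `simulate`/`populations`/`fep`/`dissect`/`lipo`/`report`)
writes TSV + JSON reports with the complete configuration echoed for
provenance; reruns with the same config and seed are byte-identical.

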