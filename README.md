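# mdfluct

Comparative residue-fluctuation analysis of molecular dynamics
trajectories, for structural bioinformaticians asking *why* a
thermostable enzyme tolerates heat that unfolds its mesophilic homolog.
The typical input is one MD trajectory per homolog (multi-model PDB) plus
the protein sequences (FASTA); the output localises the difference in
flexibility to specific regions and candidate interactions.

The analysis at the package's core:

* **RMSD / RMSF.** Every frame is superposed onto a reference by the
  closed-form Kabsch solution (SVD of the centred covariance, reflection
  suppressed). Per-frame RMSD tracks global drift; per-residue RMSF,
  computed about a two-pass iterated mean structure,
  `RMSF_i = sqrt(mean_f |r_i(f) − ⟨r_i⟩|²)`, measures local flexibility.
* **Common residue numbering.** Homolog sequences are aligned (global
  affine-gap DP, BLOSUM62, gap open 10 / extend 1; progressive profile
  alignment for 3+ sequences) and every alignment column becomes a shared
  residue number, so per-residue quantities are comparable across
  proteins of different lengths.
* **Region calling.** Per common column,
  `Δ_i = RMSF_meso(i) − mean(RMSF_thermo(i))`; columns with `Δ_i`
  strictly above the average difference are merged (gap tolerance 2,
  minimum span 3) into labelled Regions I, II, ... — the contiguous
  stretches where the mesophile is distinctly more flexible.
* **Interactions.** Salt-bridge (basic Lys/Arg/His vs acidic Asp/Glu
  side-chain heavy atoms, contact ≤ 4.0 Å) and hydrogen-bond (N/O heavy
  atoms, ≤ 3.5 Å) candidates are searched in the reference geometry
  (≤ 6 Å), their per-frame distances and occupancies measured, and each
  homolog classified per candidate as SB, HB or NI — including NI by
  chemistry when the aligned partner residue cannot form the interaction.

Because real production trajectories are rarely distributable, the package
ships a synthetic-trajectory generator with planted per-residue
fluctuation amplitudes, planted two-state contacts and homolog sets with
known residue correspondence; all statistical claims of the test suite are
checked against that planted ground truth.

## Worked example

Generate a three-homolog synthetic study (one mesophile carrying two
planted high-fluctuation regions and a Lys→Met replacement, two
thermophiles) and run the full analysis:

```r
library(mdfluct)

cfg <- default_generator_config(seed = 1, n_residues = 80, n_frames = 250)
cfg$regions <- data.frame(start = c(15, 45), end = c(25, 60))
cfg_path <- generate_fixtures(cfg, "demo")

rep <- run_pipeline(read_run_config(cfg_path), output_dir = "demo/results")
print(rep)
#> mdfluct run report
#>   thermo1      mean RMSD 0.949 A, mean RMSF 0.686 A
#>   thermo2      mean RMSD 0.974 A, mean RMSF 0.684 A
#>   meso         mean RMSD 1.434 A, mean RMSF 0.926 A
#>   regions above mean delta: 2 (threshold 0.241 A)
#>   interaction rows: 165 (17 formed)
```

The mesophile drifts more (higher RMSD) and fluctuates more (higher mean
RMSF) than the thermophiles, exactly as planted. The called regions match
the planted spans:

```r
rep$regions
#>   label start_column end_column length mean_delta_in_region
#> 1     I           15         25     11            0.8413007
#> 2    II           45         60     16            0.8696029
```

and the planted Lys12–Asp82 salt bridge is formed in both thermophiles but
impossible in the mesophile, where the lysine is a methionine:

```r
subset(rep$interactions, common_pair == "c12-c82" & kind == "salt_bridge")
#>   common_pair        kind protein resno_a resid_a resno_b resid_b occupancy classification                 note
#> 7     c12-c82 salt_bridge thermo1      12     LYS      82     ASP     0.856             SB
#> 8     c12-c82 salt_bridge thermo2      12     LYS      82     ASP     0.800             SB
#> 9     c12-c82 salt_bridge    meso      12     MET      82     ASP        NA             NI incompatible_residue
```

All results are also written as tidy CSVs (`rmsd.csv`, `rmsf.csv`,
`delta_profile.csv`, `regions.csv`, `interactions.csv`, ...) plus an
aligned FASTA and a YAML report under the output directory. A thin CLI
over the same functions is installed at `inst/cli/mdfluct`
(`generate` / `analyze` / `report` subcommands; exit codes 0/2/1 for
success / validation error / runtime error).

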