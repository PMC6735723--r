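# adaptrate

Estimation of the adaptive (ωa) and non-adaptive (ωna) rates of
nonsynonymous substitution from population polymorphism and divergence
data, and analysis of how those rates vary with protein architecture.

## Who this is for

Population geneticists asking *where* in proteins adaptive amino-acid
substitutions accumulate: across genes with different expression,
recombination or intron content, and across residues with different
solvent exposure, secondary structure or intrinsic disorder.  The package
implements the full analysis chain on top of standard inputs (per-gene
codon alignments of an ingroup sample plus one outgroup; per-residue and
per-gene covariate tables) and ships a synthetic-data generator with
analytic ground truth so every stage can be validated end to end.

## The method

For each set of coding sites the data are reduced to a **spectrum set**:
synonymous/nonsynonymous unfolded site frequency spectra (SFS) for *n*
chromosomes, Nei–Gojobori site opportunities *Ls*/*Ln* (stop-codon
mutations excluded), and divergence counts *Ds*/*Dn* polarized against the
outgroup.  The rate of protein evolution is ω = (Dn/Ln)/(Ds/Ls).

A distribution of fitness effects (DFE) of scaled coefficients S = 4Nₑs is
fitted to the two SFS by Poisson maximum likelihood, using the diffusion
sojourn density h(x;S) = (1−e^(−S(1−x)))/((1−e^(−S))·x(1−x)).  Families
**Neutral**, **Gamma** (deleterious −S ~ Gamma(β, S̄d)) and **GammaExpo**
(adds a proportion p_b of beneficial mutations with exponential mean S̄b)
are compared by AIC.  The fitted deleterious DFE gives the expected
non-adaptive rate ωna = (1−p_b)·E[S/(1−e^(−S))], and

    ωa = ω − ωna,      α = ωa / ω.

Category analyses bootstrap genes (or residue-site cells) within each
category (B = 100 by default), trim replicates whose DFE mean or shape
falls outside the 1st–99th percentile band, summarize with percentile 95%
CIs, test ordered-category trends with Kendall's τ on category means, and
test two-category contrasts with the bootstrap statistic k and
P = (2k+1)/(N+1), BH-FDR corrected across pairs.  Buried/exposed
stratified refits and a sequential-SS ANCOVA (RSA first) control for the
dominant solvent-exposure confound.

## Worked example

Build a spectrum from a codon alignment (ingroup rows + an `outgroup`
record) and inspect it:

```r
library(adaptrate)
aln <- read_codon_alignment(system.file("extdata", "planted_gene.fasta",
                                        package = "adaptrate"))
build_spectrum(aln)
#> Spectrum set 'planted_gene': n = 4 chromosomes (unfolded)
#>   Ls = 9.50, Ln = 25.50; Ds = 1, Dn = 1
#>   polymorphic sites: 1 syn, 1 nonsyn
```

Simulate a residue-exposure study with a planted adaptive gradient
(beneficial proportion rising 10-fold from buried to exposed residues),
scan it, and read the report tables:

```r
st <- simulate_rsa_study(G = 500, n = 20, seed = 1, k = 8)
sc <- run_scan(st$spectra, st$units,
               list(scan_scheme("rsa", "rsa", k = 8, zero_special = TRUE,
                                unit = "site"),
                    scan_scheme("exposure", "exposure", unit = "site")),
               B = 50, seed = 1)
sc
#> Category scan: 2 scheme(s), family GammaExpo, B = 50, seed = 1
#>
#> Continuous variables (Kendall tau on category means):
#>  variable n_categories n_units tau_omega_a p_omega_a signif_omega_a
#>       rsa            8    4000      0.7857  0.005506             **
#>  tau_omega_na p_omega_na signif_omega_na tau_omega   p_omega signif_omega
#>       -0.5714    0.06101               .    0.9286 0.0003968          ***
#>
#> Discrete variables (pairwise bootstrap differences):
#>  variable n_categories n_units     comparison     stat k mean_diff p_value
#>  exposure            2    4000 buried-exposed  omega_a 0  -0.08154 0.02041
#>  exposure            2    4000 buried-exposed omega_na 1   0.04088 0.06122
#>  exposure            2    4000 buried-exposed    omega 0  -0.04069 0.02041
```

The planted trend is recovered: ωa rises across RSA categories
(τ = 0.79, P = 0.0055) and exposed residues have a significantly higher
adaptive rate than buried ones (buried − exposed = −0.082, k = 0,
P = 0.020), while ωna shows no positive trend — the adaptive signal is not
an artifact of relaxed constraint.  A genome-wide fit of the pooled
spectra returns the headline quantities:

```r
fit_dfe(aggregate_spectra(st$spectra), "GammaExpo")
#> DFE fit [GammaExpo]: logL = -148.617, k = 5, AIC = 307.234
#>   omega = 0.1197, omega_na = 0.0551, omega_a = 0.0646, alpha = 0.5398
```

ω is the total substitution rate; about half of it (α ≈ 0.54 here, with a
strong planted effect) is attributed to adaptive fixation.

A thin command-line wrapper over the same functions lives at
`inst/scripts/adaptrate-scan.R` (`simulate` and `scan` subcommands).

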