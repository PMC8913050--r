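# acltis

Simulation of the force carried by a single-bundle ACL graft during gait, and
of how that force changes when the graft's **tibial insertion site (TIS)** is
moved on the tibial plateau.

## The problem

In single-bundle ACL reconstruction the surgeon drills one tibial tunnel
somewhere inside the native tibial footprint of the ligament. Where exactly
that tunnel lands changes the geometry of the graft — and therefore the force
it carries every time the knee moves. `acltis` models the graft as a passive
elastic element spanning the knee and asks: *if the tibial insertion is moved
2.5, 5.0 or 7.5 mm anteriorly, posteriorly, medially or laterally from
center, what happens to the graft force over a gait cycle?*

The intended users are musculoskeletal-modelling researchers and biomechanics
students who want a small, fully scriptable, fully seeded version of this
sensitivity analysis without a full OpenSim tool chain.

## The model

**Geometry.** Femur and tibia carry body-fixed frames (x anterior, y
proximal, z lateral). The knee has three independent rotations — flexion
$\varphi$ (about z), adduction $\alpha$ (about x), internal rotation $\rho$
(about y), applied in that body-fixed order — plus an anteroposterior /
superoinferior translation of the tibia origin that is a tabulated function
of flexion (the "coupling"). The ligament path is the straight line from the
femoral insertion, mapped through the femur→tibia transform, to the tibial
insertion.

**Force law.** With length $L$, resting length $L_0$, strain
$e = (L - L_0)/L_0$, stiffness $k$ and linear strain limit $e_l$:

$$
f(e) = \begin{cases}
0 & e \le 0 \\
0.25\,k\,e^2 / e_l & 0 \le e \le 2e_l \\
k\,(e - e_l) & e \ge 2e_l
\end{cases}
$$

Defaults: insertions $(-1.1, -40.5, 0.7)$ cm (femur frame) and
$(1.2, -3.2, -0.1)$ cm (tibia frame), $L_0 = 2.8$ cm, $k = 3100$ N,
$e_l = 0.03$.

**Gait input.** A seeded synthetic generator produces per-subject 101-point
knee-angle cycles shaped by landmark values (stance flexion max 14°, swing
flexion max 64°, adduction peak 10° near 85% cycle, swing internal/external
rotation 7°/12°), with configurable inter-subject jitter. Real joint-angle
files in the OpenSim-style `.mot/.sto` text dialect can be used instead.

**Analysis.** Each subject is simulated at 13 insertion sites (center +
{2.5, 5.0, 7.5} mm × {anterior, posterior, medial, lateral}). Per condition
the package reports stance-phase peak forces (initial-contact and
terminal-stance windows), Pearson correlation of each force curve against
the center curve, and paired t-tests of peaks versus center.

## Worked example

```r
library(acltis)

cfg    <- default_config()          # 7 subjects, master seed 42
cohort <- cohort_from_config(cfg)
sweep  <- run_sweep(cohort, config = cfg)
sweep
#> ACL TIS sweep: 7 subjects x 13 insertion sites = 91 force curves

rep <- build_report(sweep, cfg)
rep$peak_table[, c("direction", "magnitude_mm", "first_mean", "second_mean")]
#>    direction magnitude_mm first_mean second_mean
#> 1     center          0.0     72.291     153.892
#> 2   anterior          2.5    279.935     361.950
#> 3   anterior          5.0    498.375     578.871
#> 4   anterior          7.5    724.198     803.196
#> 5  posterior          2.5      0.000       6.697
#> 6  posterior          5.0         NA          NA
#> 7  posterior          7.5         NA          NA
#> 8     medial          2.5    156.020     241.572
#> 9     medial          5.0    263.239     348.792
#> 10    medial          7.5    388.682     473.829
#> 11   lateral          2.5     27.704      87.553
#> 12   lateral          5.0     10.484      50.010
#> 13   lateral          7.5      6.006      35.941
```

Reading the table: moving the insertion **anteriorly** lengthens the graft
throughout stance, so mean peak force climbs steeply with offset (72 N at
center to 724 N at 7.5 mm anterior — approaching the lower bound of the
600–2300 N cadaveric ultimate-force range, which the report flags).
**Medial** offsets also increase force, **lateral** offsets decrease it, and
a **posterior** shift of 5 mm or more leaves the graft slack for the whole
cycle: those cells are N/A, not zero — a slack graft is a nonfunctional one,
not a low-force one. Correlations with the center curve
(`rep$correlation_means`) decay with offset distance in every taut
direction.

The same pipeline is scriptable from a shell via `exec/acltis`
(`generate`, `sweep`, `report`, `all` subcommands).

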