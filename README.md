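# pbsnet

Chromophore-network analysis for phycobilisomes (PBS), the giant
light-harvesting antenna complexes of cyanobacteria and red algae. Given an
atomic coordinate model, `pbsnet` extracts the bilin chromophores
(phycocyanobilin and relatives), measures the inter-bilin geometry that
governs excitation energy transfer (EET), deduces transfer pathways to
user-designated terminal emitters, compares hexamer packing modes, and
tallies assembly stoichiometry. It is aimed at structural biologists and
photosynthesis researchers who have a cryo-EM model of a PBS (or any
pigment-protein assembly with point-like chromophore anchors) and want the
distance/orientation analysis done reproducibly rather than by hand in a
molecular viewer.

## What it computes

Every bilin is reduced to its **C10 anchor** — the central methine carbon
between pyrrole rings B and C — and inter-bilin distances are Euclidean
distances between anchors. For a donor/acceptor pair with unit transition
dipoles μ̂_D, μ̂_A separated by the unit vector R̂, the Förster orientation
factor is

    κ  =  μ̂_D · μ̂_A − 3 (μ̂_D · R̂)(μ̂_A · R̂)
    κ² =  (cos θτ − 3 cos θ_D cos θ_A)²

with κ² in [0, 4] and isotropic average 2/3; θτ is the angle between the
dipoles and θ_D, θ_A the angles each dipole makes with the donor–acceptor
line. Both forms are implemented and agree to numerical precision. Dipoles
are either supplied (e.g. from quantum-chemical calculations) or
approximated geometrically as the first principal axis of each bilin's
conjugated-system atoms.

EET pathways are deduced on a graph whose nodes are chromophores and whose
edges join pairs under a distance cutoff (default 45 Å), following the
shortest-bilin-distance rule: either minimal summed distance (`min_total`)
or minimal longest hop (`min_max_step`). An assembly census turns a
declarative component schema into exact protomer/bilin/polypeptide tallies.
A synthetic generator builds rod-packed (coaxially stacked) and chain-packed
(laterally staggered) toy hexamer assemblies with analytically known
geometry, so the entire pipeline is testable without downloading deposited
structures.

## Worked example

```r
library(pbsnet)

# a 3-hexamer chain-packed toy assembly, written to disk and read back
asm    <- make_assembly(synthetic_params(n_hexamers = 3, packing = "chain", seed = 7))
paths  <- write_fixture(asm, "demo")
model  <- read_structure(paths$structure) |> apply_label_map(paths$label_map)

inter_group_min_distance(model, "H1", "H2")
#>   group_a group_b site_a  site_b   distance
#> 1 H1      H2      CYC_A_1 CYC_B_31       37

g <- build_graph(model, cutoff = 45)
glance(g)
#>   n_nodes n_edges cutoff weighting n_components min_distance max_distance
#> 1      54     299     45 distance             1         11.2         43.3

shortest_pathways(g, sites_in_group(model, "H1")[1], sites_in_group(model, "H3"))
#>   source  terminal n_steps total_length max_step
#> 1 CYC_A_1 CYC_C_31       5         149.     38.0

rod <- make_assembly(synthetic_params(n_hexamers = 3, packing = "rod",
                                      axial_spacing = 24.3, seed = 7))
compare_packings(model, rod$model, list(c("H1","H2"), c("H2","H3")),
                 model_names = c("chain", "rod"))
#>   model junction min_distance n_contacts classification
#> 1 chain H1-H2            37            1 single-pathway
#> 2 chain H2-H3            37            1 single-pathway
#> 3 rod   H1-H2            24.3        174 network
#> 4 rod   H2-H3            24.3        174 network

census(read_assembly_schema(system.file("extdata", "ap_pbs_schema.tsv",
                                        package = "pbsnet")))
#> <census_result>
#>   chromophores: 360 total (144 core, 216 periphery)
#>   protomers:    144 (72 core, 72 periphery)
#>   polypeptides: 310
```

The chain junctions each have exactly one sub-cutoff bilin contact (37 Å) —
a single preferred inner-chain pathway — while the rod junctions expose many
equivalent contacts (24.3 Å closest), forming a transfer network. The
shipped schema tallies a paddle-shaped PBS: 360 bilins, 144 in the
allophycocyanin core and 216 in the phycocyanin periphery, from 72 + 72
protomer equivalents.

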