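# Example custom configuration: a tense star next to a passive circle in
# a wider periodic box. Run with
#   Rscript inst/scripts/ibstokes.R run inst/extdata/two_membranes.yaml
name: two_membranes
mu: 1
dt: 0.0001
n_steps: 200
grid:
  nx: 64
  ny: 64
  extents: [-2, 2, -2, 2]
structures:
  - kind: star          # the 8-lobed interface, max radius 0.9
    Nb: 96
    r_rest: 0.3
    cs: 20
  - kind: circle        # passive membrane above the star
    Nb: 64
    radius: 0.25
    center: [0.0, 1.4]
    cs: 0.05
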