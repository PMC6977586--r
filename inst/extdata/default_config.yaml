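# Template run configuration for the metnets pipeline.
# Copy, edit, and pass to `metnet <stages> --config <file>` or
# metnets::read_config(). Missing keys fall back to package defaults.

paths:
  model: null            # native JSON model, or produced by `simulate`
  measurements: null     # measurement TSV (see read_measurements)
  output_dir: metnets_out

curation:
  boundary_compartment: null
  extracellular_compartment: null
  # case-insensitive regular expressions matched against reaction
  # identifiers and names; matching reactions are treated as simulation
  # artifacts and removed
  name_patterns:
    - biomass
    - protein (assembly|degradation)

network:
  compartmentalize: false
  compartment_filter: null   # e.g. [mitochondrion]
  process_filter: null       # e.g. [citric acid cycle]
  # chemically ubiquitous hubs, rarely informative in metabolomics
  hubs_category1:
    - proton
    - water
    - dioxygen
    - phosphate
    - diphosphate
    - carbon_dioxide
    - sulfate
    - hydrogen_peroxide
    - ammonium
    - sulfite
    - sodium
    - hydrogen_carbonate
    - hydroxide
  # biologically relevant but prolifically connected hubs
  hubs_category2:
    - coenzyme_a
    - acetyl_coenzyme_a
    - acyl_carrier_protein
    - carnitine
    - nicotinamide_adenine_dinucleotide
    - nicotinamide_adenine_dinucleotide_phosphate
    - flavin_adenine_dinucleotide
    - adenosine_triphosphate
    - adenosine_diphosphate
    - adenosine_monophosphate
  degree_threshold: 50
  keep_largest_component: true

metrics:
  mode: metabolite
  replicates: 10

measurement:
  coverage_threshold: 0.5
  var_equal: true        # false uses the Welch t-test

clusters:
  n_modules: 25
  depth: 2
  overlap_thresholds: [0.25, 0.50, 0.75]

simulate:
  toy: toy4
  effects: {}

seed: 1
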