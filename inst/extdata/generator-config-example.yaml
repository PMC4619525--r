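# Annotated generator configuration for hospsample.
# Any field left out falls back to the package default shown here.

seed: 1                      # required: makes generation deterministic

stratum_sizes:               # hospitals per type stratum
  academic: 8
  teaching: 28
  general: 53

n_regions: 7                 # organizational regions, labelled R1..R7
dual_academic_region: R1     # region hosting two academic centres

beds_range:                  # integer bed-count range per stratum
  academic: [700, 1350]
  teaching: [400, 900]
  general: [150, 600]

# Per-product count model, log scale:
#   mean = exp(intercept[type] + slope * beds) * shared_effect * product_effect
coefficients:
  rbc:
    intercept: {academic: 7.341, teaching: 7.362, general: 7.223}
    slope: 0.0025
  ffp:
    intercept: {academic: 5.424, teaching: 5.270, general: 5.059}
    slope: 0.0028
  plt:
    intercept: {academic: 4.881, teaching: 4.722, general: 4.322}
    slope: 0.0032

latent_sd: 0.12              # shared log-normal effect: raises cross-product
                             # rank correlation between rbc/ffp/plt
noise_sd:                    # independent per-product effect: lowers it
  rbc: 0.08                  # red-cell use tracks hospital activity closely
  ffp: 0.33                  # plasma and platelet use vary more between
  plt: 0.30                  # hospitals (wastage, shelf life, case mix)
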