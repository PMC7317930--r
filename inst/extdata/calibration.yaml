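# Generating calibration for synthetic immunogold scenes.
#
# Densities are mean surface densities in immunoparticles/um^2.
# source: body_text   -- value printed in the study's Results text
#         figure_legend -- value printed only in a figure legend (recorded
#                          under `alternates` when it conflicts with body text)
#         assumed      -- not printed anywhere; a single plausible value chosen
#                         to complete the soma->spine density gradient
# Total expected density of a condition is lambda_c * mean_cluster_size +
# lambda_s with lambda_s = frac_scattered * density and
# lambda_c = (1 - frac_scattered) * density / mean_cluster_size.

raster:
  nm_per_px: 1.0
  particle_diameter_nm: 10
  background_level: 0.85
  disk_depth: 0.55
  noise_sd: 0.05
  shade_amp: 0.06
  shade_scale_nm: 250

process:
  frac_scattered: 0.15
  mean_cluster_size: 6
  offspring_dispersion: 2
  cluster_radius_nm: 20
  hard_core_nm: 15
  eface_background_per_um2: 0.3
  link_distance_nm: 50
  min_cluster_size: 3

# Default profile geometry per compartment class: sampled area (um^2) and the
# number of profiles analysed per animal/condition. n for slm oblique
# dendrites (16) and spines (21) are the printed 6-month sample sizes.
profiles:
  soma:            {area_um2: 4.0,  n_profiles: 10, shape: blob}
  apical_dendrite: {area_um2: 2.0,  n_profiles: 16, shape: ribbon}
  oblique_dendrite: {area_um2: 1.0, n_profiles: 16, shape: ribbon}
  spine:           {area_um2: 0.2,  n_profiles: 21, shape: blob}
  axon_terminal:   {area_um2: 0.3,  n_profiles: 20, shape: blob, az_area_um2: 0.05}

# Somato-dendritic density gradient, 11 compartments. WT baseline is shared
# across ages; only the printed 6-month slm values anchor the absolute scale.
gradient:
  baseline:          # WT, particles/um^2
    - {layer: sp,      klass: soma,             density: 6.3,    source: assumed}
    - {layer: sr_prox, klass: apical_dendrite,  density: 14.8,   source: assumed}
    - {layer: sr_dist, klass: apical_dendrite,  density: 19.6,   source: assumed}
    - {layer: so,      klass: oblique_dendrite, density: 26.4,   source: assumed}
    - {layer: sr_prox, klass: oblique_dendrite, density: 31.7,   source: assumed}
    - {layer: sr_dist, klass: oblique_dendrite, density: 42.5,   source: assumed}
    - {layer: slm,     klass: oblique_dendrite, density: 64.34,  source: body_text}
    - {layer: so,      klass: spine,            density: 47.2,   source: assumed}
    - {layer: sr_prox, klass: spine,            density: 58.3,   source: assumed}
    - {layer: sr_dist, klass: spine,            density: 72.9,   source: assumed}
    - {layer: slm,     klass: spine,            density: 101.58, source: body_text}
  # Per-age genotype overrides; conditions not listed equal the baseline.
  overrides:
    - {age_months: 6,  genotype: APP_PS1, layer: slm, klass: oblique_dendrite,
       density: 28.83, source: body_text}
    - {age_months: 6,  genotype: APP_PS1, layer: slm, klass: spine,
       density: 49.76, source: body_text}
  # 12-month APP/PS1: reduced in all strata and compartments (printed claim,
  # magnitudes not printed); modelled as a uniform fraction of WT.
  app_12mo_fraction: 0.40

# Presynaptic membrane densities at 12 months (axon terminals, active zone
# vs extrasynaptic), particles/um^2, all printed.
presynaptic:
  - {genotype: WT,      layer: sr,  az_density: 103.31, extra_density: 42.97, source: body_text}
  - {genotype: WT,      layer: slm, az_density: 109.03, extra_density: 60.79, source: body_text}
  - {genotype: APP_PS1, layer: sr,  az_density: 120.95, extra_density: 28.08, source: body_text}
  - {genotype: APP_PS1, layer: slm, az_density: 17.32,  extra_density: 24.64, source: body_text}

# Pre-embedding membrane vs intracellular partition (fraction of particles on
# the plasma membrane), all printed percentages / 100.
pre_embedding:
  d_offset_nm: 25
  mean_particles_per_profile: 30
  conditions:
    - {age_months: 1,  genotype: WT,      layer: sr,  p_membrane: 0.6404, source: body_text}
    - {age_months: 1,  genotype: WT,      layer: slm, p_membrane: 0.6468, source: body_text}
    - {age_months: 1,  genotype: APP_PS1, layer: sr,  p_membrane: 0.6552, source: body_text}
    - {age_months: 1,  genotype: APP_PS1, layer: slm, p_membrane: 0.6511, source: body_text}
    - {age_months: 6,  genotype: WT,      layer: sr,  p_membrane: 0.6345, source: body_text}
    - {age_months: 6,  genotype: WT,      layer: slm, p_membrane: 0.6206, source: body_text}
    - {age_months: 6,  genotype: APP_PS1, layer: sr,  p_membrane: 0.6346, source: body_text}
    - {age_months: 6,  genotype: APP_PS1, layer: slm, p_membrane: 0.4105, source: body_text}
    - {age_months: 12, genotype: WT,      layer: sr,  p_membrane: 0.5881, source: body_text}
    - {age_months: 12, genotype: WT,      layer: slm, p_membrane: 0.5423, source: body_text}
    - {age_months: 12, genotype: APP_PS1, layer: sr,  p_membrane: 0.3260, source: body_text}
    - {age_months: 12, genotype: APP_PS1, layer: slm, p_membrane: 0.1519, source: body_text}

# Cluster composition at 12 months in oblique dendrites, pooled over a fixed
# reference area of 140.00 um^2 per condition (printed totals and size
# ranges). mean_size parameterizes the shifted-negative-binomial size law
# (sizes = 3 + NegBin(mu = mean_size - 3, size = dispersion)).
clusters_12mo:
  reference_area_um2: 140.0
  dispersion: 1.5
  conditions:
    - {genotype: WT,      layer: sr_prox, n_clusters: 298, size_min: 3, size_max: 29,
       mean_size: 8.0, source: body_text}
    - {genotype: APP_PS1, layer: sr_prox, n_clusters: 68,  size_min: 3, size_max: 12,
       mean_size: 5.5, source: body_text}
    - {genotype: WT,      layer: sr_dist, n_clusters: 204, size_min: 3, size_max: 29,
       mean_size: 8.0, source: body_text}
    - {genotype: APP_PS1, layer: sr_dist, n_clusters: 57,  size_min: 3, size_max: 12,
       mean_size: 5.5, source: body_text}
    - {genotype: WT,      layer: slm,     n_clusters: 234, size_min: 3, size_max: 37,
       mean_size: 8.5, source: body_text}
    - {genotype: APP_PS1, layer: slm,     n_clusters: 60,  size_min: 3, size_max: 13,
       mean_size: 5.5, source: body_text}

# Printed values that conflict with the body text (recorded, not used).
alternates:
  figure_legend_6mo_slm:
    - {genotype: WT,      klass: oblique_dendrite, density: 60.27, sem: 5.60}
    - {genotype: APP_PS1, klass: oblique_dendrite, density: 35.37, sem: 3.61}
    - {genotype: WT,      klass: spine,            density: 103.68, sem: 18.69}
    - {genotype: APP_PS1, klass: spine,            density: 58.09,  sem: 13.78}
  figure_legend_12mo_clusters:
    - {genotype: WT,      layer: sr,  n_clusters: 298, size_min: 3, size_max: 21}
    - {genotype: WT,      layer: slm, n_clusters: 230, size_min: 3, size_max: 22}
    - {genotype: APP_PS1, layer: sr,  n_clusters: 68,  size_min: 3, size_max: 12}
    - {genotype: APP_PS1, layer: slm, n_clusters: 60,  size_min: 3, size_max: 13}
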