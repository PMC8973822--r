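# Example pipeline configuration.
# synthgen: scene parameters applied to every genotype; alpha_map gives the
# membrane fraction per genotype (the wild type must be present).
synthgen:
  image_height: 256
  image_width: 256
  n_cells: 2
  psf_sigma: 1
  alpha_map:
    WT: 0.8
    p.L620P: 0.1
    p.G1820S: 0.1
    p.E188G: 0.8
segmentation:
  median_radius: 4
  min_area: 800
  histogram_bins: 256
  border_policy: keep
stats:
  wt_label: WT
  min_cells: 30
run:
  images_per_genotype: 20
  comarkers: [PM, ER]
  base_seed: 1
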