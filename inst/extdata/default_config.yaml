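# Default configuration for the image-based SAR pipeline.
# Every key is optional; absent keys fall back to these values.

physics:
  f0: 1.28e+08            # Hz; 3T Larmor frequency. NOTE: some 3T scanners
                          # operate near 123 MHz — set the measured value,
                          # the EPT scaling is directly proportional to it.
  mu0: 1.2566370614359173e-06   # H/m, vacuum permeability (4*pi*1e-7)
  eps0: 8.8541878128e-12  # F/m, vacuum permittivity
  rho: 1000               # kg/m^3, tissue mass density for SAR
  time_convention: "+iwt" # sign of i*omega*eps in the admittance; |E| and
                          # SAR are invariant to the choice

tissues:
  # Electrical properties at 128 MHz from the standard tissue dielectric
  # database (Gabriel parametric model / IT'IS compilation): conductivity
  # in S/m, relative permittivity dimensionless.
  - {tissue: gm,  code: 1, sigma: 0.59, eps_r: 73.5}
  - {tissue: wm,  code: 2, sigma: 0.34, eps_r: 52.5}
  - {tissue: csf, code: 3, sigma: 2.14, eps_r: 84.0}

correction:
  # Tissue-specific factors repairing the systematic underestimation of
  # B1+-only SAR (B1- and Bz unmeasurable by MRI), derived from ensembles
  # of anatomical models with full-field reference simulations.
  - {tissue: gm,  code: 1, sar_factor: 3.08, sar10g_factor: 2.11}
  - {tissue: wm,  code: 2, sar_factor: 1.79, sar10g_factor: 2.06}
  - {tissue: csf, code: 3, sar_factor: 2.59, sar10g_factor: 1.95}

filters:
  ept:                     # Savitzky-Golay kernel for the phase Laplacian
    shape: cuboid
    size: 5                # 5x5x5 voxel footprint
    degree: 2
    weight: 0.05           # anatomical adaptation weight
  postprocess:             # reference-adapted conductivity smoothing
    shape: cube
    size: 10               # symmetric 11x11x11 footprint
    weight: 0.1
  efield:                  # kernel for the B1+ derivatives
    shape: ellipsoid
    size: 4                # semi-axis in voxels
    degree: 2
    weight: 0.05
  gaussian_sigma: 0.4      # voxels; SAR smoothing
  outlier_k: 9             # remove SAR voxels above mean + k*SD

pipeline: {}
  # Either NIfTI input paths:
  #   phase: phase.nii
  #   b1_magnitude: b1.nii
  #   labels: labels.nii
  #   reference: mprage.nii
  # or a synthetic phantom:
  #   phantom: {kind: brainlike}
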