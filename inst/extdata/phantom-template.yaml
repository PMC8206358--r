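# Phantom specification template for `vista simulate --spec <file>`.
# Keys mirror the arguments of vistar::phantom_spec(); omitted keys take
# the package defaults.  All lengths are nanometers.

field_shape: [2, 192, 192]   # (z, y, x) voxels
pixel_size_xy: 497           # nm per pixel in plane
z_step: 1000                 # nm between z slices
psf_fwhm_xy: 1000            # lateral PSF FWHM of the simulated optics
seed: 1                      # phantom RNG seed (identical spec => identical data)

background:
  gel_ch2_weight: 0.05       # smooth hydrogel CH2 crosstalk; 0 = deuterated gel
  water_oh_weight: 0.02      # uniform water O-H crosstalk; 0 = D2O

noise:
  model: poisson_gaussian    # or "gaussian" (read noise only)
  read_sigma: 0.01           # read-noise sd, intensity units
  photon_scale: 200          # counts per intensity unit (shot noise)

structures:                  # one entry per structure kind
  - kind: nucleus
    count: 6
    size_nm: 9000            # mean radius
    protein_density: 1.0     # relative CH3 intensity
    retention: 1.0           # fraction surviving homogenization
  - kind: vessel
    count: 3
    size_nm: 1500            # tube radius
    protein_density: 1.2
  - kind: soma
    count: 4
    size_nm: 6000            # blob radius (each soma carries a nucleus)
    protein_density: 0.8
  - kind: dendrite
    count: 6
    size_nm: 500             # filament half-width
    protein_density: 0.6
  - kind: chromosome_void
    count: 4
    size_nm: 2500            # low-density blob radius, carved from nuclei
    protein_density: 0.3     # must stay below the nucleus density
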