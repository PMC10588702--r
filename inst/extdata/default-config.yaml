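# Default simulation configuration: the labelled kidney phantom under mild
# internal pressure. All physics parameters live here; see the package
# vignette for the full table of defaults, units and ranges.
fixture:
  type: phantom          # phantom | icosphere | grid
  subdivision: 3         # icosphere refinement of the base surface
  tumor_fraction: 0.35   # tumor radius / organ radius
forces:
  k_spring: 50           # edge-spring stiffness (N/m)
  damping: 0.5           # velocity damping rate d (1/s); v <- v*(1 - d*dt)
  pressure: 10           # inflation pressure (N/m^2)
  offset_magnitude: 0    # interaction offset force (N), along inward normals
  dt: 0.01               # time step (s)
solver:
  iterations: 4          # Gauss-Seidel sweeps per step
  k_str: 0.9             # stretch stiffness in [0, 1]
  k_bend: 0.5            # bend stiffness in [0, 1]
  break_mode: relative   # tearing criterion: relative | absolute
  break_threshold: 0.4   # relative extension beyond which edges tear
steps: 200
seed: 1
frame_stride: 0          # OBJ frame export stride; 0 disables
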