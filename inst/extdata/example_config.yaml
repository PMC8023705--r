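# Example run configuration for the shieldens command-line front end.
# Exactly one current-density source: a bundle path or a model spec.
model:
  type: loop          # loop | vortex | benzene_like
  radius: 2.5         # bohr
  width: 0.6          # bohr
  strength: 1.0       # a.u. circulation per unit field
  tropicity: diatropic
nucleus: 1
component: zz         # xx/yy/zz/... or isotropic
grid:
  radial_accuracy: 1.0e-10
  angular_order: 194
  becke_k: 3
  size_adjust: true
output: shieldens_run
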