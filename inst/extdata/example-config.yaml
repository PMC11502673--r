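# Example pipeline configuration: a small synthetic cohort.
mode: generate
nScenes: 5
seed: 1
sceneSpec:
  nCompartments: 40
  polarization: 0.5
  seed: 1
channels:
  lysosome: LAMP1
  antigen: Ag
  nested: SNX5
threshold:
  method: otsu
  perSlice: false
  erodeIterations: 1
analysisRadius: 3.5
particleBounds: [0.10, 4.00]
binEdges: [6, 12]
minOverlap: 1
synapticPlane: actin-max
backgroundOffset: 0
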