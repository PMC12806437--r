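# Desk-scale additive-manufacturing fixture: static substrate slab with an
# ellipsoidal molten region translating through it, 48-cube grid, 10 time
# points, 18-degree wedges.
seed: 1
phantom:
  kind: melt_pool
  gridSize: 48
  nTimepoints: 10
simulate:
  framesPerRotation: 400
  rotations: 0.5
acquisition:
  nTimepoints: 10
  wedgeDeg: 18.0
  framesPerRotation: 400
  mode: streaming
scene:
  spatialGrid: 32
  temporalGrid: 10
  featureDim: 8
  mlpLayers: 2
  mlpWidth: 32
train:
  iterations: 300
  raysPerBatch: 128
  logEvery: 100
render:
  gridSize: 48
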