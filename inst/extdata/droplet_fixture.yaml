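# Desk-scale droplet-coalescence fixture: two bodies approach, merge and
# relax on a 32-cube grid over 8 time points, acquired as 18-degree wedges
# (10x temporal enhancement) from a continuous rotation at 400 frames per
# revolution.
seed: 1
phantom:
  kind: merging_droplets
  gridSize: 32
  nTimepoints: 8
simulate:
  framesPerRotation: 400
  rotations: 0.4
acquisition:
  nTimepoints: 8
  wedgeDeg: 18.0
  framesPerRotation: 400
  mode: streaming
scene:
  spatialGrid: 32
  temporalGrid: 8
  featureDim: 8
  mlpLayers: 2
  mlpWidth: 32
train:
  iterations: 300
  raysPerBatch: 128
  logEvery: 100
render:
  gridSize: 32
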