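# Example simulation: a small three-gear design (two mesh nets plus a
# predator) around a flat population, roughly 500 expected fish per gear.
params:
  theta1: 0.71
  theta2: 12.94
  theta3: 2.13
  theta4: 0.41
gears:
  G14:
    family: mesh
    mesh_size: 14
  G25:
    family: mesh
    mesh_size: 25
  GC:
    family: predator
population:
  "4": 40
  "6": 80
  "8": 120
  "10": 120
  "12": 100
  "14": 80
  "16": 60
  "18": 45
  "20": 35
  "22": 25
  "24": 15
  "26": 10
  "28": 6
  "30": 3
target_per_gear: 500
seed: 20260921
replicates: 3
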