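# SE1DCNN architecture for the leukemia-shaped problem (4 classes,
# 500 selected genes), per corruption parameter a.
dataset: leukemia
model: se1dcnn
k: 500
classes: 4
per_a:
  "1": {k1: 22, w1: 21, p1: 4, k2: 5,  w2: 21, p2: 4}
  "2": {k1: 17, w1: 21, p1: 4, k2: 5,  w2: 21, p2: 4}
  "3": {k1: 22, w1: 21, p1: 4, k2: 5,  w2: 21, p2: 4}
  "4": {k1: 9,  w1: 21, p1: 4, k2: 16, w2: 21, p2: 4}
  "5": {k1: 17, w1: 21, p1: 4, k2: 5,  w2: 21, p2: 4}
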