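# SESAE architecture for the leukemia-shaped problem (4 classes,
# 500 selected genes), per corruption parameter a.
dataset: leukemia
model: sesae
k: 500
classes: 4
per_a:
  "1": {hidden: [30, 30]}
  "2": {hidden: [30, 30]}
  "3": {hidden: [30, 30]}
  "4": {hidden: [30, 30]}
  "5": {hidden: [30, 30]}
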