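# SESAE architecture for the breast-cancer-shaped problem (2 classes,
# 500 selected genes), per corruption parameter a.
dataset: breast
model: sesae
k: 500
classes: 2
per_a:
  "1": {hidden: [50, 50]}
  "2": {hidden: [50, 50]}
  "3": {hidden: [50, 50]}
  "4": {hidden: [50, 50]}
  "5": {hidden: [50, 50]}
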