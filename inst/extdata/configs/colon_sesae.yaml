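# SESAE architecture for the colon-cancer-shaped problem (2 classes,
# 500 selected genes), per corruption parameter a.
dataset: colon
model: sesae
k: 500
classes: 2
per_a:
  "1": {hidden: [100, 100]}
  "2": {hidden: [100, 100]}
  "3": {hidden: [100, 100]}
  "4": {hidden: [100, 100]}
  "5": {hidden: [100, 100]}
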