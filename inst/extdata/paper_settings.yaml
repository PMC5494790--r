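# Published operating point of the three-class EEG classifier
strategy: oao
kernel:
  family: gaussian
  two_sigma_sq: 500
C: 5
epsilon: 0.001
window: 512
hop: 256
fs: 173.61
k_folds: 4
class_list: [A, D, E]
# Structure configs for the sequential strategies (root pair / root class);
# chosen here because the ictal class is the most separable one.
dag_structure: [A, E]
bt_structure: E
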