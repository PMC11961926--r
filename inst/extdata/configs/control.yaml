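# Control condition: identity scaling, no spine loss.
seed: 1
condition:
  name: control
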