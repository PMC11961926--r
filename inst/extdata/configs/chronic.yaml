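# Chronic stress: 16% loss of excitatory dendritic spines.
seed: 1
condition:
  name: chronic
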