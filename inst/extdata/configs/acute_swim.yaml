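# Acute forced-swim stress: recurrent current multipliers from the
# stressed/control EPSC amplitude ratios (NMDA 425/197, AMPA 98.8/58.6).
seed: 1
condition:
  name: acute_swim
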