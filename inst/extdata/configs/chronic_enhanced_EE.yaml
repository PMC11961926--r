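# Chronic stress (16% spine loss) with strengthened within-group E-E
# coupling under reinforced between-group inhibition: the competition
# demonstration. Strong same-selectivity excitatory coupling lets a subset
# of groups win and sustain delay-period firing while inhibitory neurons of
# the winning groups silence the rest, so measured capacity stays below the
# four structural groups.
seed: 1
network:
  p_connect:
    ie_between: 0.25
  weights:
    ie: 1.0
  synapse:
    g_NMDA_rec: 1.2
condition:
  name: chronic
  overrides:
    ee_scale: 3.0
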