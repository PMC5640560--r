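# Tc-99m principal emissions per decay (standard nuclear-data compilation
# values, rounded; minor lines below 0.1% yield lumped into nearby entries).
# type: photon | electron; energy in keV; yield = emissions per decay.
type,energy_keV,yield
photon,140.511,0.885
photon,18.367,0.0421
photon,18.251,0.0213
photon,20.619,0.0122
electron,119.467,0.0879
electron,121.426,0.0112
electron,137.468,0.0107
electron,15.3,0.0203
electron,2.17,1.10
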