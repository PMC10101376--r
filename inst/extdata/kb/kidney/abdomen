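# whole abdomen tissue on contrast CT
IntensityRange -400 2000
# mean cross-sectional area prior: confidence 0 at 100 cm^2 or less,
# rising linearly to 1.0 at 500 cm^2 or more
CrossSectionalArea 100cm2 0.0 500cm2 1.0
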