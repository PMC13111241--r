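# Standard sagittal body-segment proportion table (Winter-style dimensionless
# regression constants): segment length as fraction of stature, segment mass as
# fraction of body mass, centre-of-mass location as fraction of segment length
# from the proximal end, and radius of gyration about the segment COM as a
# fraction of segment length. The pelvis_trunk row carries the residual mass so
# that segment masses always sum exactly to body mass (mass_frac = NA).
# version: 1
segment,length_frac,mass_frac,com_frac,gyration_frac
foot,0.152,0.0145,0.500,0.475
shank,0.246,0.0465,0.433,0.302
thigh,0.245,0.1000,0.433,0.323
pelvis_trunk,0.288,NA,0.626,0.496
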