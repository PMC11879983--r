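# Anthropometric scaling fractions for the planar 7-segment skeleton.
# Winter-style regression table: per-segment mass as a fraction of body mass,
# segment length as a fraction of body height, center-of-mass distance from the
# proximal joint as a fraction of segment length, and radius of gyration about
# the center of mass as a fraction of segment length.  The head-arms-trunk
# (HAT) segment absorbs the mass remainder so that segment masses always sum
# to body mass; its tabulated fraction is listed for reference only.
segment,mass_frac,length_frac,com_frac,rog_frac
HAT,0.678,0.288,0.626,0.496
thigh,0.100,0.245,0.433,0.323
shank,0.0465,0.246,0.433,0.302
foot,0.0145,0.152,0.500,0.475
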