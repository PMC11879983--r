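# Foot-ground contact defaults (per contact point; heel and toe on each foot).
# stiffness N/m, damping s/m (velocity coefficient of the vertical force),
# friction (dimensionless), slip_vel m/s (tanh smoothing velocity of the
# friction law), pen_smooth m (softplus smoothing of penetration),
# force_smooth N (softplus floor keeping the vertical force non-negative).
parameter,value
stiffness,75000
damping,0.85
friction,1.0
slip_vel,0.1
pen_smooth,0.001
force_smooth,0.5
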