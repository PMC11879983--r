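# Hill-type muscle parameters for the 8 muscle groups of one leg (mirrored to
# 16).  Values follow the established planar 9-DOF sagittal gait model
# parameterization (documented substitutes; see the methods vignette).
# fmax N, lceopt m, width (force-length Gaussian width, dimensionless),
# vmax (optimal lengths / s), slack (series-elastic slack length, m),
# tau_act / tau_deact s.  Moment arms d_* in m, signed for the package's
# conventions: hip flexion +, knee flexion +, ankle dorsiflexion +; a positive
# arm means the muscle moment increases that joint angle; 0 = not spanned.
name,fmax,lceopt,width,vmax,slack,tau_act,tau_deact,d_hip,d_knee,d_ankle
iliopsoas,1500,0.102,0.56,10,0.142,0.01,0.04,0.050,0,0
glutei,3000,0.200,0.56,10,0.157,0.01,0.04,-0.062,0,0
hamstrings,3000,0.104,0.56,10,0.334,0.01,0.04,-0.072,0.034,0
rectus_femoris,1200,0.081,0.56,10,0.398,0.01,0.04,0.034,-0.050,0
vasti,7000,0.093,0.56,10,0.223,0.01,0.04,0,-0.042,0
gastrocnemius,3000,0.055,0.56,10,0.420,0.01,0.04,0,0.020,-0.053
soleus,8000,0.055,0.56,10,0.245,0.01,0.04,0,0,-0.053
tibialis_anterior,3000,0.082,0.56,10,0.317,0.01,0.04,0,0,0.037
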