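# Structural causal model for net metabolic power during walking in
# ambulatory children with cerebral palsy (GMFCS I-III).
#
# BrainInjury is the initial, unmeasured brain injury: it is the shared
# latent cause of the four neuromuscular impairments and cannot be
# conditioned on.  Walking speed is affected by the impairments and by
# body size/age, and itself affects only the gait pattern (GDI) and
# metabolic power.
#
# This graph is one reconstruction consistent with the published adjustment
# sets and text; it is not an author-supplied arrow list.

latent: BrainInjury

BrainInjury -> Spasticity
BrainInjury -> Strength
BrainInjury -> SMC
BrainInjury -> DMC

Sex -> Height
Sex -> Mass
Age -> Height
Age -> Mass
Height -> Mass

Age -> Spasticity
Age -> Strength
Age -> SMC
Age -> DMC
Height -> Spasticity
Height -> Strength
Height -> SMC
Height -> DMC
Mass -> Spasticity
Mass -> Strength
Mass -> SMC
Mass -> DMC

Spasticity -> Speed
Strength -> Speed
SMC -> Speed
DMC -> Speed
Age -> Speed
Height -> Speed
Mass -> Speed

Speed -> GDI
Spasticity -> GDI
Strength -> GDI
SMC -> GDI
DMC -> GDI
Age -> GDI
Height -> GDI
Mass -> GDI

GDI -> MetPower
Speed -> MetPower
Spasticity -> MetPower
Strength -> MetPower
SMC -> MetPower
DMC -> MetPower
Age -> MetPower
Height -> MetPower
Mass -> MetPower
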