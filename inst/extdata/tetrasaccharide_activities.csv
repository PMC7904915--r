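substrate,structure,specific_activity_u_mg,conversion_efficiency_pct
P4-4,dUA-GlcNAc6S-GlcA-GlcNS6S + dUA-GlcNAc6S-IdoA-GlcNS6S,<1,15.90
P4-5,dUA-GlcNS-GlcA-GlcNS6S + dUA-GlcNS-IdoA-GlcNS6S,3.98,9.37
P4-6,dUA-GlcNS6S-GlcA-GlcNS6S,24.22,34.68
P4-7,dUA2S-GlcNS6S-GlcA-GlcNS6S,49.12,100
P4-8,dUA2S-GlcNS6S-IdoA2S-GlcNS6S,79.49,100
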