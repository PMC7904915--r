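# Reference oligosaccharide structures in chain notation (see hp_fixtures()).
dUA-GlcNAc6S-GlcA-GlcNS6S  # P4-4a
dUA-GlcNAc6S-IdoA-GlcNS6S  # P4-4b
dUA-GlcNS-GlcA-GlcNS6S  # P4-5a
dUA-GlcNS-IdoA-GlcNS6S  # P4-5b
dUA-GlcNS6S-GlcA-GlcNS6S  # P4-6
dUA2S-GlcNS6S-GlcA-GlcNS6S  # P4-7
dUA2S-GlcNS6S-IdoA2S-GlcNS6S  # P4-8
GlcNS6S-GlcA-GlcNS3S6S-IdoA2S-GlcNS6S(OMe)  # fondaparinux
dUA-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S  # P8-4
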