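(Synergus_sp:130,(Ganaspis_sp:91.1,(Leptolamina_sp:85,(Trybliographa_sp:76.4,(((Leptopilina_heterotoma:12,Leptopilina_clavipes:12)12:8,Leptopilina_boulardi:20)20:40,(Rhoptromeris_sp:40,Trichoplasta_sp:40)40_22_59:20)60:16.4)76.4_55_100:8.6)85:6.1)91.1:38.9)130;
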