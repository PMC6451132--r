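compound,component,energy_kcal_mol,role
C45,PVF,-5.86,component
C45,Cyto,-5.45,component
C45,Gua,-8.42,component
C45,PVF-Cyto-Gua,-19.26,net
CL,PVF,-18.07,component
CL,Cyto,-5.17,component
CL,Gua,-8.68,component
CL,PVF-Cyto-Gua,-31.49,net
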