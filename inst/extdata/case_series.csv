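patient_id,metric,before,after,max_score
P1,fvi_percent,27.16,0.28,NA
P1,fvasi,5.7,0.7,NA
P1,vdlqi,11,3,42
P1,vitiqol,24,1,90
P2,fvi_percent,55.95,11.83,NA
P2,fvasi,5.1,1.3,NA
P2,vdlqi,17,14,42
P2,vitiqol,73,46,90
P3,fvi_percent,29.32,1.16,NA
P3,fvasi,4.4,0.2,NA
P3,vdlqi,40,7,42
P3,vitiqol,80,22,90
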