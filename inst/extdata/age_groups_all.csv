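side,site,age_group,n,mean_mm,sd_mm
right,lateral,young,56,3.468,0.420
right,lateral,middle_aged,70,3.271,0.338
right,lateral,older,47,3.312,0.374
right,lateral,retirement,59,3.481,0.376
right,middle,young,56,2.855,0.258
right,middle,middle_aged,70,2.909,0.266
right,middle,older,47,2.878,0.240
right,middle,retirement,59,2.869,0.243
right,medial,young,56,3.266,0.391
right,medial,middle_aged,70,3.273,0.359
right,medial,older,47,3.275,0.404
right,medial,retirement,59,3.464,0.450
left,lateral,young,56,3.434,0.408
left,lateral,middle_aged,70,3.269,0.391
left,lateral,older,47,3.331,0.323
left,lateral,retirement,59,3.439,0.391
left,middle,young,56,2.881,0.329
left,middle,middle_aged,70,2.952,0.269
left,middle,older,47,2.911,0.270
left,middle,retirement,59,2.854,0.305
left,medial,young,56,3.248,0.461
left,medial,middle_aged,70,3.324,0.351
left,medial,older,47,3.179,0.330
left,medial,retirement,59,3.436,0.446
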