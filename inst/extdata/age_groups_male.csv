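side,site,age_group,n,mean_mm,sd_mm
right,lateral,young,23,3.584,0.361
right,lateral,middle_aged,27,3.412,0.293
right,lateral,older,22,3.384,0.283
right,lateral,retirement,28,3.614,0.293
right,middle,young,23,2.855,0.281
right,middle,middle_aged,27,2.972,0.264
right,middle,older,22,2.927,0.267
right,middle,retirement,28,2.887,0.238
right,medial,young,23,3.361,0.403
right,medial,middle_aged,27,3.370,0.285
right,medial,older,22,3.427,0.437
right,medial,retirement,28,3.678,0.383
left,lateral,young,23,3.619,0.411
left,lateral,middle_aged,27,3.439,0.367
left,lateral,older,22,3.471,0.277
left,lateral,retirement,28,3.656,0.316
left,middle,young,23,2.960,0.351
left,middle,middle_aged,27,3.037,0.279
left,middle,older,22,2.950,0.271
left,middle,retirement,28,2.981,0.261
left,medial,young,23,3.464,0.432
left,medial,middle_aged,27,3.518,0.339
left,medial,older,22,3.241,0.338
left,medial,retirement,28,3.642,0.415
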