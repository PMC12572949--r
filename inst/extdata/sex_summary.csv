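side,site,sex,n,mean_mm,sd_mm
right,lateral,all,232,3.380,0.385
right,middle,all,232,2.880,0.252
right,medial,all,232,3.320,0.407
left,lateral,all,232,3.364,0.387
left,middle,all,232,2.902,0.294
left,medial,all,232,3.305,0.409
right,lateral,female,132,3.288,0.406
right,middle,female,132,2.856,0.243
right,medial,female,132,3.210,0.381
left,lateral,female,132,3.225,0.353
left,middle,female,132,2.839,0.284
left,medial,female,132,3.172,0.362
right,lateral,male,100,3.502,0.320
right,middle,male,100,2.911,0.262
right,medial,male,100,3.468,0.395
left,lateral,male,100,3.548,0.354
left,middle,male,100,2.984,0.288
left,medial,male,100,3.479,0.404
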