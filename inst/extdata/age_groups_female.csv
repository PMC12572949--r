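side,site,age_group,n,mean_mm,sd_mm
right,lateral,young,33,3.387,0.444
right,lateral,middle_aged,43,3.182,0.337
right,lateral,older,25,3.249,0.435
right,lateral,retirement,31,3.361,0.406
right,middle,young,33,2.856,0.246
right,middle,middle_aged,43,2.870,0.262
right,middle,older,25,2.835,0.209
right,middle,retirement,31,2.853,0.249
right,medial,young,33,3.201,0.375
right,medial,middle_aged,43,3.212,0.389
right,medial,older,25,3.142,0.327
right,medial,retirement,31,3.271,0.422
left,lateral,young,33,3.305,0.358
left,lateral,middle_aged,43,3.162,0.371
left,lateral,older,25,3.208,0.315
left,lateral,retirement,31,3.242,0.348
left,middle,young,33,2.826,0.306
left,middle,middle_aged,43,2.899,0.251
left,middle,older,25,2.878,0.270
left,middle,retirement,31,2.739,0.299
left,medial,young,33,3.098,0.425
left,medial,middle_aged,43,3.201,0.304
left,medial,older,25,3.125,0.320
left,medial,retirement,31,3.250,0.392
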