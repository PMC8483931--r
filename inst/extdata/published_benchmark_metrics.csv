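image_id,method,psnr_db,ssim
a,ldct,25.375,0.768
b,ldct,24.653,0.731
c,ldct,24.987,0.763
d,ldct,23.826,0.711
e,ldct,30.145,0.863
f,ldct,27.836,0.792
g,ldct,26.834,0.723
h,ldct,26.214,0.719
i,ldct,22.245,0.712
a,wgan,28.346,0.912
b,wgan,26.398,0.892
c,wgan,29.321,0.924
d,wgan,27.873,0.865
e,wgan,32.146,0.962
f,wgan,30.124,0.845
g,wgan,29.834,0.835
h,wgan,30.013,0.862
i,wgan,26.215,0.821
a,red_cnn,28.783,0.921
b,red_cnn,29.012,0.901
c,red_cnn,30.876,0.932
d,red_cnn,28.987,0.912
e,red_cnn,31.273,0.920
f,red_cnn,30.023,0.823
g,red_cnn,29.867,0.844
h,red_cnn,29.839,0.843
i,red_cnn,27.831,0.873
a,proposed,30.245,0.942
b,proposed,29.374,0.911
c,proposed,31.238,0.953
d,proposed,30.872,0.934
e,proposed,31.698,0.925
f,proposed,30.836,0.912
g,proposed,31.345,0.902
h,proposed,31.314,0.909
i,proposed,30.134,0.901
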