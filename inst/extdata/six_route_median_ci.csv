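route_id,group,lower,upper
X1,X,0.034,0.037
X2,X,0.036,0.038
X3,X,0.006,0.013
Y1,Y,0.004,0.019
Y2,Y,0.025,0.034
Y3,Y,0.038,0.057
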