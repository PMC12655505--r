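tissue,volume_l,flow_l_h,fw,fnl,fph
adipose,14.5,19.5,0.18,0.79,0.002
bone,5.0,16.0,0.43,0.074,0.0011
brain,1.45,46.0,0.77,0.051,0.0565
gut,1.65,60.0,0.77,0.0487,0.0163
heart,0.33,18.0,0.76,0.0115,0.0166
kidney,0.31,70.0,0.78,0.0207,0.0162
liver,1.80,19.0,0.74,0.0348,0.0252
lung,0.53,390.0,0.79,0.003,0.009
muscle,28.0,66.0,0.76,0.0238,0.0072
skin,2.60,22.0,0.72,0.0284,0.0111
spleen,0.19,11.0,0.78,0.0201,0.0198
reproductive,0.035,0.2,0.80,0.018,0.010
rest,3.0,42.3,0.76,0.040,0.010
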