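rat_id,group,day,injection,stage,se
s1,sham,1,1,V,TRUE
s1,sham,2,1,V,FALSE
s1,sham,3,1,I,FALSE
s1,sham,3,2,I,FALSE
s1,sham,3,3,I,FALSE
s1,sham,3,4,I,FALSE
s2,sham,1,1,II,FALSE
s2,sham,1,2,V,FALSE
s2,sham,2,1,V,FALSE
s2,sham,3,1,I,FALSE
s2,sham,3,2,V,FALSE
s3,sham,1,1,II,FALSE
s3,sham,1,2,V,TRUE
s3,sham,2,1,I,FALSE
s3,sham,2,2,II,FALSE
s3,sham,2,3,II,FALSE
s3,sham,2,4,I,FALSE
s3,sham,3,1,I,FALSE
s3,sham,3,2,I,FALSE
s3,sham,3,3,I,FALSE
s3,sham,3,4,I,FALSE
s4,sham,1,1,V,FALSE
s4,sham,2,1,V,FALSE
s4,sham,3,1,V,FALSE
s5,sham,1,1,V,TRUE
s5,sham,2,1,I,FALSE
s5,sham,2,2,I,FALSE
s5,sham,2,3,I,FALSE
s5,sham,2,4,I,FALSE
s5,sham,3,1,V,TRUE
s6,sham,1,1,V,FALSE
s6,sham,2,1,V,FALSE
s6,sham,3,1,V,FALSE
s7,sham,1,1,V,FALSE
s7,sham,2,1,V,FALSE
s7,sham,3,1,V,TRUE
s8,sham,1,1,V,TRUE
s8,sham,2,1,I,FALSE
s8,sham,2,2,V,FALSE
s8,sham,3,1,I,FALSE
s8,sham,3,2,I,FALSE
s8,sham,3,3,II,FALSE
s8,sham,3,4,V,FALSE
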