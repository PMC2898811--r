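cell_id,y,count
c01,1,2
c02,1,3
c02,2,1
c03,1,2
c04,1,1
c05,1,8
c05,2,4
c05,3,2
c06,1,3
c06,2,1
c07,1,2
c08,1,1
c09,1,2
c09,2,1
c10,1,2
c11,1,1
c12,1,3
c12,2,1
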