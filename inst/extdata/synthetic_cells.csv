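cell_id,population,x,y
c01,800,0,0
c02,1000,1,0
c03,900,2,0
c04,700,3,0
c05,1200,0,1
c06,1100,1,1
c07,950,2,1
c08,600,3,1
c09,1000,0,2
c10,850,1,2
c11,750,2,2
c12,1300,3,2
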