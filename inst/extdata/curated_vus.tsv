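gene	hgvs	inheritance	log2fc	criteria
CACNA1F	NM_001256789.3:c.4009-3C>G	XL	2.7	PM2, BP4
CDH23	NM_022124.5:c.4231G>A	AR	2.0	PM2, PP3
CDHR1	NM_001171971.3:c.1589C>G	AR	2.6	PM1, PM2, BP1
COL11A1	NM_080629.2:c.4838C>A	AD	1.6	PM2, PP2
GDF6	NM_001001557.4:c.125G>T	AR_AD	2.0	PM1, PM2, PP5, BP6
IMPG2	NM_016247.4:c.1460A>T	AR_AD	2.7	PM2, BP4
MERTK	NM_006343.3:c.2435A>G	AR	2.0	PM1, PM2, PP3, BP6
NYX	NM_022567.2:c.505A>G	XL	2.9	PM2
OFD1	NM_003611.2:c.87T>G	XL	2.7	PM2, PP3, BP1
RP1	NM_006269.2:c.2497T>C	AR_AD	1.7	PM2, BP4
WFS1	NM_001145853.1:c.1597C>T	AR_AD	3.7	PM2, PP3
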