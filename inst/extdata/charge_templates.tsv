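resname	atom	charge	radius
DN	P	-1.0000	1.90
DN	O1	0.0000	1.52
DN	C1	0.0000	1.70
DN	N1	0.0000	1.55
DN	B1	0.0000	1.70
RU	P	-0.9000	1.90
RU	O1	-0.2000	1.52
RU	C1	0.1000	1.70
RU	N1	-0.1000	1.55
RU	B1	0.1000	1.70
RU	B2	0.0000	1.70
C	P	-0.9000	1.90
C	O1	-0.1500	1.52
C	C1	0.0500	1.70
C	N1	-0.2000	1.55
C	B1	0.2000	1.70
C	B2	0.0000	1.70
ARG	NH1	1.0000	2.00
LYS	NZ	1.0000	2.00
ASP	OD1	-1.0000	1.80
GLU	OE1	-1.0000	1.80
GLY	CA	0.0000	1.80
ION	C1	0.0000	2.00
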