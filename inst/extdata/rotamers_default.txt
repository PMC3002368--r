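# Default backbone-independent rotamer library (idealized canonical bins).
# Synthetic stand-in for statistical rotamer libraries: chi angles sit on
# the classical g+/t/g- wells (aromatic chi2 on +/-90 degrees).
# Format: RES chi1 [chi2 [chi3 [chi4 [chi5]]]]  (degrees)
# LYS rows omit chi4 (defaulted to 180); ARG rows omit chi4/chi5 (180/0).
SER 60
SER 180
SER -60
CYS 60
CYS 180
CYS -60
THR 60
THR 180
THR -60
VAL 60
VAL 180
VAL -60
ILE 60 60
ILE 60 180
ILE 60 -60
ILE 180 60
ILE 180 180
ILE 180 -60
ILE -60 60
ILE -60 180
ILE -60 -60
LEU 60 60
LEU 60 180
LEU 60 -60
LEU 180 60
LEU 180 180
LEU 180 -60
LEU -60 60
LEU -60 180
LEU -60 -60
MET 60 60 60
MET 60 60 180
MET 60 60 -60
MET 60 180 60
MET 60 180 180
MET 60 180 -60
MET 60 -60 60
MET 60 -60 180
MET 60 -60 -60
MET 180 60 60
MET 180 60 180
MET 180 60 -60
MET 180 180 60
MET 180 180 180
MET 180 180 -60
MET 180 -60 60
MET 180 -60 180
MET 180 -60 -60
MET -60 60 60
MET -60 60 180
MET -60 60 -60
MET -60 180 60
MET -60 180 180
MET -60 180 -60
MET -60 -60 60
MET -60 -60 180
MET -60 -60 -60
ASP 60 60
ASP 60 180
ASP 60 -60
ASP 180 60
ASP 180 180
ASP 180 -60
ASP -60 60
ASP -60 180
ASP -60 -60
ASN 60 60
ASN 60 180
ASN 60 -60
ASN 180 60
ASN 180 180
ASN 180 -60
ASN -60 60
ASN -60 180
ASN -60 -60
GLU 60 60 60
GLU 60 60 180
GLU 60 60 -60
GLU 60 180 60
GLU 60 180 180
GLU 60 180 -60
GLU 60 -60 60
GLU 60 -60 180
GLU 60 -60 -60
GLU 180 60 60
GLU 180 60 180
GLU 180 60 -60
GLU 180 180 60
GLU 180 180 180
GLU 180 180 -60
GLU 180 -60 60
GLU 180 -60 180
GLU 180 -60 -60
GLU -60 60 60
GLU -60 60 180
GLU -60 60 -60
GLU -60 180 60
GLU -60 180 180
GLU -60 180 -60
GLU -60 -60 60
GLU -60 -60 180
GLU -60 -60 -60
GLN 60 60 60
GLN 60 60 180
GLN 60 60 -60
GLN 60 180 60
GLN 60 180 180
GLN 60 180 -60
GLN 60 -60 60
GLN 60 -60 180
GLN 60 -60 -60
GLN 180 60 60
GLN 180 60 180
GLN 180 60 -60
GLN 180 180 60
GLN 180 180 180
GLN 180 180 -60
GLN 180 -60 60
GLN 180 -60 180
GLN 180 -60 -60
GLN -60 60 60
GLN -60 60 180
GLN -60 60 -60
GLN -60 180 60
GLN -60 180 180
GLN -60 180 -60
GLN -60 -60 60
GLN -60 -60 180
GLN -60 -60 -60
LYS 60 60 60
LYS 60 60 180
LYS 60 60 -60
LYS 60 180 60
LYS 60 180 180
LYS 60 180 -60
LYS 60 -60 60
LYS 60 -60 180
LYS 60 -60 -60
LYS 180 60 60
LYS 180 60 180
LYS 180 60 -60
LYS 180 180 60
LYS 180 180 180
LYS 180 180 -60
LYS 180 -60 60
LYS 180 -60 180
LYS 180 -60 -60
LYS -60 60 60
LYS -60 60 180
LYS -60 60 -60
LYS -60 180 60
LYS -60 180 180
LYS -60 180 -60
LYS -60 -60 60
LYS -60 -60 180
LYS -60 -60 -60
ARG 60 60 60
ARG 60 60 180
ARG 60 60 -60
ARG 60 180 60
ARG 60 180 180
ARG 60 180 -60
ARG 60 -60 60
ARG 60 -60 180
ARG 60 -60 -60
ARG 180 60 60
ARG 180 60 180
ARG 180 60 -60
ARG 180 180 60
ARG 180 180 180
ARG 180 180 -60
ARG 180 -60 60
ARG 180 -60 180
ARG 180 -60 -60
ARG -60 60 60
ARG -60 60 180
ARG -60 60 -60
ARG -60 180 60
ARG -60 180 180
ARG -60 180 -60
ARG -60 -60 60
ARG -60 -60 180
ARG -60 -60 -60
HIS 60 90
HIS 60 -90
HIS 180 90
HIS 180 -90
HIS -60 90
HIS -60 -90
PHE 60 90
PHE 60 -90
PHE 180 90
PHE 180 -90
PHE -60 90
PHE -60 -90
TYR 60 90
TYR 60 -90
TYR 180 90
TYR 180 -90
TYR -60 90
TYR -60 -90
TRP 60 90
TRP 60 -90
TRP 180 90
TRP 180 -90
TRP -60 90
TRP -60 -90
PRO 30
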