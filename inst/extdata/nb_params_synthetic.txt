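# Synthetic united-atom non-bonded parameter table (stand-in for a
# statistical force field; element-based Lennard-Jones wells, simplified
# partial charges). Columns: RES ATOM q A_half B_half eps.
# Pairwise combination: A_ij = A_i*A_j, B_ij = B_i*B_j,
# eps_ij = sqrt(eps_i*eps_j); LJ pair term = eps_ij*(A_ij/r^12 - B_ij/r^6).
ALA N    -0.300   1291.46797  50.82259 0.170
ALA CA    0.250   2736.71526  73.98264 0.100
ALA C     0.550   2736.71526  73.98264 0.100
ALA O    -0.500    481.89030  31.04482 0.210
ALA CB    0.000   2736.71526  73.98264 0.100
ARG N    -0.300   1291.46797  50.82259 0.170
ARG CA    0.250   2736.71526  73.98264 0.100
ARG C     0.550   2736.71526  73.98264 0.100
ARG O    -0.500    481.89030  31.04482 0.210
ARG CB    0.000   2736.71526  73.98264 0.100
ARG CG    0.000   2736.71526  73.98264 0.100
ARG CD    0.000   2736.71526  73.98264 0.100
ARG NE   -0.400   1291.46797  50.82259 0.170
ARG CZ    0.500   2736.71526  73.98264 0.100
ARG NH1   0.450   1291.46797  50.82259 0.170
ARG NH2   0.450   1291.46797  50.82259 0.170
ASN N    -0.300   1291.46797  50.82259 0.170
ASN CA    0.250   2736.71526  73.98264 0.100
ASN C     0.550   2736.71526  73.98264 0.100
ASN O    -0.500    481.89030  31.04482 0.210
ASN CB    0.000   2736.71526  73.98264 0.100
ASN CG    0.550   2736.71526  73.98264 0.100
ASN OD1  -0.550    481.89030  31.04482 0.210
ASN ND2   0.000   1291.46797  50.82259 0.170
ASP N    -0.300   1291.46797  50.82259 0.170
ASP CA    0.250   2736.71526  73.98264 0.100
ASP C     0.550   2736.71526  73.98264 0.100
ASP O    -0.500    481.89030  31.04482 0.210
ASP CB    0.000   2736.71526  73.98264 0.100
ASP CG    0.500   2736.71526  73.98264 0.100
ASP OD1  -0.750    481.89030  31.04482 0.210
ASP OD2  -0.750    481.89030  31.04482 0.210
CYS N    -0.300   1291.46797  50.82259 0.170
CYS CA    0.250   2736.71526  73.98264 0.100
CYS C     0.550   2736.71526  73.98264 0.100
CYS O    -0.500    481.89030  31.04482 0.210
CYS CB    0.100   2736.71526  73.98264 0.100
CYS SG   -0.100   2565.72641  71.63416 0.250
GLN N    -0.300   1291.46797  50.82259 0.170
GLN CA    0.250   2736.71526  73.98264 0.100
GLN C     0.550   2736.71526  73.98264 0.100
GLN O    -0.500    481.89030  31.04482 0.210
GLN CB    0.000   2736.71526  73.98264 0.100
GLN CG    0.000   2736.71526  73.98264 0.100
GLN CD    0.550   2736.71526  73.98264 0.100
GLN OE1  -0.550    481.89030  31.04482 0.210
GLN NE2   0.000   1291.46797  50.82259 0.170
GLU N    -0.300   1291.46797  50.82259 0.170
GLU CA    0.250   2736.71526  73.98264 0.100
GLU C     0.550   2736.71526  73.98264 0.100
GLU O    -0.500    481.89030  31.04482 0.210
GLU CB    0.000   2736.71526  73.98264 0.100
GLU CG    0.000   2736.71526  73.98264 0.100
GLU CD    0.500   2736.71526  73.98264 0.100
GLU OE1  -0.750    481.89030  31.04482 0.210
GLU OE2  -0.750    481.89030  31.04482 0.210
GLY N    -0.300   1291.46797  50.82259 0.170
GLY CA    0.250   2736.71526  73.98264 0.100
GLY C     0.550   2736.71526  73.98264 0.100
GLY O    -0.500    481.89030  31.04482 0.210
HIS N    -0.300   1291.46797  50.82259 0.170
HIS CA    0.250   2736.71526  73.98264 0.100
HIS C     0.550   2736.71526  73.98264 0.100
HIS O    -0.500    481.89030  31.04482 0.210
HIS CB    0.000   2736.71526  73.98264 0.100
HIS CG    0.100   2736.71526  73.98264 0.100
HIS ND1  -0.300   1291.46797  50.82259 0.170
HIS CD2   0.000   2736.71526  73.98264 0.100
HIS CE1   0.400   2736.71526  73.98264 0.100
HIS NE2  -0.200   1291.46797  50.82259 0.170
ILE N    -0.300   1291.46797  50.82259 0.170
ILE CA    0.250   2736.71526  73.98264 0.100
ILE C     0.550   2736.71526  73.98264 0.100
ILE O    -0.500    481.89030  31.04482 0.210
ILE CB    0.000   2736.71526  73.98264 0.100
ILE CG1   0.000   2736.71526  73.98264 0.100
ILE CG2   0.000   2736.71526  73.98264 0.100
ILE CD1   0.000   2736.71526  73.98264 0.100
LEU N    -0.300   1291.46797  50.82259 0.170
LEU CA    0.250   2736.71526  73.98264 0.100
LEU C     0.550   2736.71526  73.98264 0.100
LEU O    -0.500    481.89030  31.04482 0.210
LEU CB    0.000   2736.71526  73.98264 0.100
LEU CG    0.000   2736.71526  73.98264 0.100
LEU CD1   0.000   2736.71526  73.98264 0.100
LEU CD2   0.000   2736.71526  73.98264 0.100
LYS N    -0.300   1291.46797  50.82259 0.170
LYS CA    0.250   2736.71526  73.98264 0.100
LYS C     0.550   2736.71526  73.98264 0.100
LYS O    -0.500    481.89030  31.04482 0.210
LYS CB    0.000   2736.71526  73.98264 0.100
LYS CG    0.000   2736.71526  73.98264 0.100
LYS CD    0.000   2736.71526  73.98264 0.100
LYS CE    0.250   2736.71526  73.98264 0.100
LYS NZ    0.750   1291.46797  50.82259 0.170
MET N    -0.300   1291.46797  50.82259 0.170
MET CA    0.250   2736.71526  73.98264 0.100
MET C     0.550   2736.71526  73.98264 0.100
MET O    -0.500    481.89030  31.04482 0.210
MET CB    0.000   2736.71526  73.98264 0.100
MET CG    0.000   2736.71526  73.98264 0.100
MET SD    0.000   2565.72641  71.63416 0.250
MET CE    0.000   2736.71526  73.98264 0.100
PHE N    -0.300   1291.46797  50.82259 0.170
PHE CA    0.250   2736.71526  73.98264 0.100
PHE C     0.550   2736.71526  73.98264 0.100
PHE O    -0.500    481.89030  31.04482 0.210
PHE CB    0.000   2736.71526  73.98264 0.100
PHE CG    0.000   2736.71526  73.98264 0.100
PHE CD1   0.000   2736.71526  73.98264 0.100
PHE CD2   0.000   2736.71526  73.98264 0.100
PHE CE1   0.000   2736.71526  73.98264 0.100
PHE CE2   0.000   2736.71526  73.98264 0.100
PHE CZ    0.000   2736.71526  73.98264 0.100
PRO N    -0.300   1291.46797  50.82259 0.170
PRO CA    0.250   2736.71526  73.98264 0.100
PRO C     0.550   2736.71526  73.98264 0.100
PRO O    -0.500    481.89030  31.04482 0.210
PRO CB    0.000   2736.71526  73.98264 0.100
PRO CG    0.000   2736.71526  73.98264 0.100
PRO CD    0.000   2736.71526  73.98264 0.100
SER N    -0.300   1291.46797  50.82259 0.170
SER CA    0.250   2736.71526  73.98264 0.100
SER C     0.550   2736.71526  73.98264 0.100
SER O    -0.500    481.89030  31.04482 0.210
SER CB    0.250   2736.71526  73.98264 0.100
SER OG   -0.250    481.89030  31.04482 0.210
THR N    -0.300   1291.46797  50.82259 0.170
THR CA    0.250   2736.71526  73.98264 0.100
THR C     0.550   2736.71526  73.98264 0.100
THR O    -0.500    481.89030  31.04482 0.210
THR CB    0.250   2736.71526  73.98264 0.100
THR OG1  -0.250    481.89030  31.04482 0.210
THR CG2   0.000   2736.71526  73.98264 0.100
TRP N    -0.300   1291.46797  50.82259 0.170
TRP CA    0.250   2736.71526  73.98264 0.100
TRP C     0.550   2736.71526  73.98264 0.100
TRP O    -0.500    481.89030  31.04482 0.210
TRP CB    0.000   2736.71526  73.98264 0.100
TRP CG    0.000   2736.71526  73.98264 0.100
TRP CD1   0.100   2736.71526  73.98264 0.100
TRP CD2   0.000   2736.71526  73.98264 0.100
TRP NE1  -0.100   1291.46797  50.82259 0.170
TRP CE2   0.000   2736.71526  73.98264 0.100
TRP CE3   0.000   2736.71526  73.98264 0.100
TRP CZ2   0.000   2736.71526  73.98264 0.100
TRP CZ3   0.000   2736.71526  73.98264 0.100
TRP CH2   0.000   2736.71526  73.98264 0.100
TYR N    -0.300   1291.46797  50.82259 0.170
TYR CA    0.250   2736.71526  73.98264 0.100
TYR C     0.550   2736.71526  73.98264 0.100
TYR O    -0.500    481.89030  31.04482 0.210
TYR CB    0.000   2736.71526  73.98264 0.100
TYR CG    0.000   2736.71526  73.98264 0.100
TYR CD1   0.000   2736.71526  73.98264 0.100
TYR CD2   0.000   2736.71526  73.98264 0.100
TYR CE1   0.000   2736.71526  73.98264 0.100
TYR CE2   0.000   2736.71526  73.98264 0.100
TYR CZ    0.250   2736.71526  73.98264 0.100
TYR OH   -0.250    481.89030  31.04482 0.210
VAL N    -0.300   1291.46797  50.82259 0.170
VAL CA    0.250   2736.71526  73.98264 0.100
VAL C     0.550   2736.71526  73.98264 0.100
VAL O    -0.500    481.89030  31.04482 0.210
VAL CB    0.000   2736.71526  73.98264 0.100
VAL CG1   0.000   2736.71526  73.98264 0.100
VAL CG2   0.000   2736.71526  73.98264 0.100
* OXT  -0.500    481.89030  31.04482 0.210
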