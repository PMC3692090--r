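# Executable modification templates.
#
# Each template is an ordered atom-edit plan against its target residue
# building block.  Directives:
#   target  RES            target residue (or NTER:RES for an N-terminal
#                          modification of residue RES)
#   product XXX            3-letter product residue code
#   delete  NAME           remove an atom (and its bonds)
#   rename  OLD NEW        rename an atom in place
#   set     NAME TYPE Q    re-type / re-charge an existing atom
#   add     NAME TYPE Q  REF_BOND REF_ANGLE REF_DIHEDRAL  R THETA PHI
#                          place a new atom by internal coordinates
#                          (nm / degrees); a bond NAME-REF_BOND is implied
#
# Geometry uses ideal bond lengths/angles from standard chemical tables;
# charges are documented placeholders in united-atom style.  Additions are
# topologically ordered: every reference atom exists after the prior steps.
#
# Product codes: wwPDB chemical-component codes where they exist (SEP, TPO,
# PTR, ALY, MLZ, MLY, M3L, HYP, CGU, NIY, CSO, AYA; deamidation products are
# canonical ASP/GLU); codes marked "registry-local" in reactions.tsv are
# package-local inventions.

[template phos_ser]
target SER
product SEP
delete HG
set CB CH2 0.000
set OG OA -0.360
add P   P   0.560  OG CB CA  0.161 119.0 180.0
add O1P OM -0.734  P  OG CB  0.148 109.5  60.0
add O2P OM -0.733  P  OG CB  0.148 109.5 -60.0
add O3P OM -0.733  P  OG CB  0.148 109.5 180.0

[template phos_thr]
target THR
product TPO
delete HG1
set CB CH1 0.000
set OG1 OA -0.360
add P   P   0.560  OG1 CB CA  0.161 119.0 180.0
add O1P OM -0.734  P  OG1 CB  0.148 109.5  60.0
add O2P OM -0.733  P  OG1 CB  0.148 109.5 -60.0
add O3P OM -0.733  P  OG1 CB  0.148 109.5 180.0

[template phos_tyr]
target TYR
product PTR
delete HH
set CZ C 0.000
set OH OA -0.360
add P   P   0.560  OH CZ CE1  0.161 119.0 180.0
add O1P OM -0.734  P  OH CZ   0.148 109.5  60.0
add O2P OM -0.733  P  OH CZ   0.148 109.5 -60.0
add O3P OM -0.733  P  OH CZ   0.148 109.5 180.0

[template acet_lys]
target LYS
product ALY
delete HZ1
delete HZ2
delete HZ3
set CE CH2 0.000
set NZ NT -0.280
add HZ H    0.280  NZ CE CD  0.100 118.0   0.0
add CX C    0.380  NZ CE CD  0.133 122.0 180.0
add OX O   -0.380  CX NZ CE  0.123 122.0   0.0
add CY CH3  0.000  CX NZ CE  0.153 115.0 180.0

[template meth_lys_mono]
target LYS
product MLZ
delete HZ1
add CM1 CH3 0.248  NZ CE CD  0.147 109.5 180.0

[template meth_lys_di]
target LYS
product MLY
delete HZ1
delete HZ2
add CM1 CH3 0.248  NZ CE CD  0.147 109.5 180.0
add CM2 CH3 0.248  NZ CE CD  0.147 109.5  60.0

[template meth_lys_tri]
target LYS
product M3L
delete HZ1
delete HZ2
delete HZ3
add CM1 CH3 0.248  NZ CE CD  0.147 109.5 180.0
add CM2 CH3 0.248  NZ CE CD  0.147 109.5  60.0
add CM3 CH3 0.248  NZ CE CD  0.147 109.5 -60.0

# chained entries: a second/third methylation applied to an already
# modified (re-uploaded) residue
[template meth_mlz_di]
target MLZ
product MLY
delete HZ2
add CM2 CH3 0.248  NZ CE CD  0.147 109.5  60.0

[template meth_mly_tri]
target MLY
product M3L
delete HZ3
add CM3 CH3 0.248  NZ CE CD  0.147 109.5 -60.0

[template meth_arg]
target ARG
product RME
delete HH11
add CM CH3 0.240  NH1 CZ NE  0.147 120.0   0.0

[template hydroxy_pro]
target PRO
product HYP
set CG CH1 0.150
add OD1 OA -0.548  CG CB CA  0.143 109.5 -150.0
add HD1 H   0.398  OD1 CG CB 0.100 109.5 180.0

[template carboxy_glu]
target GLU
product CGU
rename CD CD1
set CG CH1 0.000
add CD2 C   0.270  CG  CB CA  0.153 109.5 -60.0
add OE3 OM -0.635  CD2 CG CB  0.125 120.0   0.0
add OE4 OM -0.635  CD2 CG CB  0.125 120.0 180.0

[template nitro_tyr]
target TYR
product NIY
set CE1 C 0.000
add NN  NT  0.400  CE1 CD1 CG  0.145 120.0 180.0
add ON1 OM -0.200  NN  CE1 CD1 0.122 120.0   0.0
add ON2 OM -0.200  NN  CE1 CD1 0.122 120.0 180.0

[template carbonyl_lys]
target LYS
product KCA
delete NZ
delete HZ1
delete HZ2
delete HZ3
set CE C 0.380
add OE O -0.380  CE CD CG  0.123 121.0   0.0

[template carbonyl_arg]
target ARG
product RCA
delete NE
delete HE
delete CZ
delete NH1
delete HH11
delete HH12
delete NH2
delete HH21
delete HH22
set CD C 0.380
add OE1 O -0.380  CD CG CB  0.123 121.0   0.0

[template carbonyl_pro]
target PRO
product PCB
set CD C 0.380
add OD1 O -0.380  CD CG CB  0.123 126.0 120.0

[template carbonyl_thr]
target THR
product TCA
delete HG1
set CB C 0.380
set OG1 O -0.380

[template deamid_asn]
target ASN
product ASP
delete HD21
delete HD22
rename ND2 OD2
set CG C 0.270
set OD1 OM -0.635
set OD2 OM -0.635

[template deamid_gln]
target GLN
product GLU
delete HE21
delete HE22
rename NE2 OE2
set CD C 0.270
set OE1 OM -0.635
set OE2 OM -0.635

# reverse of deamidation: lets re-uploaded products be amidated back
[template amid_asp]
target ASP
product ASN
set CG C 0.380
set OD1 O -0.380
rename OD2 ND2
set ND2 NT -0.830
add HD21 H 0.415  ND2 CG CB  0.100 120.0   0.0
add HD22 H 0.415  ND2 CG CB  0.100 120.0 180.0

[template amid_glu]
target GLU
product GLN
set CD C 0.380
set OE1 O -0.380
rename OE2 NE2
set NE2 NT -0.830
add HE21 H 0.415  NE2 CD CG  0.100 120.0   0.0
add HE22 H 0.415  NE2 CD CG  0.100 120.0 180.0

[template oxid_met]
target MET
product MOX
set SD S 0.080
add OD1 O -0.380  SD CG CB  0.150 107.0  60.0

[template oxid_cys]
target CYS
product CSO
delete HG
set SG S 0.100
add OD OA -0.498  SG CB CA  0.165 100.0 180.0
add HD H   0.398  OD SG CB  0.100 109.5 180.0

[template nterm_acet_ala]
target NTER:ALA
product AYA
add CX C    0.380  N  CA C   0.133 122.0   0.0
add OX O   -0.380  CX N  CA  0.123 122.0   0.0
add CY CH3  0.000  CX N  CA  0.153 115.0 180.0
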