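# United-atom molecular-mechanics parameter table.
#
# Functional forms (documented choice; GROMOS-like magnitudes, simplified
# forms): harmonic bonds E = 0.5*kb*(b-b0)^2, harmonic angles
# E = 0.5*kt*(theta-theta0)^2 (theta in radians), proper dihedrals
# E = kp*(1 + cos(n*phi - phis)), Lennard-Jones 12-6 with sigma/epsilon
# combination by arithmetic/geometric (Lorentz-Berthelot) rules, plain
# Coulomb with a hard cutoff.  These are documented placeholder parameters:
# gradient correctness, not parameter fidelity, is the tested contract.
#
# Lookup rules (implemented in the package):
#   bonds:     exact type pair first, then element-class pair ("class" rows)
#   angles:    exact triple first, then center-type wildcard (X ti X)
#   dihedrals: exact central type pair first, then wildcard (X X)

[atomtypes]
# type   mass      sigma(nm) epsilon(kJ/mol)
C        12.0110   0.336     0.40
CH1      13.0190   0.400     0.30
CH2      14.0270   0.400     0.40
CH3      15.0350   0.375     0.70
CR1      13.0190   0.364     0.50
N        14.0067   0.324     0.64
NT       14.0067   0.324     0.64
NL       14.0067   0.324     0.64
NR       14.0067   0.324     0.64
NE       14.0067   0.324     0.64
NZ       14.0067   0.324     0.64
O        15.9994   0.263     1.00
OA       15.9994   0.295     0.85
OM       15.9994   0.263     1.00
S        32.0600   0.355     1.00
P        30.9738   0.374     1.50
H         1.0080   0.000     0.00

[bondtypes]
# ti    tj    b0(nm)  kb(kJ/mol/nm^2)
C       O     0.123   25000
C       OM    0.125   25000
C       N     0.133   25000
C       NT    0.133   25000
C       NR    0.138   25000
CR1     NR    0.133   25000
C       CR1   0.139   25000
CR1     CR1   0.139   25000
P       OM    0.148   25000
P       OA    0.161   25000
S       O     0.150   25000
S       OA    0.165   25000
class C C     0.153   25000
class C N     0.147   25000
class C O     0.143   25000
class C S     0.178   25000
class N H     0.100   25000
class O H     0.100   25000
class S H     0.133   25000

[angletypes]
# ti   tj    tk   theta0(deg) kt(kJ/mol/rad^2)
OM     C     OM   126.0       300
OM     P     OM   109.5       300
X      CH1   X    109.5       300
X      CH2   X    111.0       300
X      N     X    120.0       300
X      NT    X    120.0       300
X      NL    X    109.5       300
X      NR    X    108.0       300
X      NE    X    120.0       300
X      NZ    X    120.0       300
X      C     X    120.0       300
X      CR1   X    120.0       300
X      OA    X    109.5       300
X      OM    X    120.0       300
X      O     X    120.0       300
X      S     X    100.0       300
X      P     X    109.5       300

[dihedraltypes]
# ti   tj    phis(deg)  n  kp(kJ/mol)
C      N     180        2  33.5
C      NT    180        2  33.5
C      NR    180        2  20.0
C      NZ    180        2  20.0
C      NE    180        2  20.0
C      CR1   180        2  20.0
CR1    CR1   180        2  20.0
CR1    NR    180        2  20.0
# backbone phi (N-CA central bond; measured as C(-1)-N-CA-C): minima at 0
# and +-120 deg, so the generator's extended conformation is a torsional
# minimum.  The CA-C bond's representative dihedral (N-CA-C-O) already has
# its minimum at the generator's value under the generic term.
N      CH1   180        3  8.0
N      CH2   180        3  8.0
X      X     0          3  8.0

[impropertypes]
# applied to every 3-coordinated sp2 center (types listed); harmonic
# out-of-plane term E = 0.5*kxi*(xi - xi0)^2, xi the i-j-k-l dihedral with
# the center second (this dihedral is +-180 deg for a planar group, and the
# deviation is wrapped, so both signs count as planar)
# sp2types   xi0(deg)  kxi(kJ/mol/rad^2)
planar C N NT NE NZ NR CR1   180.0   160

[pairs14]
# third-neighbour (1-4) Lennard-Jones softening, GROMOS-style reduced
# short-range parameters; Coulomb stays at full strength
# sigma_scale  epsilon_scale
scale 0.85 0.50

[coulomb]
# effective relative dielectric for in-vacuo work: emulates the screening
# otherwise provided by solvent; bare vacuum charges drive slow
# hydrogen-bond collapse cascades during minimization
# epsilon_r
dielectric 4.0
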