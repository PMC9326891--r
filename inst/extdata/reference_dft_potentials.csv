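species,method_tag,protocol,potential_V,sd_V
A,PBEOP,static_direct,1.12,NA
C,PBEOP,static_direct,1.53,NA
G,PBEOP,static_direct,0.85,NA
T,PBEOP,static_direct,1.54,NA
U,PBEOP,static_direct,1.90,NA
A,PBEOP,cycle1,1.10,NA
C,PBEOP,cycle1,1.69,NA
G,PBEOP,cycle1,0.58,NA
T,PBEOP,cycle1,2.07,NA
U,PBEOP,cycle1,2.62,NA
A,PBEOP,cycle2,1.11,NA
C,PBEOP,cycle2,1.72,NA
G,PBEOP,cycle2,0.58,NA
T,PBEOP,cycle2,2.04,NA
U,PBEOP,cycle2,2.62,NA
A,PBEOP,dynamic_direct_implicit,1.14,0.22
C,PBEOP,dynamic_direct_implicit,1.74,0.50
G,PBEOP,dynamic_direct_implicit,0.86,0.24
T,PBEOP,dynamic_direct_implicit,1.59,0.18
U,PBEOP,dynamic_direct_implicit,1.98,0.22
A,PBEOP,dynamic_direct_explicit,0.17,1.26
C,PBEOP,dynamic_direct_explicit,1.35,1.74
G,PBEOP,dynamic_direct_explicit,0.29,1.78
T,PBEOP,dynamic_direct_explicit,0.40,1.38
U,PBEOP,dynamic_direct_explicit,0.76,1.36
A,PBEOP,dynamic_marcus_implicit,1.13,0.07
C,PBEOP,dynamic_marcus_implicit,1.74,0.28
G,PBEOP,dynamic_marcus_implicit,0.78,0.07
T,PBEOP,dynamic_marcus_implicit,1.55,0.07
U,PBEOP,dynamic_marcus_implicit,1.88,0.06
A,PBEOP,dynamic_marcus_explicit,1.54,0.66
C,PBEOP,dynamic_marcus_explicit,2.27,0.83
G,PBEOP,dynamic_marcus_explicit,1.34,0.75
T,PBEOP,dynamic_marcus_explicit,2.08,0.63
U,PBEOP,dynamic_marcus_explicit,2.39,0.70
A,M06-2X,static_direct,1.72,NA
C,M06-2X,static_direct,2.41,NA
G,M06-2X,static_direct,1.41,NA
T,M06-2X,static_direct,2.05,NA
U,M06-2X,static_direct,2.39,NA
A,M06-2X,cycle1,1.72,NA
C,M06-2X,cycle1,2.15,NA
G,M06-2X,cycle1,1.12,NA
T,M06-2X,cycle1,2.64,NA
U,M06-2X,cycle1,3.28,NA
A,M06-2X,cycle2,1.73,NA
C,M06-2X,cycle2,2.50,NA
G,M06-2X,cycle2,1.13,NA
T,M06-2X,cycle2,2.64,NA
U,M06-2X,cycle2,3.28,NA
A,M06-2X,dynamic_direct_implicit,1.80,0.24
C,M06-2X,dynamic_direct_implicit,2.20,0.32
G,M06-2X,dynamic_direct_implicit,1.41,0.27
T,M06-2X,dynamic_direct_implicit,2.08,0.18
U,M06-2X,dynamic_direct_implicit,2.35,0.19
A,M06-2X,dynamic_direct_explicit,1.02,1.41
C,M06-2X,dynamic_direct_explicit,1.69,1.74
G,M06-2X,dynamic_direct_explicit,0.46,1.75
T,M06-2X,dynamic_direct_explicit,1.11,1.55
U,M06-2X,dynamic_direct_explicit,1.14,1.45
A,M06-2X,dynamic_marcus_implicit,1.72,0.09
C,M06-2X,dynamic_marcus_implicit,2.33,0.07
G,M06-2X,dynamic_marcus_implicit,1.37,0.08
T,M06-2X,dynamic_marcus_implicit,2.08,0.09
U,M06-2X,dynamic_marcus_implicit,2.41,0.09
A,M06-2X,dynamic_marcus_explicit,2.21,0.66
C,M06-2X,dynamic_marcus_explicit,2.96,0.73
G,M06-2X,dynamic_marcus_explicit,1.82,0.67
T,M06-2X,dynamic_marcus_explicit,2.69,0.69
U,M06-2X,dynamic_marcus_explicit,2.91,0.73
A,B3LYP,static_direct,1.47,NA
C,B3LYP,static_direct,2.28,NA
G,B3LYP,static_direct,1.17,NA
T,B3LYP,static_direct,1.87,NA
U,B3LYP,static_direct,2.22,NA
A,B3LYP,cycle1,1.47,NA
C,B3LYP,cycle1,1.64,NA
G,B3LYP,cycle1,0.90,NA
T,B3LYP,cycle1,2.40,NA
U,B3LYP,cycle1,3.05,NA
A,B3LYP,cycle2,1.48,NA
C,B3LYP,cycle2,2.05,NA
G,B3LYP,cycle2,0.91,NA
T,B3LYP,cycle2,2.40,NA
U,B3LYP,cycle2,3.05,NA
A,B3LYP,dynamic_direct_implicit,1.52,0.25
C,B3LYP,dynamic_direct_implicit,2.05,0.28
G,B3LYP,dynamic_direct_implicit,1.19,0.26
T,B3LYP,dynamic_direct_implicit,1.93,0.16
U,B3LYP,dynamic_direct_implicit,2.21,0.20
A,B3LYP,dynamic_direct_explicit,0.45,1.24
C,B3LYP,dynamic_direct_explicit,1.36,1.73
G,B3LYP,dynamic_direct_explicit,2.31,1.78
T,B3LYP,dynamic_direct_explicit,3.50,1.30
U,B3LYP,dynamic_direct_explicit,3.06,1.30
A,B3LYP,dynamic_marcus_implicit,1.46,0.07
C,B3LYP,dynamic_marcus_implicit,2.02,0.06
G,B3LYP,dynamic_marcus_implicit,1.11,0.09
T,B3LYP,dynamic_marcus_implicit,1.89,0.09
U,B3LYP,dynamic_marcus_implicit,2.21,0.07
A,B3LYP,dynamic_marcus_explicit,1.85,0.61
C,B3LYP,dynamic_marcus_explicit,2.64,0.73
G,B3LYP,dynamic_marcus_explicit,1.28,0.65
T,B3LYP,dynamic_marcus_explicit,2.22,0.67
U,B3LYP,dynamic_marcus_explicit,2.54,0.71
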