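species,slope,hpd_lower,hpd_upper
Acleris maccana,0.21,0.17,0.25
Ancylis myrtillana,0.60,0.55,0.65
Ancylis unguicella,1.52,1.27,1.77
Argyresthia svenssoni,0.28,0.002,0.53
Bryotropha galbanella,0.33,0.20,0.47
Chionodes continuellus,0.19,0.13,0.26
Chionodes nubilellus,0.09,-0.08,0.31
Clepsis senecionana,1.63,1.37,1.88
Coleophora glitzella,0.55,0.40,0.69
Coleophora idaeella,0.54,0.25,0.82
Coleophora vacciniella,0.73,0.52,1.01
Denisia similella,0.30,0.21,0.38
Denisia stipella,0.08,0.03,0.15
Dystroma citratum,0.08,-0.008,0.18
Eana osseana,1.61,1.51,1.70
Ectoedemia weaveri,0.46,0.36,0.59
Elachista parasella,0.01,-0.16,0.18
Elophos vittarius,0.44,0.32,0.56
Entephria caesiata,0.27,0.24,0.29
Epinotia maculana,0.35,0.24,0.46
Epinotia solandriana,0.12,-0.006,0.32
Epirrita autumnata,0.37,0.36,0.39
Eudonia murana,0.51,0.30,0.69
Eulia ministrana,0.07,-0.12,0.27
Eulithis populata,0.53,0.49,0.56
Eulithis testata,0.61,0.38,0.87
Eupithecia pusillata,0.35,0.20,0.48
Hellinsia tephradactyla,-0.04,-0.34,0.29
Incurvaria vetulella,0.10,-0.02,0.23
Lithomoia solidaginis,0.58,0.51,0.65
Mompha idaei,0.23,-0.01,0.44
Mompha locupletella,0.02,-0.15,0.19
Monopis laevigella,0.27,-0.12,0.62
Monopis spilotella,0.56,0.27,0.85
Nemapogon cloacellus,-0.15,-0.39,0.11
Neofaculta infernella,-0.07,-0.20,0.05
Operophtera brumata,0.34,0.26,0.42
Paraswammerdamia conspersella,0.55,0.52,0.58
Phiaris bipunctana,1.45,1.21,1.67
Phiaris heinrichana,0.43,0.30,0.57
Phiaris obsoletana,0.64,0.58,0.70
Phiaris palustrana,1.03,0.85,1.19
Phiaris schulziana,-0.50,-0.55,-0.45
Pleurota bicostella,0.55,0.47,0.62
Poecilocampa populi,-0.19,-0.29,-0.01
Pseudatemelia josephinae,-0.17,-0.38,0.06
Scopula ternata,0.42,0.32,0.53
Selenia dentaria,0.30,0.14,0.46
Sparganothis rubicundana,0.80,0.67,0.92
Stigmella lapponica,0.71,0.45,0.94
Syngrapha interrogationis,-0.23,-0.36,-0.11
Taleboria borealis,0.44,0.24,0.64
Thera obeliscata,0.42,0.24,0.62
Trichiura crataegi,-0.07,-0.27,0.14
Xanthorhoe decoloraria,-0.07,-0.24,0.01
Ypsolopha parenthesella,0.22,0.09,0.37
Zeiraphera griseana,0.42,0.26,0.59
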