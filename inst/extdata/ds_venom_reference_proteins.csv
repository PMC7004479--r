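accession,protein_name,family,thailand_pct,indonesia_pct
P00990,Kunitz-type serine protease inhibitor 2,KSPI,1.4,
A8Y7P5,Kunitz-type serine protease inhibitor B5,KSPI,0.66,
A8Y7P6,Kunitz-type serine protease inhibitor B6,KSPI,1.93,
A8Y7N4,Kunitz-type serine protease inhibitor C1,KSPI,8.43,
A8Y7N5,Kunitz-type serine protease inhibitor C2,KSPI,0.81,
A8Y7N7,Kunitz-type serine protease inhibitor C4,KSPI,3.75,
A8Y7N9,Kunitz-type serine protease inhibitor C6,KSPI,5.04,
H6VC06,Kunitz-type serine protease inhibitor DrKIn-II,KSPI,0.36,
A8CG86,Acidic phospholipase A2 Drk-a1,PLA2,,4.95
P31100,Acidic phospholipase A2 RV-7,PLA2,21.27,17.12
B3RFI7,Basic phospholipase A2,PLA2,12.63,21.41
P00617,Basic phospholipase A2 beta-bungarotoxin A1 chain,PLA2,0.1,
Q02471,Basic phospholipase A2 RV-4,PLA2,0.1,
B2YHV5,Phospholipase A2,PLA2,1.13,
P86529,Phospholipase A2 1,PLA2,2.69,4.89
CL290.Contig28_NnSL,Factor X activator light chain 1,snaclec,1.58,
K9JDJ1,Factor X activator light chain 2,snaclec,0.25,
K9JBU9,P31 alpha subunit,snaclec,0.19,
CL1101.Contig2_DrSL,P31 alpha subunit,snaclec,3.54,
K9JBV3,P31 beta subunit,snaclec,0.35,
K9JDF6,P31 beta subunit,snaclec,0.23,
K9JBV0,P68 alpha subunit,snaclec,1.01,
K9JDF2,P68 alpha subunit,snaclec,,0.44
CL2900.Contig2_NnSL,P68 alpha subunit,snaclec,0.03,
A0A2H4Z2X7,RVV-X light chain 1,snaclec,1.35,
Q4PRD0,Snaclec 3,snaclec,0.32,0.09
Q4PRC9,Snaclec 4,snaclec,0.02,
Q4PRD1,Snaclec coagulation factor X-activating enzyme light chain 1,snaclec,1.38,0.21
Q4PRD2,Snaclec coagulation factor X-activating enzyme light chain 2,snaclec,0.38,0.29
E5L0E3,Alpha-fibrinogenase-like,SVSP,0.95,0.47
E0Y419,Beta-fibrinogenase,SVSP,1.41,
E5L0E4,Beta-fibrinogenase-like,SVSP,3.22,0.18
P18965,Factor V activator RVV-V gamma,SVSP,5.11,4.5
Unigene26743_DrSL,Factor V activator RVV-V gamma,SVSP,0.32,
Unigene26743_EsM,Factor V activator RVV-V gamma,SVSP,,1.54
CL3102.Contig2_NnSL,RVV-V gamma-like protein precursor,SVSP,0.31,0.04
CL2958.Contig2_DrSL,Serine beta-fibrinogenase,SVSP,0.4,3.97
CL310.Contig24_NnSL,Serine protease VLSP-1,SVSP,0.32,
E0Y420,Serine protease VLSP-3,SVSP,4.27,0.34
Q9PT40,Venom serine proteinase-like protein 2,SVSP,1.76,11.37
Q7LZ61,Coagulation factor X-activating enzyme heavy chain,SVMP,3.04,1.83
T1P647,Factor X activator light chain 2,SVMP,,0.32
G8XQX1,L-amino-acid oxidase,LAAO,,0.53
P0C2D7,L-amino-acid oxidase,LAAO,,0.94
P67861,Snake venom vascular endothelial growth factor toxin VR-1,svVEGF,2.46,
P0DL42,Snake venom vascular endothelial growth factor toxin VR-1',svVEGF,2.96,
V9I1K1,Venom nerve growth factor 1,svNGF,0.52,0.85
U3T7C6,5'-nucleotidase,5NUC,0.54,
W8EFS0,5'-nucleotidase,5NUC,0.39,
CL3322.Contig1_DrSL,Snake venom 5'-nucleotidase,5NUC,,0.18
CL3322.Contig2_DrSL,Snake venom 5'-nucleotidase,5NUC,0.39,
CL2941.Contig2_EcSL,Snake venom 5'-nucleotidase OS,5NUC,0.53,
U3TBJ5,Phosphodiesterase,PDE,0.08,0.6
CL3655.Contig2_DrSL,Phosphodiesterase 1,PDE,0.08,0.29
Q7ZZM2,Disintegrin jerdostatin,DIS,,6.21
(unidentified),Unidentified proteins,,,16.44
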