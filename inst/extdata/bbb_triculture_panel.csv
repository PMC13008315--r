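casrn,compound,papp_ab_1e6,sd_ab_1e6,ab_censored,papp_ba_1e6,sd_ba_1e6,ba_censored,er_printed,er_censored,rate_printed
22083-74-5,DL-Nicotine,0.08,0.01,FALSE,0.08,0.04,FALSE,0.98,FALSE,Slow
89-25-8,Edaravone,0.41,0.13,FALSE,0.25,0.16,FALSE,0.61,FALSE,Slow
52-53-9,Verapamil,0.57,0.02,FALSE,1.0,0.14,FALSE,1.75,FALSE,Slow
88-99-3,Phthalic acid,0.75,0.19,FALSE,0.59,0.05,FALSE,0.79,FALSE,Slow
1222998-36-8,Torin 1,2.2,0.07,FALSE,1.3,0.6,FALSE,0.56,FALSE,Moderate
103-90-2,Acetaminophen,3.7,0.64,FALSE,2.3,0.5,FALSE,0.62,FALSE,Moderate
19216-56-9,Prazosin,3.7,0.8,FALSE,7.0,1.8,FALSE,1.88,FALSE,Moderate
53230-10-7,Mefloquine,4.7,0.1,FALSE,36.9,4.4,FALSE,7.81,FALSE,Moderate
50-23-7,Hydrocortisone,4.8,2.5,FALSE,1.3,0.6,FALSE,0.26,FALSE,Moderate
259793-96-9,Favipiravir,5.2,2.4,FALSE,4.4,1.7,FALSE,0.83,FALSE,Moderate
535-80-8,3-Chlorobenzoic acid,5.6,0.6,FALSE,3.1,0.6,FALSE,0.55,FALSE,Moderate
123-31-9,Hydroquinone,7.2,3.5,FALSE,10.0,3.9,FALSE,1.38,FALSE,Moderate
84-66-2,Diethyl phthalate,7.7,1.1,FALSE,7.2,1.6,FALSE,0.94,FALSE,Moderate
88321-09-9,Aloxistatin,8.1,0.8,FALSE,6.6,0.4,FALSE,0.81,FALSE,Moderate
2628280-40-8,Nirmatrelvir,8.5,0.1,FALSE,6.9,0.2,FALSE,0.81,FALSE,Moderate
551-16-6,6-Aminopenicillic acid,10.6,1.6,FALSE,16.3,1.9,FALSE,1.54,FALSE,Moderate
298-46-4,Carbamazepine,12.2,1.3,FALSE,10.9,0.4,FALSE,0.90,FALSE,Fast
60-92-4,"Adenosine 3',5'-cyclic monophosphate (cAMP)",12.4,2.8,FALSE,13.0,2.8,FALSE,1.04,FALSE,Fast
15686-71-2,Cephalexin,12.7,3.3,FALSE,25.8,2.5,FALSE,2.03,FALSE,Fast
5786-21-0,Clozapine,13.4,1.2,FALSE,12.0,1.5,FALSE,0.89,FALSE,Fast
579-75-9,2-Methoxybenzoic acid,13.4,1.5,FALSE,10.5,0.6,FALSE,0.78,FALSE,Fast
2492423-29-5,Molnupiravir,13.4,0.1,FALSE,10.7,0.9,FALSE,0.80,FALSE,Fast
51-28-5,"2,4-Dinitrophenol",13.5,0.7,FALSE,11.3,1.5,FALSE,0.84,FALSE,Fast
2798-05-2,"4,4'-Methylenebis(phenyl isothiocyanate)",13.5,3.9,FALSE,9.8,3.1,FALSE,0.73,FALSE,Fast
120-83-2,"2,4-Dichlorophenol",13.6,2.2,FALSE,13.5,3.0,FALSE,0.99,FALSE,Fast
54910-89-3,Fluoxetine,14.4,4.7,FALSE,20.1,3.6,FALSE,1.4,FALSE,Fast
57-41-0,Phenytoin,15.1,2.8,FALSE,14.6,2.2,FALSE,0.96,FALSE,Fast
118-92-3,Anthranilic acid,15.9,1.6,FALSE,12.2,0.77,FALSE,0.77,FALSE,Fast
58-08-2,Caffeine,16.6,1.7,FALSE,10.6,2.3,FALSE,0.64,FALSE,Fast
na,BisMetPtNH2,17.4,1.5,FALSE,22.9,3.5,FALSE,1.31,FALSE,Fast
67-20-9,Nitrofurantoin,18.3,0.6,FALSE,23.5,1.3,FALSE,1.28,FALSE,Fast
414864-00-9,Belinostat,18.8,3.6,FALSE,0.07,0.01,FALSE,0.004,FALSE,Fast
4044-65-9,"1,4-Phenylene diisothiocyanate",20.0,3.0,FALSE,6.6,1.8,FALSE,0.33,FALSE,Fast
105650-23-5,"2-Amino-1-methyl-6-phenylimidazo[4,5-b]pyridine",20.7,6.0,FALSE,14.6,3.0,FALSE,0.70,FALSE,Fast
54-64-8,Thimerosal,20.8,2.2,FALSE,19.4,1.6,FALSE,0.93,FALSE,Fast
4685-14-7,Paraquat,21.9,3.7,FALSE,20.6,7.0,FALSE,0.94,FALSE,Fast
80-05-7,Bisphenol A,22.9,6.7,FALSE,28.5,1.8,FALSE,1.24,FALSE,Fast
101-26-8,Pyridostigmine Bromide,23.0,3.4,FALSE,14.0,7.6,FALSE,0.61,FALSE,Fast
987-78-0,Cytidine 5'-diphosphocholine,25.9,3.0,FALSE,37.5,0.7,FALSE,1.45,FALSE,Fast
118-91-2,2-Chlorobenzoic acid,28.7,5.5,FALSE,26.6,3.8,FALSE,0.93,FALSE,Fast
2474-72-8,Hydroxyquinone,29.9,3.4,FALSE,9.3,0.5,FALSE,0.31,FALSE,Fast
636-00-0,6-Hydroxydopamine hydrobromide,31.3,3.9,FALSE,10.8,1.9,FALSE,0.34,FALSE,Fast
na,BisMetPt,33.9,4.0,FALSE,36.0,2.6,FALSE,1.06,FALSE,Fast
6998-60-3,Rifamycin SV,45.9,2.1,FALSE,29.9,7.6,FALSE,0.65,FALSE,Fast
150-76-5,Methoxyphenol,54.8,11.1,FALSE,37.6,10.2,FALSE,0.69,FALSE,Fast
10265-92-6,Methanidophos,56.1,7.7,FALSE,18.3,11.9,FALSE,0.33,FALSE,Fast
99-66-1,Valproic acid,500,NA,TRUE,117,14,FALSE,0.24,TRUE,Very fast
43121-43-3,Triadimefon,500,NA,TRUE,149,14,FALSE,0.30,TRUE,Very fast
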