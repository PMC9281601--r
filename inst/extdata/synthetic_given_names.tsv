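name	sex	weight
MARIA	F	1
ANA	F	0.535887
FRANCISCA	F	0.372041
ANTONIA	F	0.287175
ADRIANA	F	0.234924
JULIANA	F	0.199372
MARCIA	F	0.173545
FERNANDA	F	0.153893
PATRICIA	F	0.138415
ALINE	F	0.125893
SANDRA	F	0.115544
CAMILA	F	0.106841
AMANDA	F	0.099415
BRUNA	F	0.093
JESSICA	F	0.087401
LETICIA	F	0.082469
JULIA	F	0.07809
LUCIANA	F	0.074175
VANESSA	F	0.070652
MARIANA	F	0.067464
GABRIELA	F	0.064566
VERA	F	0.061918
VITORIA	F	0.05949
LARISSA	F	0.057255
CLAUDIA	F	0.055189
BEATRIZ	F	0.053275
LUANA	F	0.051496
SIMONE	F	0.049838
RAFAELA	F	0.048288
ROSANGELA	F	0.046837
CRISTIANE	F	0.045475
ANDREIA	F	0.044194
DANIELA	F	0.042987
TEREZA	F	0.041847
MICHELE	F	0.04077
CARLA	F	0.039749
DEBORA	F	0.038781
SONIA	F	0.037861
ELIANE	F	0.036986
NATALIA	F	0.036153
RITA	F	0.035359
REGINA	F	0.0346
APARECIDA	F	0.033875
JOANA	F	0.033181
CAROLINA	F	0.032517
HELENA	F	0.03188
ISABEL	F	0.031269
LUZIA	F	0.030682
ROSA	F	0.030118
CONCEICAO	F	0.029575
SEBASTIANA	F	0.029053
IRACEMA	F	0.028549
JOSEFA	F	0.028064
RAIMUNDA	F	0.027596
EDNA	F	0.027144
MARTA	F	0.026707
SUELI	F	0.026285
TATIANE	F	0.025877
PRISCILA	F	0.025482
KELLY	F	0.025099
VIVIANE	F	0.024729
SABRINA	F	0.02437
MONICA	F	0.024021
ROSELI	F	0.023683
SILVANA	F	0.023355
ELAINE	F	0.023036
CINTIA	F	0.022727
DENISE	F	0.022425
IVONE	F	0.022133
NEUSA	F	0.021848
MARINA	F	0.021571
LAURA	F	0.021301
ALICE	F	0.021038
CLARA	F	0.020782
CECILIA	F	0.020533
LIVIA	F	0.020289
RENATA	F	0.020052
TALITA	F	0.019821
INGRID	F	0.019595
PAMELA	F	0.019374
MIRIAN	F	0.019159
SOLANGE	F	0.018948
MARLENE	F	0.018743
NAIR	F	0.018542
ZILDA	F	0.018345
DALVA	F	0.018153
IVANA	F	0.017965
TANIA	F	0.017781
ELZA	F	0.017601
NILDA	F	0.017425
JOSE	M	1
JOAO	M	0.535887
ANTONIO	M	0.372041
FRANCISCO	M	0.287175
CARLOS	M	0.234924
PAULO	M	0.199372
PEDRO	M	0.173545
LUCAS	M	0.153893
LUIZ	M	0.138415
MARCOS	M	0.125893
LUIS	M	0.115544
GABRIEL	M	0.106841
RAFAEL	M	0.099415
DANIEL	M	0.093
MARCELO	M	0.087401
BRUNO	M	0.082469
EDUARDO	M	0.07809
FELIPE	M	0.074175
RAIMUNDO	M	0.070652
RODRIGO	M	0.067464
MANOEL	M	0.064566
MATEUS	M	0.061918
ANDRE	M	0.05949
FERNANDO	M	0.057255
FABIO	M	0.055189
LEONARDO	M	0.053275
GUSTAVO	M	0.051496
GUILHERME	M	0.049838
LEANDRO	M	0.048288
TIAGO	M	0.046837
SEBASTIAO	M	0.045475
MARCIO	M	0.044194
DIEGO	M	0.042987
RICARDO	M	0.041847
VITOR	M	0.04077
ALEXANDRE	M	0.039749
EDSON	M	0.038781
ANDERSON	M	0.037861
JORGE	M	0.036986
ROBERTO	M	0.036153
ADRIANO	M	0.035359
WELLINGTON	M	0.0346
SERGIO	M	0.033875
CLAUDIO	M	0.033181
GERALDO	M	0.032517
ROGERIO	M	0.03188
SAMUEL	M	0.031269
JOAQUIM	M	0.030682
DOMINGOS	M	0.030118
RENATO	M	0.029575
MIGUEL	M	0.029053
VINICIUS	M	0.028549
FLAVIO	M	0.028064
OSVALDO	M	0.027596
JULIO	M	0.027144
CESAR	M	0.026707
BENEDITO	M	0.026285
MAURICIO	M	0.025877
OTAVIO	M	0.025482
ROBSON	M	0.025099
MOISES	M	0.024729
DAVI	M	0.02437
JAIR	M	0.024021
WASHINGTON	M	0.023683
ELIAS	M	0.023355
EMERSON	M	0.023036
JACKSON	M	0.022727
RONALDO	M	0.022425
ALAN	M	0.022133
JEFERSON	M	0.021848
IGOR	M	0.021571
HUGO	M	0.021301
NELSON	M	0.021038
WILSON	M	0.020782
WALTER	M	0.020533
ARTHUR	M	0.020289
HEITOR	M	0.020052
ABRAAO	M	0.019821
CAIO	M	0.019595
DOUGLAS	M	0.019374
EVERTON	M	0.019159
GILBERTO	M	0.018948
HELIO	M	0.018743
ISAAC	M	0.018542
IVAN	M	0.018345
LAZARO	M	0.018153
NATAN	M	0.017965
ORLANDO	M	0.017781
RUBENS	M	0.017601
SALOMAO	M	0.017425
VALDIR	M	0.017253
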