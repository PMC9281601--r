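surname	weight
SILVA	1
SANTOS	0.535887
OLIVEIRA	0.372041
SOUZA	0.287175
RODRIGUES	0.234924
FERREIRA	0.199372
ALVES	0.173545
PEREIRA	0.153893
LIMA	0.138415
GOMES	0.125893
COSTA	0.115544
RIBEIRO	0.106841
MARTINS	0.099415
CARVALHO	0.093
ALMEIDA	0.087401
LOPES	0.082469
SOARES	0.07809
FERNANDES	0.074175
VIEIRA	0.070652
BARBOSA	0.067464
ROCHA	0.064566
DIAS	0.061918
NASCIMENTO	0.05949
ANDRADE	0.057255
MOREIRA	0.055189
NUNES	0.053275
MARQUES	0.051496
MACHADO	0.049838
MENDES	0.048288
FREITAS	0.046837
CARDOSO	0.045475
RAMOS	0.044194
GONCALVES	0.042987
SANTANA	0.041847
TEIXEIRA	0.04077
ARAUJO	0.039749
MELO	0.038781
BARROS	0.037861
PINTO	0.036986
MONTEIRO	0.036153
MOURA	0.035359
BATISTA	0.0346
CAMPOS	0.033875
CORREIA	0.033181
JESUS	0.032517
MIRANDA	0.03188
CASTRO	0.031269
SALES	0.030682
DUARTE	0.030118
AZEVEDO	0.029575
CUNHA	0.029053
QUEIROZ	0.028549
REIS	0.028064
MORAES	0.027596
BORGES	0.027144
MEDEIROS	0.026707
NOGUEIRA	0.026285
TAVARES	0.025877
AGUIAR	0.025482
XAVIER	0.025099
FARIAS	0.024729
BEZERRA	0.02437
SIQUEIRA	0.024021
LEAL	0.023683
PAIVA	0.023355
BRITO	0.023036
MAGALHAES	0.022727
SAMPAIO	0.022425
ASSIS	0.022133
GUIMARAES	0.021848
MOTA	0.021571
NEVES	0.021301
VASCONCELOS	0.021038
PACHECO	0.020782
REZENDE	0.020533
FONSECA	0.020289
CAVALCANTE	0.020052
MAIA	0.019821
BRAGA	0.019595
PRADO	0.019374
VALE	0.019159
AMORIM	0.018948
COELHO	0.018743
BUENO	0.018542
FOGACA	0.018345
VARGAS	0.018153
LEMOS	0.017965
PIRES	0.017781
MESQUITA	0.017601
SERRA	0.017425
BITTENCOURT	0.017253
DANTAS	0.017084
ESTEVES	0.016919
FRANCO	0.016757
GALVAO	0.016598
HOLANDA	0.016442
JARDIM	0.016289
LACERDA	0.01614
MACEDO	0.015993
NEGREIROS	0.015849
OTONI	0.015708
PORTELA	0.015569
QUADROS	0.015433
RANGEL	0.015299
SEABRA	0.015168
TELES	0.015039
URIBE	0.014913
VILELA	0.014788
ZANETTI	0.014666
ABREU	0.014546
BENTO	0.014428
CHAVES	0.014312
DOMINGUES	0.014198
EVANGELISTA	0.014086
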