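# synthetic_curve.14c -- synthetic radiocarbon calibration curve
# (not a measured atmospheric record; for examples and tests)
# cal BP, 14C age BP, 1-sigma error
4000,4000.0,15
4010,4012.5,15
4020,4025.0,15
4030,4037.4,15
4040,4049.6,15
4050,4061.8,15
4060,4073.7,15
4070,4085.4,15
4080,4096.9,15
4090,4108.1,15
4100,4119.0,15
4110,4129.6,15
4120,4140.0,15
4130,4150.0,15
4140,4159.6,15
4150,4169.0,15
4160,4178.1,15
4170,4186.9,15
4180,4195.4,15
4190,4203.7,15
4200,4211.8,15
4210,4219.6,15
4220,4227.4,15
4230,4235.0,15
4240,4242.5,15
4250,4250.0,15
4260,4257.5,15
4270,4265.0,15
4280,4272.6,15
4290,4280.4,15
4300,4288.2,15
4310,4296.3,15
4320,4304.6,15
4330,4313.1,15
4340,4321.9,15
4350,4331.0,15
4360,4340.4,15
4370,4350.0,15
4380,4360.0,15
4390,4370.4,15
4400,4381.0,15
4410,4391.9,15
4420,4403.1,15
4430,4414.6,15
4440,4426.3,15
4450,4438.2,15
4460,4450.4,15
4470,4462.6,15
4480,4475.0,15
4490,4487.5,15
4500,4500.0,15
4510,4512.5,15
4520,4525.0,15
4530,4537.4,15
4540,4549.6,15
4550,4561.8,15
4560,4573.7,15
4570,4585.4,15
4580,4596.9,15
4590,4608.1,15
4600,4619.0,15
4610,4629.6,15
4620,4640.0,15
4630,4650.0,15
4640,4659.6,15
4650,4669.0,15
4660,4678.1,15
4670,4686.9,15
4680,4695.4,15
4690,4703.7,15
4700,4711.8,15
4710,4719.6,15
4720,4727.4,15
4730,4735.0,15
4740,4742.5,15
4750,4750.0,15
4760,4757.5,15
4770,4765.0,15
4780,4772.6,15
4790,4780.4,15
4800,4788.2,15
4810,4796.3,15
4820,4804.6,15
4830,4813.1,15
4840,4821.9,15
4850,4831.0,15
4860,4840.4,15
4870,4850.0,15
4880,4860.0,15
4890,4870.4,15
4900,4881.0,15
4910,4891.9,15
4920,4903.1,15
4930,4914.6,15
4940,4926.3,15
4950,4938.2,15
4960,4950.4,15
4970,4962.6,15
4980,4975.0,15
4990,4987.5,15
5000,5000.0,15
5010,5012.5,15
5020,5025.0,15
5030,5037.4,15
5040,5049.6,15
5050,5061.8,15
5060,5073.7,15
5070,5085.4,15
5080,5096.9,15
5090,5108.1,15
5100,5119.0,15
5110,5129.6,15
5120,5140.0,15
5130,5150.0,15
5140,5159.6,15
5150,5169.0,15
5160,5178.1,15
5170,5186.9,15
5180,5195.4,15
5190,5203.7,15
5200,5211.8,15
5210,5219.6,15
5220,5227.4,15
5230,5235.0,15
5240,5242.5,15
5250,5250.0,15
5260,5257.5,15
5270,5265.0,15
5280,5272.6,15
5290,5280.4,15
5300,5288.2,15
5310,5296.3,15
5320,5304.6,15
5330,5313.1,15
5340,5321.9,15
5350,5331.0,15
5360,5340.4,15
5370,5350.0,15
5380,5360.0,15
5390,5370.4,15
5400,5381.0,15
5410,5391.9,15
5420,5403.1,15
5430,5414.6,15
5440,5426.3,15
5450,5438.2,15
5460,5450.4,15
5470,5462.6,15
5480,5475.0,15
5490,5487.5,15
5500,5500.0,15
5510,5512.5,15
5520,5525.0,15
5530,5537.4,15
5540,5549.6,15
5550,5561.8,15
5560,5573.7,15
5570,5585.4,15
5580,5596.9,15
5590,5608.1,15
5600,5619.0,15
5610,5629.6,15
5620,5640.0,15
5630,5650.0,15
5640,5659.6,15
5650,5669.0,15
5660,5678.1,15
5670,5686.9,15
5680,5695.4,15
5690,5703.7,15
5700,5711.8,15
5710,5719.6,15
5720,5727.4,15
5730,5735.0,15
5740,5742.5,15
5750,5750.0,15
5760,5757.5,15
5770,5765.0,15
5780,5772.6,15
5790,5780.4,15
5800,5788.2,15
5810,5796.3,15
5820,5804.6,15
5830,5813.1,15
5840,5821.9,15
5850,5831.0,15
5860,5840.4,15
5870,5850.0,15
5880,5860.0,15
5890,5870.4,15
5900,5881.0,15
5910,5891.9,15
5920,5903.1,15
5930,5914.6,15
5940,5926.3,15
5950,5938.2,15
5960,5950.4,15
5970,5962.6,15
5980,5975.0,15
5990,5987.5,15
6000,6000.0,15
6010,6012.5,15
6020,6025.0,15
6030,6037.4,15
6040,6049.6,15
6050,6061.8,15
6060,6073.7,15
6070,6085.4,15
6080,6096.9,15
6090,6108.1,15
6100,6119.0,15
6110,6129.6,15
6120,6140.0,15
6130,6150.0,15
6140,6159.6,15
6150,6169.0,15
6160,6178.1,15
6170,6186.9,15
6180,6195.4,15
6190,6203.7,15
6200,6211.8,15
6210,6219.6,15
6220,6227.4,15
6230,6235.0,15
6240,6242.5,15
6250,6250.0,15
6260,6257.5,15
6270,6265.0,15
6280,6272.6,15
6290,6280.4,15
6300,6288.2,15
6310,6296.3,15
6320,6304.6,15
6330,6313.1,15
6340,6321.9,15
6350,6331.0,15
6360,6340.4,15
6370,6350.0,15
6380,6360.0,15
6390,6370.4,15
6400,6381.0,15
6410,6391.9,15
6420,6403.1,15
6430,6414.6,15
6440,6426.3,15
6450,6438.2,15
6460,6450.4,15
6470,6462.6,15
6480,6475.0,15
6490,6487.5,15
6500,6500.0,15
6510,6512.5,15
6520,6525.0,15
6530,6537.4,15
6540,6549.6,15
6550,6561.8,15
6560,6573.7,15
6570,6585.4,15
6580,6596.9,15
6590,6608.1,15
6600,6619.0,15
6610,6629.6,15
6620,6640.0,15
6630,6650.0,15
6640,6659.6,15
6650,6669.0,15
6660,6678.1,15
6670,6686.9,15
6680,6695.4,15
6690,6703.7,15
6700,6711.8,15
6710,6719.6,15
6720,6727.4,15
6730,6735.0,15
6740,6742.5,15
6750,6750.0,15
6760,6757.5,15
6770,6765.0,15
6780,6772.6,15
6790,6780.4,15
6800,6788.2,15
6810,6796.3,15
6820,6804.6,15
6830,6813.1,15
6840,6821.9,15
6850,6831.0,15
6860,6840.4,15
6870,6850.0,15
6880,6860.0,15
6890,6870.4,15
6900,6881.0,15
6910,6891.9,15
6920,6903.1,15
6930,6914.6,15
6940,6926.3,15
6950,6938.2,15
6960,6950.4,15
6970,6962.6,15
6980,6975.0,15
6990,6987.5,15
7000,7000.0,15
7010,7012.5,15
7020,7025.0,15
7030,7037.4,15
7040,7049.6,15
7050,7061.8,15
7060,7073.7,15
7070,7085.4,15
7080,7096.9,15
7090,7108.1,15
7100,7119.0,15
7110,7129.6,15
7120,7140.0,15
7130,7150.0,15
7140,7159.6,15
7150,7169.0,15
7160,7178.1,15
7170,7186.9,15
7180,7195.4,15
7190,7203.7,15
7200,7211.8,15
7210,7219.6,15
7220,7227.4,15
7230,7235.0,15
7240,7242.5,15
7250,7250.0,15
7260,7257.5,15
7270,7265.0,15
7280,7272.6,15
7290,7280.4,15
7300,7288.2,15
7310,7296.3,15
7320,7304.6,15
7330,7313.1,15
7340,7321.9,15
7350,7331.0,15
7360,7340.4,15
7370,7350.0,15
7380,7360.0,15
7390,7370.4,15
7400,7381.0,15
7410,7391.9,15
7420,7403.1,15
7430,7414.6,15
7440,7426.3,15
7450,7438.2,15
7460,7450.4,15
7470,7462.6,15
7480,7475.0,15
7490,7487.5,15
7500,7500.0,15
7510,7512.5,15
7520,7525.0,15
7530,7537.4,15
7540,7549.6,15
7550,7561.8,15
7560,7573.7,15
7570,7585.4,15
7580,7596.9,15
7590,7608.1,15
7600,7619.0,15
7610,7629.6,15
7620,7640.0,15
7630,7650.0,15
7640,7659.6,15
7650,7669.0,15
7660,7678.1,15
7670,7686.9,15
7680,7695.4,15
7690,7703.7,15
7700,7711.8,15
7710,7719.6,15
7720,7727.4,15
7730,7735.0,15
7740,7742.5,15
7750,7750.0,15
7760,7757.5,15
7770,7765.0,15
7780,7772.6,15
7790,7780.4,15
7800,7788.2,15
7810,7796.3,15
7820,7804.6,15
7830,7813.1,15
7840,7821.9,15
7850,7831.0,15
7860,7840.4,15
7870,7850.0,15
7880,7860.0,15
7890,7870.4,15
7900,7881.0,15
7910,7891.9,15
7920,7903.1,15
7930,7914.6,15
7940,7926.3,15
7950,7938.2,15
7960,7950.4,15
7970,7962.6,15
7980,7975.0,15
7990,7987.5,15
8000,8000.0,15
8010,8012.5,15
8020,8025.0,15
8030,8037.4,15
8040,8049.6,15
8050,8061.8,15
8060,8073.7,15
8070,8085.4,15
8080,8096.9,15
8090,8108.1,15
8100,8119.0,15
8110,8129.6,15
8120,8140.0,15
8130,8150.0,15
8140,8159.6,15
8150,8169.0,15
8160,8178.1,15
8170,8186.9,15
8180,8195.4,15
8190,8203.7,15
8200,8211.8,15
8210,8219.6,15
8220,8227.4,15
8230,8235.0,15
8240,8242.5,15
8250,8250.0,15
8260,8257.5,15
8270,8265.0,15
8280,8272.6,15
8290,8280.4,15
8300,8288.2,15
8310,8296.3,15
8320,8304.6,15
8330,8313.1,15
8340,8321.9,15
8350,8331.0,15
8360,8340.4,15
8370,8350.0,15
8380,8360.0,15
8390,8370.4,15
8400,8381.0,15
8410,8391.9,15
8420,8403.1,15
8430,8414.6,15
8440,8426.3,15
8450,8438.2,15
8460,8450.4,15
8470,8462.6,15
8480,8475.0,15
8490,8487.5,15
8500,8500.0,15
8510,8512.5,15
8520,8525.0,15
8530,8537.4,15
8540,8549.6,15
8550,8561.8,15
8560,8573.7,15
8570,8585.4,15
8580,8596.9,15
8590,8608.1,15
8600,8619.0,15
8610,8629.6,15
8620,8640.0,15
8630,8650.0,15
8640,8659.6,15
8650,8669.0,15
8660,8678.1,15
8670,8686.9,15
8680,8695.4,15
8690,8703.7,15
8700,8711.8,15
8710,8719.6,15
8720,8727.4,15
8730,8735.0,15
8740,8742.5,15
8750,8750.0,15
8760,8757.5,15
8770,8765.0,15
8780,8772.6,15
8790,8780.4,15
8800,8788.2,15
8810,8796.3,15
8820,8804.6,15
8830,8813.1,15
8840,8821.9,15
8850,8831.0,15
8860,8840.4,15
8870,8850.0,15
8880,8860.0,15
8890,8870.4,15
8900,8881.0,15
8910,8891.9,15
8920,8903.1,15
8930,8914.6,15
8940,8926.3,15
8950,8938.2,15
8960,8950.4,15
8970,8962.6,15
8980,8975.0,15
8990,8987.5,15
9000,9000.0,15
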