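dataset,method,min,avg,max,sigma2,sigma,sem
BraTS2015,NaiveBayes,92.47,93.33,94.9,0.493,0.7021,0.4054
BraTS2015,MSVM,92.19,93.42,96.66,1.016,1.0083,0.5821
BraTS2015,Softmax,91.63,92.8,93.98,0.920,0.9593,0.5539
BraTS2015,EnsembleTree,92.98,94.32,95.67,1.206,1.0981,0.6340
BraTS2015,ELM,97.37,97.76,98.16,0.104,0.3225,0.1862
BraTS2017,NaiveBayes,91.04,92.35,93.66,1.144,1.0696,0.6175
BraTS2017,MSVM,92.67,93.62,94.58,0.608,0.7797,0.451
BraTS2017,Softmax,90.29,92.13,93.98,2.2693,1.5064,0.8697
BraTS2017,EnsembleTree,93.16,94.29,95.42,0.8512,0.9226,0.5326
BraTS2017,ELM,96.94,97.1,97.26,0.017,0.1306,0.0754
BraTS2018,NaiveBayes,87.42,88.45,89.49,0.7141,0.8450,0.4879
BraTS2018,MSVM,86.69,90.01,91.34,1.1704,1.0818,0.6246
BraTS2018,Softmax,91.04,91.73,92.42,0.3174,0.5633,0.3252
BraTS2018,EnsembleTree,88.64,90.21,91.79,1.6537,1.2859,0.7424
BraTS2018,ELM,92.18,92.79,93.40,0.2480,0.4980,0.2875
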