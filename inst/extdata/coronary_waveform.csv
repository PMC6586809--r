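t_frac,w
0,0.81496
0.015625,0.772731
0.03125,0.719981
0.046875,0.661431
0.0625,0.6018
0.078125,0.545201
0.09375,0.494237
0.109375,0.451281
0.125,0.418683
0.140625,0.397486
0.15625,0.386627
0.171875,0.384853
0.1875,0.390926
0.203125,0.403907
0.21875,0.423182
0.234375,0.448149
0.25,0.478347
0.265625,0.515094
0.28125,0.56094
0.296875,0.618462
0.3125,0.689741
0.328125,0.773197
0.34375,0.865614
0.359375,0.963766
0.375,1.064196
0.390625,1.162412
0.40625,1.253629
0.421875,1.333064
0.4375,1.397482
0.453125,1.447983
0.46875,1.486425
0.484375,1.514657
0.5,1.534112
0.515625,1.545466
0.53125,1.54932
0.546875,1.54628
0.5625,1.537193
0.578125,1.523187
0.59375,1.505404
0.609375,1.484955
0.625,1.462454
0.640625,1.438139
0.65625,1.412235
0.671875,1.384961
0.6875,1.356463
0.703125,1.326852
0.71875,1.296239
0.734375,1.264773
0.75,1.232803
0.765625,1.200737
0.78125,1.168987
0.796875,1.137961
0.8125,1.108068
0.828125,1.079715
0.84375,1.053308
0.859375,1.028827
0.875,1.005412
0.890625,0.982102
0.90625,0.957958
0.921875,0.932972
0.9375,0.908344
0.953125,0.885351
0.96875,0.865023
0.984375,0.843956
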