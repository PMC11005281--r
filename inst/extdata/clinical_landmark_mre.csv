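dataset,landmark,mre
validation,v1,5.432
validation,v2,4.429
validation,v3,2.266
validation,v4,1.514
validation,v5,2.226
validation,v6,2.547
validation,v7,2.081
validation,v8,2.325
validation,v9,3.223
validation,v10,1.740
test,v1,4.131
test,v2,2.978
test,v3,2.272
test,v4,1.508
test,v5,2.233
test,v6,2.395
test,v7,2.012
test,v8,2.309
test,v9,3.105
test,v10,1.528
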