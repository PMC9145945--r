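fingerprint,r2_train,r2_test
FP2,0.9629,0.9537
FP4,0.9429,0.9283
MACCS,0.9549,0.9442
Morgan,0.9729,0.9664
Layered,0.9649,0.9562
RDKit,0.9659,0.9575
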