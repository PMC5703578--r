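measured,category,direction,inhibit,source
BNP,input-output,increase,,fixture
ERK12,input-intermediate,increase,,fixture
Ca,input-intermediate,increase,,fixture
Akt,input-intermediate,increase,,fixture
cGMP,input-intermediate,no-change,,fixture
BNP,inhibition,decrease,AT1R,fixture
Akt,inhibition,decrease,PI3K,fixture
ERK12,inhibition,decrease,Raf1,fixture
Ca,inhibition,decrease,LTCC,fixture
BNP,inhibition,decrease,Raf1,fixture
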