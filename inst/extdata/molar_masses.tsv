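name	molar_mass
arginine	174.20
histidine	155.15
isoleucine	131.17
leucine	131.17
lysine	146.19
methionine	149.21
phenylalanine	165.19
threonine	119.12
tryptophan	204.23
valine	117.15
alanine	89.09
aspartate	133.10
cysteine	121.16
glutamate	147.13
glycine	75.07
proline	115.13
serine	105.09
tyrosine	181.19
asparagine	132.12
glutamine	146.15
glucose	180.16
fructose	180.16
sucrose	342.30
maltose	342.30
lactose	342.30
epa	302.45
dha	328.49
linoleic_acid	280.45
linolenic_acid	278.43
amp	347.22
cmp	323.20
gmp	363.22
ump	324.18
imp	348.21
ca	40.078
p	30.974
k	39.098
mg	24.305
zn	65.38
cu	63.546
fe	55.845
mn	54.938
se	78.971
na	22.99
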