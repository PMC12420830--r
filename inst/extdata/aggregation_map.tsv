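fine_type	major_class
Cancer Basal SC	tumor
Cancer Her2 SC	tumor
Cancer LumA SC	tumor
Cancer LumB SC	tumor
Cancer Cycling	tumor
Luminal Progenitors	tumor
Mature Luminal	tumor
Myoepithelial	tumor
T cells CD8+	immune
T cells CD4+	immune
NK cells	immune
NKT cells	immune
Cycling T-cells	immune
B cells Memory	immune
B cells Naive	immune
Plasmablasts	immune
Macrophage	immune
Monocyte	immune
DCs	immune
Cycling Myeloid	immune
CAFs MSC iCAF-like	stroma
CAFs myCAF-like	stroma
CAFs Transitioning	stroma
PVL Differentiated	stroma
PVL Immature	stroma
Endothelial ACKR1	stroma
Endothelial RGS5	stroma
Endothelial CXCL12	stroma
Endothelial Lymphatic LYVE1	stroma
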