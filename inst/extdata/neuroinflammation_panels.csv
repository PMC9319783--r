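panel,category,gene,subgroup
complement,complement,C4A,
complement,complement,C4B,
microglia,microglia,P2RY12,activation
microglia,microglia,P2RY13,activation
microglia,microglia,CX3CR1,activation
microglia,microglia,FTL,activation
microglia,microglia,FCER1G,activation
microglia,microglia,CIITA,activation
microglia,microglia,FCGR2A,M1
microglia,microglia,FCGR3A,M1
microglia,microglia,MRC1,M2
astrocyte,astrocyte,VIM,maturity
astrocyte,astrocyte,GFAP,astrogliosis
astrocyte,astrocyte,SERPINA3,astrogliosis
pro_inflammatory,pro_inflammatory,IL-18,cytokine
pro_inflammatory,pro_inflammatory,1L1B,cytokine
pro_inflammatory,pro_inflammatory,IL-33,cytokine
pro_inflammatory,pro_inflammatory,IL-6,cytokine
pro_inflammatory,pro_inflammatory,IL1R1,receptor
pro_inflammatory,pro_inflammatory,IL6ST,receptor
pro_inflammatory,pro_inflammatory,TNFRSF1A,receptor
pro_inflammatory,pro_inflammatory,NFKB1,mediator
pro_inflammatory,pro_inflammatory,PTGS2,mediator
pro_inflammatory,pro_inflammatory,S100B,mediator
bmec,bmec,CLDN5,paracellular
bmec,bmec,OCLN,paracellular
bmec,bmec,ESAM,paracellular
bmec,bmec,CDH5,paracellular
bmec,bmec,ICAM1,transcellular
bmec,bmec,VCAM1,transcellular
bmec,bmec,ABCC1,transporter
bmec,bmec,ABCBC1,transporter
bmec,bmec,ABCG1,transporter
bmec,bmec,ABCG2,transporter
bmec,bmec,IFITM1,transmembrane
bmec,bmec,IFITM2,transmembrane
bmec,bmec,COL4A1,ecm
bmec,bmec,COL4A2,ecm
bmec,bmec,FN1,ecm
bmec,bmec,LAMA,ecm
chemokine,chemokine,CXCL1,
chemokine,chemokine,CXCL2,
chemokine,chemokine,CXCL8,
chemokine,chemokine,CCL2,
peripheral,peripheral,CD14,monocyte
peripheral,peripheral,CD93,monocyte
peripheral,peripheral,CD163,macrophage
peripheral,peripheral,FCGR1A,macrophage
peripheral,peripheral,FPR1,neutrophil
peripheral,peripheral,S100A8,neutrophil
peripheral,peripheral,S100A9,neutrophil
peripheral,peripheral,S100A12,neutrophil
peripheral,peripheral,ITGAX,dendritic
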