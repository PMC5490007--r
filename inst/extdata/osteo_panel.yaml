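# Roles and (for oncogenes) canonical hotspots of the osteosarcoma cancer-gene
# panel. Hotspot positions are 1-based genomic coordinates (GRCh37).
genes:
  TERT:
    role: oncogene
  RICTOR:
    role: oncogene
  CCND2:
    role: oncogene
  CDK4:
    role: oncogene
  MDM2:
    role: oncogene
  IGF1:
    role: oncogene
  COPS3:
    role: oncogene
  IGF1R:
    role: oncogene
  TP53:
    role: recessive
  NF1:
    role: recessive
  IGF2R:
    role: recessive
  IGFBP5:
    role: recessive
  PIK3CA:
    role: oncogene
    hotspots:
      - position: 178936091
        alt: A
      - position: 178952085
        alt: G
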