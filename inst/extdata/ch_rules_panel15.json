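{
  "panel": "panel15",
  "comment": "Driver-qualification rules for the 15-gene CH panel. Rule classes: whole_gene_ptv_plus_hotspot (any PTV along the gene body, or a catalogued hotspot), exon_restricted_ptv (PTV within the listed exons only), hotspot_only (catalogued hotspots only). Hotspot lists here are an illustrative default keyed on amino-acid change; supply a full catalogue via the same schema for production use.",
  "genes": {
    "DNMT3A": {"rule_class": "whole_gene_ptv_plus_hotspot", "hotspots": ["R882H", "R882C", "R882S", "R882P"]},
    "TET2":   {"rule_class": "whole_gene_ptv_plus_hotspot", "hotspots": ["C1135Y", "C1221Y", "R1896M"]},
    "TP53":   {"rule_class": "whole_gene_ptv_plus_hotspot", "hotspots": ["R175H", "R248Q", "R248W", "R273H", "R273C"]},
    "ASXL1":  {"rule_class": "exon_restricted_ptv", "allowed_exons": [12]},
    "PPM1D":  {"rule_class": "exon_restricted_ptv", "allowed_exons": [5, 6]},
    "SF3B1":  {"rule_class": "hotspot_only", "hotspots": ["K700E", "K666N", "K666E", "E622D", "R625C"]},
    "SRSF2":  {"rule_class": "hotspot_only", "hotspots": ["P95H", "P95L", "P95R"]},
    "GNB1":   {"rule_class": "hotspot_only", "hotspots": ["K57E", "K57T"]},
    "IDH2":   {"rule_class": "hotspot_only", "hotspots": ["R140Q", "R140L", "R172K"]},
    "JAK2":   {"rule_class": "hotspot_only", "hotspots": ["V617F"]},
    "PRPF8":  {"rule_class": "hotspot_only", "hotspots": ["M1307I", "D1598N"]},
    "KRAS":   {"rule_class": "hotspot_only", "hotspots": ["G12D", "G12V", "G12S", "G13D", "Q61H"]},
    "NRAS":   {"rule_class": "hotspot_only", "hotspots": ["G12D", "G12S", "G13D", "Q61K", "Q61R"]},
    "BRAF":   {"rule_class": "hotspot_only", "hotspots": ["V600E"]},
    "MPL":    {"rule_class": "hotspot_only", "hotspots": ["W515L", "W515K", "S505N"]}
  }
}
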