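{
 "panel": "panel58",
 "comment": "Extended 58-gene CH panel: the 15-gene rules plus additional leukemogenic driver genes qualified by protein-truncating variants anywhere in the gene body. Gene list and hotspots are an illustrative default; replace via the same schema.",
 "genes": {
  "DNMT3A": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": [
    "R882H",
    "R882C",
    "R882S",
    "R882P"
   ]
  },
  "TET2": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": [
    "C1135Y",
    "C1221Y",
    "R1896M"
   ]
  },
  "TP53": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": [
    "R175H",
    "R248Q",
    "R248W",
    "R273H",
    "R273C"
   ]
  },
  "ASXL1": {
   "rule_class": "exon_restricted_ptv",
   "allowed_exons": [
    12
   ]
  },
  "PPM1D": {
   "rule_class": "exon_restricted_ptv",
   "allowed_exons": [
    5,
    6
   ]
  },
  "SF3B1": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "K700E",
    "K666N",
    "K666E",
    "E622D",
    "R625C"
   ]
  },
  "SRSF2": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "P95H",
    "P95L",
    "P95R"
   ]
  },
  "GNB1": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "K57E",
    "K57T"
   ]
  },
  "IDH2": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "R140Q",
    "R140L",
    "R172K"
   ]
  },
  "JAK2": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "V617F"
   ]
  },
  "PRPF8": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "M1307I",
    "D1598N"
   ]
  },
  "KRAS": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "G12D",
    "G12V",
    "G12S",
    "G13D",
    "Q61H"
   ]
  },
  "NRAS": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "G12D",
    "G12S",
    "G13D",
    "Q61K",
    "Q61R"
   ]
  },
  "BRAF": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "V600E"
   ]
  },
  "MPL": {
   "rule_class": "hotspot_only",
   "hotspots": [
    "W515L",
    "W515K",
    "S505N"
   ]
  },
  "CBL": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "CEBPA": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "CSF1R": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "CSF3R": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "CTCF": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "CUX1": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "EP300": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "ETV6": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "EZH2": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "GATA2": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "GATA3": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "GNAS": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "IDH1": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "KDM6A": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "KIT": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "KMT2A": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "KMT2D": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "LUC7L2": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "MYD88": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "NF1": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "PHF6": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "PTPN11": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "RAD21": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "RUNX1": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "SETBP1": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "SETD2": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "SH2B3": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "SMC1A": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "SMC3": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "STAG2": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "STAT3": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "U2AF1": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "U2AF2": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "WT1": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "ZRSR2": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "BCOR": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "BCORL1": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "CALR": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "CARD11": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "CREBBP": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "DDX41": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "FLT3": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  },
  "MGA": {
   "rule_class": "whole_gene_ptv_plus_hotspot",
   "hotspots": []
  }
 }
}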