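{
 "comment": "Qualifying-variant model registry for gene-level collapsing. MAF thresholds are fractions (0.0005 = 0.05%). consequence: synonymous | missense | nonsynonymous (missense + PTV + inframe indel) | ptv (nonsense, frameshift, splice_site) | composite (union of `components`). mtr_gate applies (MTR < 0.78 OR MTR centile < 50). All models are dominant except `rec`.",
 "models": [
  {"name": "syn", "consequence": "synonymous", "maf_global_max": 0.00005, "maf_ancestry_max": null, "revel_min": null, "mtr_gate": false, "genetic_model": "dominant"},
  {"name": "flexdmg", "consequence": "nonsynonymous", "maf_global_max": 0.0005, "maf_ancestry_max": 0.001, "revel_min": 0.25, "mtr_gate": false, "genetic_model": "dominant"},
  {"name": "flexnonsynmtr", "consequence": "nonsynonymous", "maf_global_max": 0.0005, "maf_ancestry_max": 0.001, "revel_min": null, "mtr_gate": true, "genetic_model": "dominant"},
  {"name": "UR", "consequence": "nonsynonymous", "maf_global_max": 0, "maf_ancestry_max": null, "revel_min": 0.25, "mtr_gate": false, "genetic_model": "dominant"},
  {"name": "URmtr", "consequence": "nonsynonymous", "maf_global_max": 0, "maf_ancestry_max": null, "revel_min": 0.25, "mtr_gate": true, "genetic_model": "dominant"},
  {"name": "raredmg", "consequence": "missense", "maf_global_max": 0.00005, "maf_ancestry_max": null, "revel_min": 0.25, "mtr_gate": false, "genetic_model": "dominant"},
  {"name": "raredmgmtr", "consequence": "missense", "maf_global_max": 0.00005, "maf_ancestry_max": null, "revel_min": 0.25, "mtr_gate": true, "genetic_model": "dominant"},
  {"name": "ptv", "consequence": "ptv", "maf_global_max": 0.001, "maf_ancestry_max": 0.001, "revel_min": null, "mtr_gate": false, "genetic_model": "dominant"},
  {"name": "ptv5pcnt", "consequence": "ptv", "maf_global_max": 0.05, "maf_ancestry_max": 0.05, "revel_min": null, "mtr_gate": false, "genetic_model": "dominant"},
  {"name": "ptvraredmg", "consequence": "composite", "components": ["ptv", "raredmg"], "maf_global_max": null, "maf_ancestry_max": null, "revel_min": null, "mtr_gate": false, "genetic_model": "dominant"},
  {"name": "rec", "consequence": "nonsynonymous", "maf_global_max": 0.005, "maf_ancestry_max": 0.005, "revel_min": null, "mtr_gate": false, "genetic_model": "recessive"}
 ]
}
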