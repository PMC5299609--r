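{
  "comment": "Curated brown adipogenic regulatory network topology (early / core / thermogenic modules). Hand-assembled from the adipogenesis literature; per-edge confidence notes mark how well each link is established. Editable data, not code.",
  "nodes": [
    {"gene": "Nfia",     "module": "early"},
    {"gene": "Klf4",     "module": "early"},
    {"gene": "Klf2",     "module": "early"},
    {"gene": "Cebpb",    "module": "early"},
    {"gene": "Cebpd",    "module": "early"},
    {"gene": "Ebf1",     "module": "early"},
    {"gene": "Ebf2",     "module": "early"},
    {"gene": "Zfp423",   "module": "early"},
    {"gene": "Pparg",    "module": "core"},
    {"gene": "Cebpa",    "module": "core"},
    {"gene": "Rxrg",     "module": "core"},
    {"gene": "Stat5a",   "module": "core"},
    {"gene": "Prdm16",   "module": "core"},
    {"gene": "Ppara",    "module": "thermogenic"},
    {"gene": "Ppargc1a", "module": "thermogenic"},
    {"gene": "Ucp1",     "module": "thermogenic"}
  ],
  "edges": [
    {"source": "Klf4",     "target": "Cebpb",    "type": "activation",      "confidence": "established"},
    {"source": "Cebpb",    "target": "Pparg",    "type": "activation",      "confidence": "established"},
    {"source": "Cebpd",    "target": "Pparg",    "type": "activation",      "confidence": "established"},
    {"source": "Cebpb",    "target": "Cebpa",    "type": "activation",      "confidence": "established"},
    {"source": "Ebf1",     "target": "Pparg",    "type": "activation",      "confidence": "established"},
    {"source": "Ebf2",     "target": "Pparg",    "type": "activation",      "confidence": "established"},
    {"source": "Ebf2",     "target": "Prdm16",   "type": "activation",      "confidence": "established"},
    {"source": "Zfp423",   "target": "Pparg",    "type": "activation",      "confidence": "established"},
    {"source": "Stat5a",   "target": "Pparg",    "type": "activation",      "confidence": "reported"},
    {"source": "Cebpa",    "target": "Pparg",    "type": "activation",      "confidence": "established"},
    {"source": "Pparg",    "target": "Cebpa",    "type": "activation",      "confidence": "established"},
    {"source": "Pparg",    "target": "Ucp1",     "type": "activation",      "confidence": "established"},
    {"source": "Ppara",    "target": "Ucp1",     "type": "activation",      "confidence": "established"},
    {"source": "Ppargc1a", "target": "Ucp1",     "type": "activation",      "confidence": "established"},
    {"source": "Rxrg",     "target": "Ucp1",     "type": "activation",      "confidence": "reported"},
    {"source": "Klf2",     "target": "Pparg",    "type": "inhibition",      "confidence": "reported"},
    {"source": "Prdm16",   "target": "Cebpb",    "type": "protein-protein", "confidence": "established"},
    {"source": "Prdm16",   "target": "Ppargc1a", "type": "protein-protein", "confidence": "established"},
    {"source": "Prdm16",   "target": "Pparg",    "type": "protein-protein", "confidence": "established"},
    {"source": "Ppargc1a", "target": "Pparg",    "type": "protein-protein", "confidence": "established"},
    {"source": "Ppargc1a", "target": "Ppara",    "type": "protein-protein", "confidence": "established"},
    {"source": "Rxrg",     "target": "Pparg",    "type": "protein-protein", "confidence": "established"},
    {"source": "Nfia",     "target": "Pparg",    "type": "activation",      "confidence": "promoter binding + knockdown response"},
    {"source": "Nfia",     "target": "Rxrg",     "type": "activation",      "confidence": "promoter binding + knockdown response"},
    {"source": "Nfia",     "target": "Ppara",    "type": "activation",      "confidence": "promoter binding + knockdown response"},
    {"source": "Nfia",     "target": "Ppargc1a", "type": "activation",      "confidence": "promoter binding + knockdown response"},
    {"source": "Nfia",     "target": "Ebf1",     "type": "activation",      "confidence": "promoter binding"},
    {"source": "Nfia",     "target": "Ebf2",     "type": "activation",      "confidence": "promoter binding"},
    {"source": "Nfia",     "target": "Zfp423",   "type": "activation",      "confidence": "promoter binding"}
  ]
}
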