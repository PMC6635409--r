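# Detection-method reliability scores (0 = lowest confidence, 10 =
# highest) with PSI-MI parent links used for score inheritance and
# representative-term selection. Anchors: X-ray crystallography scores
# 10, genetic interference 0, high-throughput screens (two-hybrid,
# MS-based proteomics) at most 5. Unlisted child terms inherit the score
# of their nearest scored ancestor.
mi_scores:
  "MI:0045": 5    # experimental interaction detection (fallback)
  "MI:0114": 10   # x-ray crystallography
  "MI:0077": 9    # nuclear magnetic resonance
  "MI:0071": 8    # molecular sieving
  "MI:0096": 7    # pull down
  "MI:0019": 7    # coimmunoprecipitation
  "MI:0006": 6    # anti bait coimmunoprecipitation
  "MI:0055": 6    # fluorescent resonance energy transfer
  "MI:0018": 4    # two hybrid
  "MI:0397": 3    # two hybrid array
  "MI:0401": 5    # biochemical
  "MI:0943": 4    # detection by mass spectrometry
  "MI:0254": 0    # genetic interference
mi_parents:
  "MI:0114": "MI:0045"
  "MI:0077": "MI:0045"
  "MI:0071": "MI:0045"
  "MI:0401": "MI:0045"
  "MI:0096": "MI:0401"
  "MI:0019": "MI:0096"
  "MI:0006": "MI:0019"
  "MI:0055": "MI:0045"
  "MI:0018": "MI:0045"
  "MI:0397": "MI:0018"
  "MI:0943": "MI:0401"
  "MI:0254": "MI:0045"
  # interaction-type branch
  "MI:0915": "MI:0190"   # physical association <- interaction type
  "MI:0914": "MI:0915"   # association
  "MI:0407": "MI:0915"   # direct interaction
  "MI:0195": "MI:0407"   # covalent binding
  "MI:0408": "MI:0407"   # disulfide bond
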