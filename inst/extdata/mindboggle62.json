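{
  "scouts": [
    {
      "name": "caudalanteriorcingulate_L",
      "hemisphere": "L",
      "lobe": "cingulate"
    },
    {
      "name": "caudalmiddlefrontal_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "cuneus_L",
      "hemisphere": "L",
      "lobe": "occipital"
    },
    {
      "name": "entorhinal_L",
      "hemisphere": "L",
      "lobe": "temporal"
    },
    {
      "name": "fusiform_L",
      "hemisphere": "L",
      "lobe": "temporal"
    },
    {
      "name": "inferiorparietal_L",
      "hemisphere": "L",
      "lobe": "parietal"
    },
    {
      "name": "inferiortemporal_L",
      "hemisphere": "L",
      "lobe": "temporal"
    },
    {
      "name": "insula_L",
      "hemisphere": "L",
      "lobe": "insula"
    },
    {
      "name": "isthmuscingulate_L",
      "hemisphere": "L",
      "lobe": "cingulate"
    },
    {
      "name": "lateraloccipital_L",
      "hemisphere": "L",
      "lobe": "occipital"
    },
    {
      "name": "lateralorbitofrontal_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "lingual_L",
      "hemisphere": "L",
      "lobe": "occipital"
    },
    {
      "name": "medialorbitofrontal_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "middletemporal_L",
      "hemisphere": "L",
      "lobe": "temporal"
    },
    {
      "name": "paracentral_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "parahippocampal_L",
      "hemisphere": "L",
      "lobe": "temporal"
    },
    {
      "name": "parsopercularis_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "parsorbitalis_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "parstriangularis_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "pericalcarine_L",
      "hemisphere": "L",
      "lobe": "occipital"
    },
    {
      "name": "postcentral_L",
      "hemisphere": "L",
      "lobe": "parietal"
    },
    {
      "name": "posteriorcingulate_L",
      "hemisphere": "L",
      "lobe": "cingulate"
    },
    {
      "name": "precentral_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "precuneus_L",
      "hemisphere": "L",
      "lobe": "parietal"
    },
    {
      "name": "rostralanteriorcingulate_L",
      "hemisphere": "L",
      "lobe": "cingulate"
    },
    {
      "name": "rostralmiddlefrontal_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "superiorfrontal_L",
      "hemisphere": "L",
      "lobe": "frontal"
    },
    {
      "name": "superiorparietal_L",
      "hemisphere": "L",
      "lobe": "parietal"
    },
    {
      "name": "superiortemporal_L",
      "hemisphere": "L",
      "lobe": "temporal"
    },
    {
      "name": "supramarginal_L",
      "hemisphere": "L",
      "lobe": "parietal"
    },
    {
      "name": "transversetemporal_L",
      "hemisphere": "L",
      "lobe": "temporal"
    },
    {
      "name": "caudalanteriorcingulate_R",
      "hemisphere": "R",
      "lobe": "cingulate"
    },
    {
      "name": "caudalmiddlefrontal_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "cuneus_R",
      "hemisphere": "R",
      "lobe": "occipital"
    },
    {
      "name": "entorhinal_R",
      "hemisphere": "R",
      "lobe": "temporal"
    },
    {
      "name": "fusiform_R",
      "hemisphere": "R",
      "lobe": "temporal"
    },
    {
      "name": "inferiorparietal_R",
      "hemisphere": "R",
      "lobe": "parietal"
    },
    {
      "name": "inferiortemporal_R",
      "hemisphere": "R",
      "lobe": "temporal"
    },
    {
      "name": "insula_R",
      "hemisphere": "R",
      "lobe": "insula"
    },
    {
      "name": "isthmuscingulate_R",
      "hemisphere": "R",
      "lobe": "cingulate"
    },
    {
      "name": "lateraloccipital_R",
      "hemisphere": "R",
      "lobe": "occipital"
    },
    {
      "name": "lateralorbitofrontal_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "lingual_R",
      "hemisphere": "R",
      "lobe": "occipital"
    },
    {
      "name": "medialorbitofrontal_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "middletemporal_R",
      "hemisphere": "R",
      "lobe": "temporal"
    },
    {
      "name": "paracentral_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "parahippocampal_R",
      "hemisphere": "R",
      "lobe": "temporal"
    },
    {
      "name": "parsopercularis_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "parsorbitalis_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "parstriangularis_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "pericalcarine_R",
      "hemisphere": "R",
      "lobe": "occipital"
    },
    {
      "name": "postcentral_R",
      "hemisphere": "R",
      "lobe": "parietal"
    },
    {
      "name": "posteriorcingulate_R",
      "hemisphere": "R",
      "lobe": "cingulate"
    },
    {
      "name": "precentral_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "precuneus_R",
      "hemisphere": "R",
      "lobe": "parietal"
    },
    {
      "name": "rostralanteriorcingulate_R",
      "hemisphere": "R",
      "lobe": "cingulate"
    },
    {
      "name": "rostralmiddlefrontal_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "superiorfrontal_R",
      "hemisphere": "R",
      "lobe": "frontal"
    },
    {
      "name": "superiorparietal_R",
      "hemisphere": "R",
      "lobe": "parietal"
    },
    {
      "name": "superiortemporal_R",
      "hemisphere": "R",
      "lobe": "temporal"
    },
    {
      "name": "supramarginal_R",
      "hemisphere": "R",
      "lobe": "parietal"
    },
    {
      "name": "transversetemporal_R",
      "hemisphere": "R",
      "lobe": "temporal"
    }
  ],
  "region_sets": {
    "frontal_left": ["caudalmiddlefrontal_L", "lateralorbitofrontal_L", "medialorbitofrontal_L", "paracentral_L", "parsopercularis_L", "parsorbitalis_L", "parstriangularis_L", "precentral_L", "rostralmiddlefrontal_L", "superiorfrontal_L"],
    "frontal_right": ["caudalmiddlefrontal_R", "lateralorbitofrontal_R", "medialorbitofrontal_R", "paracentral_R", "parsopercularis_R", "parsorbitalis_R", "parstriangularis_R", "precentral_R", "rostralmiddlefrontal_R", "superiorfrontal_R"]
  }
}
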