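{
  "graphs": [
    {
      "id": "http://purl.obolibrary.org/obo/hp-toy.json",
      "nodes": [
        {
          "id": "http://purl.obolibrary.org/obo/HP_0000001",
          "lbl": "Abnormality of body height",
          "type": "CLASS",
          "meta": {
            "definition": {
              "val": "Deviation from the norm of height with respect to that which is expected according to age and gender norms.",
              "xrefs": ["HPO:probinson"]
            },
            "comments": ["Height is measured standing."],
            "synonyms": [
              {"pred": "hasExactSynonym", "val": "Tall stature"},
              {"pred": "hasExactSynonym", "val": "Abnormal body height"}
            ]
          }
        },
        {
          "id": "http://purl.obolibrary.org/obo/HP_0000002",
          "lbl": "Abnormality of body weight",
          "type": "CLASS",
          "meta": {
            "definition": {"val": "An abnormal increase or decrease of weight.", "xrefs": []},
            "synonyms": [
              {"pred": "hasRelatedSynonym", "val": "Abnormal body weight"}
            ]
          }
        },
        {
          "id": "http://purl.obolibrary.org/obo/HP_0000003",
          "lbl": "Multicystic kidney dysplasia",
          "type": "CLASS",
          "meta": {
            "deprecated": true
          }
        },
        {
          "id": "http://purl.obolibrary.org/obo/BFO_0000050",
          "lbl": "part of",
          "type": "PROPERTY"
        }
      ],
      "edges": [
        {"sub": "http://purl.obolibrary.org/obo/HP_0000002",
         "pred": "is_a",
         "obj": "http://purl.obolibrary.org/obo/HP_0000001"}
      ]
    }
  ]
}
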