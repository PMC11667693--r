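format-version: 1.4
ontology: hp-toy

[Term]
id: HP:0000001
name: Abnormality of body height
def: "Deviation from the norm of height with respect to that which is expected according to age and gender norms." [HPO:probinson]
comment: Height is measured standing.
synonym: "Tall stature" EXACT []
synonym: "Abnormal body height" EXACT [HPO:skoehler]

[Term]
id: HP:0000002
name: Abnormality of body weight
def: "An abnormal increase or decrease of weight." []
synonym: "Abnormal body weight" RELATED []

[Term]
id: HP:0000003
name: Multicystic kidney dysplasia
is_obsolete: true

[Typedef]
id: part_of
name: part of
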