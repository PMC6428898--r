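# Arrest-stage decision table: ordered rules mapping a point-arrest
# coarse-grained profile to a cell-cycle stage (first match wins).
# `dna` refers to the position of the furthest active DNA macro state in
# its declared cycle order: start (licensed), early (replicating),
# late (replicated), end (segregated), or none; `nuclei_min`/`nuclei_max`
# constrain the nuclei count derived from completed nuclear divisions.
# Post-division profiles (DNA back at start/none) split into G1 versus T
# arrest on the nuclei count alone: a T-arrested cell has finished nuclear
# division but not cytokinesis and so carries two nuclei.
rules:
  - when: {dna: [early]}
    stage: S
  - when: {dna: [late]}
    stage: G2/M
  - when: {dna: [end]}
    stage: M
  - when: {nuclei_min: 2}
    stage: T
  - when: {dna: [start, none], nuclei_max: 1}
    stage: G1
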