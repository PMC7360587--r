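# Machine-readable default branch-model ladder: one background ratio plus
# foreground omega classes over labelled clades (A1 Pinnipedia, A2 Canidae,
# A3 Feliformia, B1 Cetacea, B2 Ruminantia, C1 Chiroptera, D1 Rodentia) and
# stem branches (BranchA1 Pinnipedia, BranchB1 Cetacea). `comparisons`
# records every nested test of the ladder together with its published
# likelihood-ratio statistic, degrees of freedom and p-value.
models:
  "A": ~
  "B": { fg1: [A1, BranchA1] }
  "C": { fg1: [A2] }
  "D": { fg1: [A3] }
  "E": { fg1: [B1, BranchB1] }
  "F": { fg1: [B2] }
  "G": { fg1: [BranchA1] }
  "H": { fg1: [BranchB1] }
  "I": { fg1: [C1] }
  "J": { fg1: [D1] }
  "K": { fg1: [A1, BranchA1, B1, BranchB1] }
  "L": { fg1: [A1, BranchA1], fg2: [B1, BranchB1] }
  "M": { fg1: [A1, B1], fg2: [BranchB1], fg3: [BranchA1] }
  "N": { fg1: [A1], fg2: [BranchA1], fg3: [B1], fg4: [BranchB1] }
comparisons:
  - { "null": "A", alt: "B", df: 1, lrt: 30.4, p: "<0.05" }
  - { "null": "A", alt: "C", df: 1, lrt: 0.68, p: "0.41" }
  - { "null": "A", alt: "D", df: 1, lrt: 0.36, p: "0.55" }
  - { "null": "A", alt: "E", df: 1, lrt: 35, p: "<0.05" }
  - { "null": "A", alt: "F", df: 1, lrt: 0.98, p: "0.32" }
  - { "null": "A", alt: "G", df: 1, lrt: 3.56, p: "0.06" }
  - { "null": "A", alt: "H", df: 1, lrt: 0.06, p: "0.81" }
  - { "null": "A", alt: "I", df: 1, lrt: 0.47, p: "0.49" }
  - { "null": "A", alt: "J", df: 1, lrt: 1.83, p: "0.18" }
  - { "null": "A", alt: "K", df: 1, lrt: 67.07, p: "<0.05" }
  - { "null": "A", alt: "L", df: 2, lrt: 67.76, p: "<0.05" }
  - { "null": "A", alt: "M", df: 3, lrt: 74.62, p: "<0.05" }
  - { "null": "A", alt: "N", df: 4, lrt: 74.62, p: "<0.05" }
  - { "null": "K", alt: "L", df: 1, lrt: 0.70, p: "0.40" }
  - { "null": "K", alt: "M", df: 2, lrt: 7.56, p: "<0.05" }
  - { "null": "K", alt: "N", df: 3, lrt: 7.56, p: "0.06" }
  - { "null": "M", alt: "N", df: 1, lrt: 0.00, p: "1.00" }
# omega estimates reported under the best-supported model (M)
omega_estimates:
  clade_pinnipedia_cetacea: 1.033
  branch_pinnipedia: 1.726
  branch_cetacea: 0.322
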