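# Model permeation landscape: interfacial entry barrier, interfacial well,
# midplane well (kcal/mol, Angstrom).  For `memperm.R generate windows`.
potential:
  heights: [2.14, -5.0, -4.0]
  centers: [20, 12, 0]
  widths: [2, 2, 3]
windows:
  centers: [35, 34, 33, 32, 31, 30, 29, 28, 27, 26, 25, 24, 23, 22, 21, 20,
            19, 18, 17, 16, 15, 14, 13, 12, 11, 10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0]
  force_constant: 2.39
  temperature: 303.15
  dt: 0.005
  n_steps: 100000
  seed: 1
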