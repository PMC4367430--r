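# Default plasma-liquid OH reaction network (mirrors build_default_network()).
# Rate coefficients are effective two-body values in cm^3/s; the three-body
# recombination is folded at third_body_density M.
species:
  - name: OH
    charge: 0
    composition: {H: 1, O: 1}
  - name: H2O2
    charge: 0
    composition: {H: 2, O: 2}
  - name: HO2
    charge: 0
    composition: {H: 1, O: 2}
  - name: H2O
    charge: 0
    composition: {H: 2, O: 1}
  - name: O
    charge: 0
    composition: {O: 1}
reactions:
  - reactants: {OH: 2}
    products: {H2O2: 1}
    k: 1.78e-11
    label: "OH + OH -> H2O2 (ambient air)"
  - reactants: {OH: 1, H2O2: 1}
    products: {HO2: 1, H2O: 1}
    k: 1.7e-12
    label: "OH + H2O2 -> HO2 + H2O"
  - reactants: {OH: 2}
    products: {H2O2: 1}
    k: 2.2e-11
    label: "OH + OH + M -> H2O2 + M (folded at M)"
  - reactants: {OH: 2}
    products: {H2O: 1, O: 1}
    k: 2.0e-12
    label: "secondary OH loss channel"
third_body_density: 2.5e+19
alpha_override: 2.3e-11
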