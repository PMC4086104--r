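# Polymerase-buffer presets.
#
# Exact ionic compositions of commercial high-fidelity buffers are
# proprietary; the monovalent/Tris/Mg values below are estimates assembled
# from typical published protocol sheets and should be treated as synthetic
# approximations (see each provenance_note). Users can override any preset,
# or add new ones, by supplying their own YAML file of the same shape.
#
# Concentration units: monovalent_mM, tris_mM, divalent_mM, dntp_mM in mM;
# primer_M and template_M in mol/L. dntp_mM is the TOTAL dNTP concentration
# (sum over the four nucleotides); Mg chelated by dNTPs is subtracted before
# the divalent term enters the monovalent-equivalent conversion.
#
# Presets use the symmetric equilibrium-constant formulation (K = 4/[Primer])
# for compatibility with the vendor calculators most users cross-check
# against; custom buffers built with buffer_conditions() default to the
# excess-primer simplification instead.
presets:
  - name: q5
    provenance_note: >
      High-fidelity Q5-style reaction buffer at 1x with the standard
      protocol (0.5 uM primers, 0.2 mM each dNTP, 2 mM Mg2+). Monovalent and
      Tris values are estimates; the true composition is proprietary.
    monovalent_mM: 80
    tris_mM: 20
    divalent_mM: 2.0
    dntp_mM: 0.8
    primer_M: 5.0e-7
    template_M: 5.0e-10
    k_mode: symmetric
  - name: phusion_hf
    provenance_note: >
      Phusion-style HF buffer at 1x (0.5 uM primers, 0.2 mM each dNTP,
      1.5 mM Mg2+). Monovalent and Tris values are estimates.
    monovalent_mM: 50
    tris_mM: 20
    divalent_mM: 1.5
    dntp_mM: 0.8
    primer_M: 5.0e-7
    template_M: 5.0e-10
    k_mode: symmetric
  - name: taq_standard
    provenance_note: >
      Classic Taq buffer: 50 mM KCl, 10 mM Tris-HCl, 1.5 mM MgCl2, 0.2 mM
      each dNTP, 0.2 uM primers. Composition published by most vendors.
    monovalent_mM: 50
    tris_mM: 10
    divalent_mM: 1.5
    dntp_mM: 0.8
    primer_M: 2.0e-7
    template_M: 5.0e-10
    k_mode: symmetric
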