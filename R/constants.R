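# Physical constants (SI, CODATA 2018)
.const <- list(
  kB = 1.380649e-23,      # Boltzmann constant, J K^-1
  Na = 6.02214076e23,     # Avogadro number, mol^-1
  R  = 8.314462618,       # universal gas constant, J mol^-1 K^-1
  water_molarity = 55.6   # molarity of pure water, mol L^-1
)
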