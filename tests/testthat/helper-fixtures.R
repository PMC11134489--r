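# Shared fixtures: everything is built in code at test time.

BENZENE <- "c1ccccc1"
PYRIDINE <- "c1ccncc1"
THIOPHENE <- "c1ccsc1"
TOLUENE <- "Cc1ccccc1"
INDOLE <- "c1ccc2[nH]ccc2c1"
BIPHENYL <- "c1ccc(-c2ccccc2)cc1"
PHBPIN <- "CC1(C)OB(OC1(C)C)c1ccccc1"
B2PIN2 <- "CC1(C)OB(OC1(C)C)B1OC(C)(C)C(C)(C)O1"

# one well-formed borylation reaction SMILES with Ir agent
borylation_rxn <- function(substrate, product) {
  paste0(substrate, ">", B2PIN2, ".[Ir]>", product)
}

# independent counting oracle for enumeration: substitute H -> Bpin at every
# raw eligible carbon position and count distinct canonical products
brute_force_products <- function(substrate, mode = "aromatic_CH") {
  mol <- borysite:::get_mol(substrate)
  eligible <- which(mol$elem == "C" & mol$nH >= 1L &
                    (if (mode == "aromatic_CH") mol$arom else TRUE))
  unique(vapply(eligible, function(a) attach_boron(substrate, a), character(1)))
}

# small diverse substrate panel used by several property tests
substrate_panel <- function(n = 25, seed = 42) generate_substrates(n, seed)
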