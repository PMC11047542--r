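# Shared fixtures built in code.

tiny_plate <- function() {
  PlateTimeSeries(
    times  = c(0, 60, 120),
    wells  = data.frame(well = c("A1", "A2"),
                        sample = c("Trolox", "BLANK"),
                        conc_uM = c(10, 0), replicate = c(1L, 1L)),
    signal = cbind(c(100, 90, 80), c(100, 60, 30)))
}

# Published frontier-orbital energies (eV) and the displayed descriptor
# values they should reproduce.
orbital_table <- function() {
  data.frame(
    molecule = c("Trolox", "Ascorbic acid", "RvD1", "Analogue 1", "Analogue 2"),
    e_homo = c(-5.294, -6.554, -6.045, -5.914, -5.690),
    e_lumo = c(-0.655, -1.324, -0.959, -0.490, -0.553),
    eta    = c(2.31, 2.61, 2.54, 2.71, 2.56),
    sigma  = c(0.432, 0.383, 0.393, 0.369, 0.390),
    chi    = c(2.974, 3.938, 3.500, 3.201, 3.121),
    omega  = c(1.914, 2.970, 2.411, 1.890, 1.902),
    mu     = c(-2.974, -3.938, -3.500, -3.201, -3.121))
}

# Hydroxyl bond lengths (Angstrom) per molecule, as tabulated from the
# optimized structures, with the resulting average lengths.
oh_length_table <- function() {
  read.csv(system.file("extdata", "oh_bond_lengths.csv", package = "oxicap"),
           check.names = FALSE)
}

extdata <- function(...) system.file("extdata", ..., package = "oxicap")
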