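#' The galectin-3 relative binding affinity benchmark
#'
#' Published relative binding free energies (kJ/mol) of seven
#' transformations between substituted
#' tetrafluorophenyl-triazole-thiogalactoside inhibitors of galectin-3,
#' calculated by alchemical FEP/MBAR under six method variants - three
#' ligand charge derivations (RH: RESP at HF geometries, BA: AM1-BCC at HF
#' geometries, BH: AM1-BCC at AM1 geometries) crossed with two perturbed
#' groups (SP: the substituent only, LP: the whole tetrafluorophenyl
#' group) - together with the experimental relative affinities from
#' competitive fluorescence polarisation (the Pyr->F measurement has no
#' reported standard error) and the published consensus column (mean over
#' the six variants, SE from their variation).
#'
#' @return `galectin3_calculated()`: an `"fep_results"` table with 42
#'   entries (7 transformations x 6 variants); `galectin3_experimental()`:
#'   an `"fep_experimental"` table with 7 entries;
#'   `galectin3_consensus()`: the published consensus column as an
#'   `"fep_experimental"`-shaped data frame.
#' @examples
#' res <- galectin3_calculated()
#' exp <- galectin3_experimental()
#' evaluate_affinities(res, exp, n_rep = 100, seed = 1)
#' @export
galectin3_calculated <- function() {
  read_result_table(system.file("extdata", "galectin3_calculated.tsv",
                                package = "relfep", mustWork = TRUE))
}

#' @rdname galectin3_calculated
#' @export
galectin3_experimental <- function() {
  read_experimental_table(system.file("extdata",
                                      "galectin3_experimental.tsv",
                                      package = "relfep", mustWork = TRUE))
}

#' @rdname galectin3_calculated
#' @export
galectin3_consensus <- function() {
  read_experimental_table(system.file("extdata", "galectin3_consensus.tsv",
                                      package = "relfep", mustWork = TRUE))
}

#' @rdname galectin3_calculated
#' @export
galectin3_transformations <- function() {
  c("OMe->OH", "NHMe->OMe", "NMe2->NHMe", "NMe2->NH2", "OEt->OMe",
    "Pyr->F", "OH->F")
}

#' Method-variant labels
#'
#' Renders a charge set (RH, BA or BH) and perturbed-group size (SP or LP)
#' as the conventional "charges/group" label.
#'
#' @param charge_set One of `"RH"`, `"BA"`, `"BH"`.
#' @param perturbed_group One of `"SP"`, `"LP"`.
#' @return The label string, e.g. `"BA/LP"`.
#' @export
method_variant <- function(charge_set = c("RH", "BA", "BH"),
                           perturbed_group = c("SP", "LP")) {
  paste(match.arg(charge_set), match.arg(perturbed_group), sep = "/")
}

#' @rdname method_variant
#' @export
method_variants <- function() {
  as.vector(outer(c("RH", "BA", "BH"), c("SP", "LP"),
                  function(a, b) paste(a, b, sep = "/")))
}
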