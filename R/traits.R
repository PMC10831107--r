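#' Boltzmann constant in electron volts per kelvin
#' @export
k_boltzmann_ev <- 8.617333e-5

#' Metabolic traits of an ecotype
#'
#' Bundles the two key metabolic traits that determine aerobic habitat
#' suitability, plus the constants entering the Metabolic Index:
#' the hypoxic tolerance coefficient `A_c` (normalized so that habitability
#' is \eqn{\phi > 1}) and the temperature sensitivity `E_o`, together with
#' the linear temperature correction of `E_o` and the reference temperature.
#'
#' @param A_c hypoxic tolerance coefficient, 1/atm; must be positive.
#'   A pure linear scale factor on \eqn{\phi}.
#' @param E_o temperature sensitivity of hypoxia vulnerability, eV. Values
#'   outside the commonly observed span \[-0.2, 1.0\] eV trigger a warning.
#' @param dEo_dT linear temperature dependence of `E_o`, eV/K
#'   (default 0.022).
#' @param T_ref reference temperature, K (default 288.15, i.e. 15 degC).
#' @param species optional label.
#' @return an object of class `trait_set`.
#' @examples
#' trait_set(A_c = 10, E_o = 0.4)
#' @export
trait_set <- function(A_c, E_o, dEo_dT = 0.022, T_ref = 288.15,
                      species = NULL) {
  stopifnot(is.numeric(A_c), length(A_c) == 1L, is.finite(A_c),
            is.numeric(E_o), length(E_o) == 1L, is.finite(E_o),
            is.numeric(dEo_dT), length(dEo_dT) == 1L,
            is.numeric(T_ref), length(T_ref) == 1L, T_ref > 0)
  if (A_c <= 0) stopf("A_c must be positive (got %g atm^-1)", A_c)
  if (E_o < -0.2 || E_o > 1.0)
    warnf("E_o = %g eV is outside the validated span [-0.2, 1.0] eV", E_o)
  structure(
    list(A_c = A_c, E_o = E_o, dEo_dT = dEo_dT, T_ref = T_ref,
         k_B = k_boltzmann_ev,
         species = species %||% sprintf("Eo=%.2f,Ac=%g", E_o, A_c)),
    class = "trait_set")
}

#' @export
print.trait_set <- function(x, ...) {
  cat(sprintf(
    "<trait_set> %s\n  A_c = %g atm^-1, E_o = %g eV, dEo/dT = %g eV/K, T_ref = %g K\n",
    x$species, x$A_c, x$E_o, x$dEo_dT, x$T_ref))
  invisible(x)
}

#' Read an ecotype trait table
#'
#' Reads a delimited text table of ecotype traits with columns
#' `species`, `A_c`, `E_o` (and optionally `dEo_dT`, `T_ref`).
#'
#' @param path path to a tab- or comma-delimited file with a header row.
#' @param sep field separator; guessed from the file extension by default.
#' @return a list of [trait_set] objects, named by species label.
#' @export
read_traits <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("species", "A_c", "E_o")
  if (!all(need %in% names(tab)))
    stopf("trait table must have columns %s", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    trait_set(A_c = tab$A_c[i], E_o = tab$E_o[i],
              dEo_dT = tab$dEo_dT[i] %||% 0.022,
              T_ref = if ("T_ref" %in% names(tab)) tab$T_ref[i] else 288.15,
              species = tab$species[i])
  })
  stats::setNames(out, tab$species)
}
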