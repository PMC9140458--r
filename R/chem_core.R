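# Adduct masses (Da) for singly protonated ions. The hydrogen-atom constant
# reproduces published 4-d.p. MH+ values for nucleosides; the proton constant
# is the physically rigorous alternative (differs by the electron mass).
.ADDUCT_MASS <- c(hydrogen = 1.00783, proton = 1.00728)

#' Mass convention for singly protonated ions
#'
#' MRM methods for nucleosides monitor the singly protonated molecule, MH+.
#' Two conventions for the adduct mass are in circulation: addition of a
#' hydrogen atom (1.00783 Da) and addition of a bare proton (1.00728 Da,
#' i.e. a hydrogen atom minus the electron mass). Published transition
#' tables for nucleosides round to values consistent with the hydrogen-atom
#' convention, which is therefore the default throughout this package.
#'
#' @param mode `"hydrogen"` (default) or `"proton"`.
#' @return An object of class `mass_convention` with the adduct mass in Da.
#' @examples
#' mass_convention()$adduct_mass            # 1.00783
#' mass_convention("proton")$adduct_mass    # 1.00728
#' @export
mass_convention <- function(mode = c("hydrogen", "proton")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, adduct_mass = unname(.ADDUCT_MASS[mode])),
            class = "mass_convention")
}

#' @export
print.mass_convention <- function(x, ...) {
  cat(sprintf("<mass_convention: %s addition, +%.5f Da>\n",
              x$mode, x$adduct_mass))
  invisible(x)
}

#' Parse a flat molecular formula
#'
#' Parses a flat (non-parenthesised) molecular formula such as
#' `"C11H15N5O4"` into an elemental composition. Element symbols must be
#' present in the isotope table in use; counts are optional positive
#' integers (absent count means 1). No charges, isotope labels, hydrates or
#' parentheses are accepted: catalogs must use expanded formulas.
#'
#' @param text Formula string, e.g. `"C9H12N2O5S"`.
#' @param elements Character vector of permitted element symbols; defaults
#'   to the symbols of the packaged isotope table.
#' @return An `elemental_formula`: a named integer vector of atom counts.
#' @examples
#' parse_formula("C11H15N5O4")
#' parse_formula("H")
#' @export
parse_formula <- function(text, elements = known_elements()) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string", call. = FALSE)
  if (!nzchar(text))
    stop("empty formula string", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || m[1] != 1L)
    stop(sprintf("cannot parse formula '%s': unexpected characters", text),
         call. = FALSE)
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  bad <- setdiff(syms, elements)
  if (length(bad))
    stop(sprintf("unknown element symbol(s) in '%s': %s",
                 text, paste(unique(bad), collapse = ", ")), call. = FALSE)
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  if (anyNA(counts) || any(counts <= 0L))
    stop(sprintf("zero or invalid atom count in formula '%s'", text),
         call. = FALSE)
  out <- tapply(counts, factor(syms, levels = unique(syms)), sum)
  formula_from_counts(as.integer(out), names(out))
}

formula_from_counts <- function(counts, symbols) {
  counts <- as.integer(counts)
  names(counts) <- symbols
  counts <- counts[counts > 0L]
  structure(counts, class = "elemental_formula")
}

#' Write a formula in Hill order
#'
#' Canonical writer: carbon first, then hydrogen, then remaining elements
#' alphabetically; count 1 is left implicit. `write_formula(parse_formula(x))`
#' is the identity on canonical strings.
#'
#' @param f An `elemental_formula`.
#' @return A single character string.
#' @export
write_formula <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return("")
  syms <- names(f)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  paste0(vapply(ord, function(s) {
    n <- f[[s]]
    if (n == 1L) s else paste0(s, n)
  }, character(1)), collapse = "")
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  stop("not an elemental formula", call. = FALSE)
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula:", write_formula(x), ">\n")
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) write_formula(x)

#' Formula arithmetic
#'
#' Element-wise addition and subtraction of elemental compositions.
#' Subtraction models a neutral loss; a loss exceeding the available atoms
#' of any element is an error naming that element. Monoisotopic mass is
#' conserved: `mass(f) == mass(subtract_loss(f, loss)) + mass(loss)`.
#'
#' @param f,a,b,loss `elemental_formula` objects (or formula strings).
#' @return An `elemental_formula`.
#' @examples
#' subtract_loss("C10H13N5O4", "C5H8O4")   # adenine, C5H5N5
#' @export
subtract_loss <- function(f, loss) {
  f <- as_formula(f); loss <- as_formula(loss)
  syms <- union(names(f), names(loss))
  fv <- ifelse(syms %in% names(f), f[syms], 0L)
  lv <- ifelse(syms %in% names(loss), loss[syms], 0L)
  res <- fv - lv
  if (any(res < 0L)) {
    bad <- syms[res < 0L]
    stop(sprintf("loss exceeds formula for element(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  formula_from_counts(res, syms)
}

#' @rdname subtract_loss
#' @export
add_formula <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  syms <- union(names(a), names(b))
  av <- ifelse(syms %in% names(a), a[syms], 0L)
  bv <- ifelse(syms %in% names(b), b[syms], 0L)
  formula_from_counts(av + bv, syms)
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum over elements of atom count times the exact mass of the lightest
#' isotope, from the isotope table in use.
#'
#' @param f An `elemental_formula` or formula string.
#' @param table An isotope table from [isotope_table()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C5H8O4")    # ribose neutral loss, 132.0423
#' monoisotopic_mass("C6H10O4")   # 2'-O-methylribose neutral loss, 146.0579
#' @export
monoisotopic_mass <- function(f, table = isotope_table()) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  mono <- monoisotopic_masses(table)
  bad <- setdiff(names(f), names(mono))
  if (length(bad))
    stop(sprintf("element(s) not in isotope table: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  sum(as.numeric(f) * mono[names(f)])
}

#' m/z of the singly protonated molecule (MH+)
#'
#' @inheritParams monoisotopic_mass
#' @param conv A [mass_convention()].
#' @return m/z in Da (singly charged).
#' @examples
#' protonated_mass("C12H17N5O4")  # 296.1359 (N6,N6-dimethyladenosine)
#' protonated_mass("C11H13N5O5")  # 296.0995 (N6-formyladenosine)
#' @export
protonated_mass <- function(f, conv = mass_convention(),
                            table = isotope_table()) {
  monoisotopic_mass(f, table) + conv$adduct_mass
}

# Round half away from zero, as used in printed transition tables
# (base R round() is round-half-even).
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
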