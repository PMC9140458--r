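# MRM transition generation. Precursor = MH+ of the intact nucleoside;
# product = BH2+, the protonated nucleobase left after neutral loss of the
# sugar across the N-glycosidic bond: C5H8O4 (132.0423 Da) for an
# unmodified ribose, C6H10O4 (146.0579 Da) for a 2'-O-methylribose.
# C-glycosides (pseudouridine family) do not yield BH2+; their product
# ions are data overrides.

RIBOSE_LOSS <- "C5H8O4"
METHYLRIBOSE_LOSS <- "C6H10O4"

#' Precursor ion (MH+) of a nucleoside
#'
#' @param n One catalog row (a one-row `nucleoside_catalog` subset or a
#'   list with at least `formula`).
#' @param conv A [mass_convention()].
#' @param table An [isotope_table()].
#' @return List with `exact` (m/z in Da) and `nominal` (rounded half-up
#'   to one decimal, the convention of printed transition tables).
#' @examples
#' cat <- builtin_catalog()
#' precursor_ion(catalog_lookup(cat, "Y"))$nominal   # 245.1
#' @export
precursor_ion <- function(n, conv = mass_convention(),
                          table = isotope_table()) {
  exact <- protonated_mass(n$formula, conv, table)
  list(exact = exact, nominal = round_half_up(exact, 1L))
}

#' Product ions (BH2+ or overrides) of a nucleoside
#'
#' Rule order: explicit `product_overrides` are returned verbatim
#' (nominal as printed, exact absent); otherwise a 2'-O-methyl sugar loses
#' C6H10O4 and an unmodified N-glycoside loses C5H8O4, with the product
#' exact mass computed as precursor exact minus the neutral-loss mass.
#' A C-glycoside without overrides has no observable protonated
#' nucleobase and is an error (un-monitorable).
#'
#' @inheritParams precursor_ion
#' @return Data frame with columns `exact` (NA for overrides), `nominal`
#'   (integer m/z, rounded half-up) and `rule`
#'   (`"base-loss"`, `"methylribose-loss"` or `"override"`).
#' @examples
#' cat <- builtin_catalog()
#' product_ions(catalog_lookup(cat, "m1A"))$nominal   # 150
#' product_ions(catalog_lookup(cat, "Am"))$nominal    # 136
#' product_ions(catalog_lookup(cat, "Y"))$nominal     # 209 179 155
#' @export
product_ions <- function(n, conv = mass_convention(),
                         table = isotope_table()) {
  overrides <- .parse_overrides(n$product_overrides)
  if (length(overrides)) {
    return(data.frame(exact = NA_real_, nominal = overrides,
                      rule = "override", stringsAsFactors = FALSE))
  }
  if (identical(n$glycosidic_bond, "C"))
    stop(sprintf(
      "%s is un-monitorable: C-glycoside without product overrides (no BH2+)",
      n$abbreviation), call. = FALSE)
  loss <- if (identical(n$sugar_mod, "2'-O-methyl")) METHYLRIBOSE_LOSS
          else RIBOSE_LOSS
  rule <- if (identical(n$sugar_mod, "2'-O-methyl")) "methylribose-loss"
          else "base-loss"
  subtract_loss(n$formula, loss)  # errors early if the loss does not fit
  exact <- protonated_mass(n$formula, conv, table) -
    monoisotopic_mass(loss, table)
  data.frame(exact = exact, nominal = round_half_up(exact, 0L),
             rule = rule, stringsAsFactors = FALSE)
}

#' All MRM transitions for a catalog
#'
#' One row per species-product pair, in catalog order with products in
#' descending m/z. Species without computable transitions (C-glycosides
#' lacking overrides) do not abort the batch; they are collected in the
#' `skipped` attribute with the reason.
#'
#' @param catalog A `nucleoside_catalog`.
#' @inheritParams precursor_ion
#' @return Data frame with columns `abbreviation`, `formula`,
#'   `precursor_exact`, `precursor_nominal`, `product_exact`,
#'   `product_nominal`, `rule`; attribute `skipped` is a data frame of
#'   (abbreviation, reason).
#' @examples
#' tr <- transitions_for_catalog(builtin_catalog())
#' subset(tr, abbreviation == "m7G")  # 298.1 -> 166
#' @export
transitions_for_catalog <- function(catalog, conv = mass_convention(),
                                    table = isotope_table()) {
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(catalog))) {
    sp <- catalog[i, , drop = FALSE]
    prec <- precursor_ion(sp, conv, table)
    prods <- tryCatch(product_ions(sp, conv, table), error = function(e) e)
    if (inherits(prods, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        abbreviation = sp$abbreviation, reason = conditionMessage(prods),
        stringsAsFactors = FALSE)
      next
    }
    ord <- order(prods$nominal, decreasing = TRUE)
    prods <- prods[ord, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      abbreviation = sp$abbreviation, formula = sp$formula,
      precursor_exact = prec$exact, precursor_nominal = prec$nominal,
      product_exact = prods$exact, product_nominal = prods$nominal,
      rule = prods$rule, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(abbreviation = character(0), formula = character(0),
               precursor_exact = numeric(0), precursor_nominal = numeric(0),
               product_exact = numeric(0), product_nominal = numeric(0),
               rule = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(abbreviation = character(0), reason = character(0))
  out
}
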