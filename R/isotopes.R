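# Isotopologue distributions aggregated by nominal mass shift.
#
# The instrument model is a unit-resolution triple quadrupole, so
# distributions are bucketed by integer mass shift k relative to the
# all-light isotopologue, not by exact fine structure. Because isotope
# offsets are non-negative, a convolution truncated at max_k is exact for
# every k <= max_k; the abundance mass beyond max_k is carried in
# `truncation_bound` (and equals 1 - sum(entries) exactly).

new_isotopologue_distribution <- function(formula, abundance, mass_sum,
                                          max_k) {
  k <- seq_len(max_k + 1L) - 1L
  centroid <- ifelse(abundance > 0, mass_sum / abundance, NA_real_)
  structure(list(
    formula = formula,
    max_k = max_k,
    abundance = stats::setNames(abundance, k),
    centroid_mass = stats::setNames(centroid, k),
    mass_sum = mass_sum,
    truncation_bound = max(0, 1 - sum(abundance))
  ), class = "isotopologue_distribution")
}

#' @export
print.isotopologue_distribution <- function(x, digits = 6, ...) {
  cat(sprintf("<isotopologue distribution of %s, max shift %d>\n",
              write_formula(x$formula), x$max_k))
  print(round(x$abundance, digits))
  cat(sprintf("truncation bound: %.3g\n", x$truncation_bound))
  invisible(x)
}

#' Isotopologue distribution of n atoms of one element
#'
#' Distribution of the total nominal mass shift of `count` independent
#' atoms of one element, aggregated by shift (the multinomial distribution
#' over isotope assignments, summed within each total shift), truncated at
#' `max_k` with the residual abundance recorded in `truncation_bound`.
#'
#' @param symbol Element symbol present in `table`.
#' @param count Number of atoms (>= 0).
#' @param max_k Largest nominal shift retained.
#' @param table An [isotope_table()].
#' @return An `isotopologue_distribution`.
#' @examples
#' element_distribution("S", 1, 4, isotope_table("minimal"))$abundance[["2"]]
#' @export
element_distribution <- function(symbol, count, max_k = 2L,
                                 table = isotope_table()) {
  if (count < 0L) stop("count must be >= 0", call. = FALSE)
  max_k <- as.integer(max_k)
  f <- if (count > 0L) formula_from_counts(count, symbol) else
    formula_from_counts(integer(0), character(0))
  if (count > 0L && !symbol %in% table$symbol)
    stop(sprintf("unknown element '%s'", symbol), call. = FALSE)
  abund <- c(1, rep(0, max_k))
  msum <- c(0, rep(0, max_k))
  if (count == 0L)
    return(new_isotopologue_distribution(f, abund, msum, max_k))
  sub <- table[table$symbol == symbol, ]
  one_ab <- rep(0, max_k + 1L)
  one_ms <- rep(0, max_k + 1L)
  keep <- sub$offset <= max_k
  one_ab[sub$offset[keep] + 1L] <- sub$abundance[keep]
  one_ms[sub$offset[keep] + 1L] <- sub$abundance[keep] * sub$exact_mass[keep]
  abund <- one_ab; msum <- one_ms
  for (i in seq_len(count - 1L)) {
    res <- .convolve_vectors(abund, msum, one_ab, one_ms)
    abund <- res$abundance; msum <- res$mass_sum
  }
  new_isotopologue_distribution(f, abund, msum, max_k)
}

# Truncated convolution of (abundance, abundance-weighted mass) vectors.
.convolve_vectors <- function(a_ab, a_ms, b_ab, b_ms) {
  n <- length(a_ab)
  ab <- numeric(n); ms <- numeric(n)
  for (k in seq_len(n)) {
    j <- seq_len(k)
    ab[k] <- sum(a_ab[j] * b_ab[k - j + 1L])
    ms[k] <- sum(a_ms[j] * b_ab[k - j + 1L] + a_ab[j] * b_ms[k - j + 1L])
  }
  list(abundance = ab, mass_sum = ms)
}

#' Convolve two isotopologue distributions
#'
#' Polynomial convolution: the distribution of the combined molecule
#' `a$formula + b$formula`. Exact for every shift up to the shared
#' `max_k`; the truncation bound is propagated as the exact lost mass.
#'
#' @param a,b `isotopologue_distribution` objects with equal `max_k`.
#' @return An `isotopologue_distribution`.
#' @export
convolve_distributions <- function(a, b) {
  stopifnot(inherits(a, "isotopologue_distribution"),
            inherits(b, "isotopologue_distribution"))
  if (a$max_k != b$max_k)
    stop("distributions must share max_k", call. = FALSE)
  res <- .convolve_vectors(unname(a$abundance), a$mass_sum,
                           unname(b$abundance), b$mass_sum)
  new_isotopologue_distribution(add_formula(a$formula, b$formula),
                                res$abundance, res$mass_sum, a$max_k)
}

#' Isotopologue distribution of a molecular formula
#'
#' Convolution of the per-element distributions over all elements of the
#' formula. The entry at shift 0 is the all-light isotopologue, whose
#' abundance equals the product of lightest-isotope abundances over atoms.
#'
#' @param f An `elemental_formula` or formula string.
#' @inheritParams element_distribution
#' @return An `isotopologue_distribution`.
#' @examples
#' formula_distribution("C10H13N5O4")$abundance   # adenosine
#' @export
formula_distribution <- function(f, max_k = 2L, table = isotope_table()) {
  f <- as_formula(f)
  max_k <- as.integer(max_k)
  out <- element_distribution(if (length(f)) names(f)[1] else "C",
                              if (length(f)) f[[1]] else 0L, max_k, table)
  if (length(f) > 1L) {
    for (i in 2:length(f)) {
      out <- convolve_distributions(
        out, element_distribution(names(f)[i], f[[i]], max_k, table))
    }
  }
  out
}

#' Fragment-conditional crosstalk abundance
#'
#' Fraction of a species' ion population that appears in the channel
#' shifted by `k` nominal mass units on both quadrupoles: all `k` heavy
#' isotopes must reside in the retained fragment (the protonated
#' nucleobase), while the neutral loss is all-light. Equals
#' `formula_distribution(base)[k] * formula_distribution(loss)[0]`.
#'
#' The complementary "partial" configuration (heavies in the neutral loss:
#' precursor shifted, product not) is
#' `partial_crosstalk_factor()`, computed as `base[0] * loss[k]`.
#'
#' @param base Retained fragment formula (neutral base; protonation does
#'   not change the isotope pattern materially and is ignored here).
#' @param loss Neutral-loss formula.
#' @param k Nominal shift, >= 1.
#' @inheritParams element_distribution
#' @return Abundance in `[0, 1]`.
#' @examples
#' fragment_crosstalk_factor("C5H5N5", "C5H8O4", 1)  # adenosine +1 -> both-shifted
#' @export
fragment_crosstalk_factor <- function(base, loss, k, table = isotope_table()) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  db <- formula_distribution(base, max_k = k, table = table)
  dl <- formula_distribution(loss, max_k = k, table = table)
  unname(db$abundance[[as.character(k)]] * dl$abundance[["0"]])
}

#' @rdname fragment_crosstalk_factor
#' @export
partial_crosstalk_factor <- function(base, loss, k, table = isotope_table()) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  db <- formula_distribution(base, max_k = k, table = table)
  dl <- formula_distribution(loss, max_k = k, table = table)
  unname(db$abundance[["0"]] * dl$abundance[[as.character(k)]])
}

#' Export a distribution as delimited text
#'
#' One row per computed shift: formula, shift, aggregated abundance, and
#' the exact mass of the abundance-weighted centroid of that unit-mass
#' bucket.
#'
#' @param d An `isotopologue_distribution`.
#' @param path Output file; `""` writes to stdout.
#' @return The exported data frame, invisibly.
#' @export
export_distribution <- function(d, path = "") {
  stopifnot(inherits(d, "isotopologue_distribution"))
  df <- data.frame(
    formula = write_formula(d$formula),
    k = as.integer(names(d$abundance)),
    abundance = unname(d$abundance),
    centroid_exact_mass = unname(d$centroid_mass)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
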