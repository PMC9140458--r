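# Cache for the packaged isotope tables, filled lazily.
.iso_env <- new.env(parent = emptyenv())

#' Isotope tables
#'
#' An isotope table lists, per element, the stable isotopes as
#' (nominal mass offset relative to the lightest isotope, exact mass,
#' relative abundance). Two packaged tables are provided:
#'
#' * `"full"` (default): all stable isotopes of H, C, N, O, S (plus P),
#'   with standard IUPAC exact masses and representative abundances.
#' * `"minimal"`: a reduced two-isotope table keeping only the dominant
#'   heavy isotope of each element at the abundances commonly quoted in
#'   the nucleoside LC-MS/MS literature (13C 1.11%, 2H 0.0115%,
#'   15N 0.364%, 18O 0.205%, 34S 4.21%), with the light-isotope abundance
#'   as the complement. Useful for pedagogical reproduction of published
#'   isotopic-crosstalk figures; the full table moves +1 abundances at the
#'   third significant digit.
#'
#' A user table in the same layout (TSV with columns `symbol`, `offset`,
#' `exact_mass`, `abundance`) can be loaded with [read_isotope_table()].
#'
#' @param mode `"full"` or `"minimal"`.
#' @return An `isotope_table`: a data frame with columns `symbol`,
#'   `offset`, `exact_mass`, `abundance`.
#' @examples
#' subset(isotope_table("minimal"), symbol == "S")
#' @export
isotope_table <- function(mode = c("full", "minimal")) {
  mode <- match.arg(mode)
  key <- paste0("table_", mode)
  if (!is.null(.iso_env[[key]])) return(.iso_env[[key]])
  path <- system.file("extdata", "isotopes.tsv", package = "mrmscreen",
                      mustWork = TRUE)
  tab <- read_isotope_table(path)
  if (mode == "minimal") tab <- .minimal_table(tab)
  .iso_env[[key]] <- tab
  tab
}

# Keep, per element, only offset 0 and the single most abundant heavy
# isotope, with the literature-standard heavy abundances.
.minimal_table <- function(full) {
  heavy <- c(H = 0.000115, C = 0.0111, N = 0.00364, O = 0.00205, S = 0.0421)
  hoff  <- c(H = 1L, C = 1L, N = 1L, O = 2L, S = 2L)
  rows <- lapply(unique(full$symbol), function(s) {
    light <- full[full$symbol == s & full$offset == 0L, ]
    if (!s %in% names(heavy)) {
      light$abundance <- 1
      return(light)
    }
    hv <- full[full$symbol == s & full$offset == hoff[[s]], ]
    light$abundance <- 1 - heavy[[s]]
    hv$abundance <- heavy[[s]]
    rbind(light, hv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- class(full)
  out
}

#' Read an isotope table from a delimited file
#'
#' @param path TSV file with header `symbol`, `offset`, `exact_mass`,
#'   `abundance`.
#' @return An `isotope_table` data frame, validated: per-element abundances
#'   sum to 1 within 1e-6, offsets are distinct non-negative integers and
#'   offset 0 is present for every element.
#' @export
read_isotope_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "offset", "exact_mass", "abundance")
  if (!all(need %in% names(tab)))
    stop("isotope table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$offset <- as.integer(tab$offset)
  for (s in unique(tab$symbol)) {
    sub <- tab[tab$symbol == s, ]
    if (any(sub$offset < 0L) || anyDuplicated(sub$offset))
      stop(sprintf("element %s: offsets must be distinct and >= 0", s),
           call. = FALSE)
    if (!0L %in% sub$offset)
      stop(sprintf("element %s: offset 0 (lightest isotope) missing", s),
           call. = FALSE)
    if (abs(sum(sub$abundance) - 1) > 1e-6)
      stop(sprintf("element %s: abundances sum to %.8f, not 1", s,
                   sum(sub$abundance)), call. = FALSE)
  }
  structure(tab, class = c("isotope_table", "data.frame"))
}

#' Element symbols known to the packaged isotope table
#' @return Character vector of symbols.
#' @export
known_elements <- function() unique(isotope_table()$symbol)

# Named vector of lightest-isotope exact masses.
monoisotopic_masses <- function(table = isotope_table()) {
  light <- table[table$offset == 0L, ]
  stats::setNames(light$exact_mass, light$symbol)
}
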