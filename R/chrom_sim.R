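# Synthetic MRM chromatograms: Gaussian peaks per species, contributed to
# the species' own channel(s) with weight 1 and to crosstalk channels with
# the fragment-conditional isotopologue weight. Purely illustrative of
# channel sharing and isotopic bleed-through; no retention prediction.

#' Build a peak model table
#'
#' @param abbreviation Species short codes (must be in the catalog used
#'   for simulation).
#' @param rt Retention times in minutes.
#' @param sigma Gaussian peak widths (standard deviation, minutes).
#' @param amount Injected amount, arbitrary quantity units.
#' @param response_factor Signal per unit amount; captures ionization
#'   efficiency differences (a poorly protonating species gets a small
#'   value).
#' @return Data frame of class `peak_model`.
#' @export
peak_model <- function(abbreviation, rt, sigma = 0.2, amount = 1,
                       response_factor = 1) {
  df <- data.frame(abbreviation = abbreviation, rt = rt, sigma = sigma,
                   amount = amount, response_factor = response_factor,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$sigma > 0), all(df$amount >= 0),
            all(df$response_factor >= 0))
  class(df) <- c("peak_model", "data.frame")
  df
}

#' Simulate MRM chromatogram traces
#'
#' Each panel species contributes a Gaussian of area
#' `amount * response_factor` to every channel it shares (within the
#' resolution window) and a Gaussian scaled by the fragment-conditional
#' crosstalk abundance to every channel its +k isotopologue reaches.
#' Without a seed the output is deterministic and each trace equals the
#' exact sum of its per-species contributions. With a seed, Poisson
#' counting noise (plus a small constant baseline) is applied to the
#' total; the noise is reported as its own component so the contribution
#' bookkeeping still closes.
#'
#' @param panel A [peak_model()] table.
#' @param catalog A `nucleoside_catalog` containing every panel species.
#' @param channels `"auto"` (all primary channels of the panel species)
#'   or a data frame with columns `abbreviation` (channel owner) selecting
#'   which species' channels to monitor.
#' @param params A [screening_params()].
#' @param grid Time grid in minutes; defaults to covering all peaks
#'   +/- 5 sigma at 0.01-min steps within a 50-min run.
#' @param seed Optional integer; enables counting noise.
#' @param noise_baseline Baseline counts added under Poisson noise.
#' @param conv,table Mass convention and isotope table.
#' @return List of `simulated_trace` objects: each has `channel`
#'   (owner, precursor, product), `time`, `intensity`, and
#'   `contributions` (matrix time x component).
#' @export
simulate_chromatograms <- function(panel, catalog, channels = "auto",
                                   params = screening_params(),
                                   grid = NULL, seed = NULL,
                                   noise_baseline = 5,
                                   conv = mass_convention(),
                                   table = isotope_table()) {
  missing_sp <- setdiff(panel$abbreviation, catalog$abbreviation)
  if (length(missing_sp))
    stop("species missing from catalog: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  sub <- catalog[catalog$abbreviation %in% panel$abbreviation, ,
                 drop = FALSE]
  si <- .species_info(sub, params, conv, table)
  if (identical(channels, "auto")) {
    chan_owners <- panel$abbreviation
  } else {
    chan_owners <- channels$abbreviation
  }
  if (is.null(grid)) {
    lo <- max(0, min(panel$rt - 5 * panel$sigma))
    hi <- min(50, max(panel$rt + 5 * panel$sigma))
    grid <- seq(lo, hi, by = 0.01)
  }
  if (!length(grid)) stop("empty time grid", call. = FALSE)
  traces <- list()
  for (owner in chan_owners) {
    och <- si$info[[owner]]$channels
    for (ci in seq_len(nrow(och))) {
      target <- och[ci, , drop = FALSE]
      comp <- list()
      for (sp in panel$abbreviation) {
        pk <- panel[panel$abbreviation == sp, , drop = FALSE]
        area0 <- pk$amount * pk$response_factor
        spch <- si$info[[sp]]$channels
        weight <- 0
        for (i in seq_len(nrow(spch))) {
          if (same_channel(spch[i, , drop = FALSE], target, params)) {
            weight <- weight + 1
            break
          }
        }
        if (weight == 0 && nrow(spch) && !is.na(spch$product_exact[1])) {
          tprod <- if (is.na(target$product_exact)) target$product_nominal
                   else target$product_exact
          for (k in seq_len(params$max_shift)) {
            hit <- FALSE
            for (i in seq_len(nrow(spch))) {
              dprec <- abs(spch$precursor_exact[i] + k * .SHIFT_UNIT -
                             target$precursor_exact)
              dprod <- abs(spch$product_exact[i] + k * .SHIFT_UNIT - tprod)
              if (dprec < params$resolution && dprod < params$resolution)
                hit <- TRUE
            }
            if (hit && !is.na(si$info[[sp]]$crosstalk[k]))
              weight <- weight + si$info[[sp]]$crosstalk[k]
          }
        }
        if (weight > 0) {
          comp[[sp]] <- area0 * weight *
            stats::dnorm(grid, mean = pk$rt, sd = pk$sigma)
        }
      }
      contributions <- if (length(comp))
        do.call(cbind, comp) else matrix(0, length(grid), 0)
      intensity <- if (ncol(contributions)) rowSums(contributions) else
        rep(0, length(grid))
      if (!is.null(seed)) {
        set.seed(seed + ci)
        noisy <- stats::rpois(length(grid),
                              lambda = intensity + noise_baseline)
        contributions <- cbind(contributions, noise = noisy - intensity)
        intensity <- noisy
      }
      traces[[length(traces) + 1L]] <- structure(list(
        channel = list(owner = owner,
                       precursor = target$precursor_nominal,
                       product = target$product_nominal),
        time = grid, intensity = intensity,
        contributions = contributions), class = "simulated_trace")
    }
  }
  traces
}

#' @export
print.simulated_trace <- function(x, ...) {
  cat(sprintf("<simulated trace: channel %.1f -> %s (%s), %d points, max %.3g>\n",
              x$channel$precursor, x$channel$product, x$channel$owner,
              length(x$time), max(x$intensity)))
  invisible(x)
}

#' Trapezoidal peak area of a trace (or one contribution)
#'
#' @param trace A `simulated_trace`.
#' @param component Optional contribution column name; default total.
#' @return Area in intensity x minutes.
#' @export
trace_area <- function(trace, component = NULL) {
  y <- if (is.null(component)) trace$intensity else
    trace$contributions[, component]
  x <- trace$time
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Elution orders stated for the monomethyladenosine standards on the
# three column chemistries, encoded as ordinal ranks (no invented
# absolute times). PFP did not baseline-separate m2A and m6A.
.ELUTION_ORDERS <- list(
  HILIC = list(order = c("m6A", "m2A", "m1A"),
               not_baseline_separated = character(0)),
  PFP   = list(order = c("m1A", "m2A", "m6A"),
               not_baseline_separated = c("m2A", "m6A")),
  ODS   = list(order = c("m1A", "m2A", "m6A"),
               not_baseline_separated = character(0))
)

#' Ordinal elution ranks on the three column chemistries
#'
#' Returns the observed elution order of the monomethyladenosine isomers
#' as ordinal ranks for a given column chemistry (HILIC amide, PFP, or
#' ODS C18), plus which pairs were not baseline separated. The run-time
#' envelope of the 50-min method is attached as attribute `run_time` and
#' is the default grid span for [simulate_chromatograms()]. Ranks are
#' ordinal only; when absolute times are needed for simulation they are
#' synthesized by spacing ranks uniformly over the run (illustrative, not
#' physical).
#'
#' @param column `"HILIC"`, `"PFP"` or `"ODS"`.
#' @return Data frame with columns `abbreviation`, `rank`; attributes
#'   `not_baseline_separated` (character vector) and `run_time` (50).
#' @examples
#' elution_order_fixture("HILIC")
#' @export
elution_order_fixture <- function(column = c("HILIC", "PFP", "ODS")) {
  if (!is.character(column) || !column[1] %in% names(.ELUTION_ORDERS))
    stop(sprintf("unknown column '%s'; use HILIC, PFP or ODS",
                 as.character(column)[1]), call. = FALSE)
  column <- match.arg(column)
  fx <- .ELUTION_ORDERS[[column]]
  out <- data.frame(abbreviation = fx$order,
                    rank = seq_along(fx$order), stringsAsFactors = FALSE)
  attr(out, "not_baseline_separated") <- fx$not_baseline_separated
  attr(out, "run_time") <- 50
  out
}
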