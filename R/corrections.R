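#' Define one linear fractionation-correction step
#'
#' Isotope values measured on bone mineral are related to the quantities of
#' interest (drinking water, diet) through a chain of well-characterised
#' linear fractionation relationships. Each step maps a per-mil value v to
#' `slope * v + intercept`; a step with slope 1 and intercept 0 is the
#' identity.
#'
#' @param name short label for the step (e.g. `"suess"`).
#' @param slope dimensionless multiplier.
#' @param intercept additive offset in per mil.
#' @param citation_note free-text provenance note carried through to output.
#' @return An object of class `"correction_step"`.
#' @seealso [apply_chain()], [default_d18o_chain()], [d13c_corrections()]
#' @export
#' @examples
#' suess <- correction_step("suess", 1, 1.5)
#' apply_chain(-10, list(suess))
correction_step <- function(name, slope = 1, intercept = 0, citation_note = "") {
  stopifnot(is.character(name), length(name) == 1L)
  stop_if_not_scalar_finite(slope, "slope")
  stop_if_not_scalar_finite(intercept, "intercept")
  structure(
    list(name = name, slope = slope, intercept = intercept,
         citation_note = citation_note),
    class = "correction_step"
  )
}

#' @export
print.correction_step <- function(x, ...) {
  cat(sprintf("correction step '%s': v <- %g * v + %g\n",
              x$name, x$slope, x$intercept))
  invisible(x)
}

#' Apply an ordered chain of correction steps to raw isotope values
#'
#' Folds `v <- slope * v + intercept` over the steps in order. The empty
#' chain is the identity, and chains compose associatively, so a chain can
#' be split or concatenated freely.
#'
#' @param raw_value numeric vector of per-mil values; must be finite.
#' @param chain list of [correction_step()] objects (possibly empty).
#' @return Numeric vector of corrected per-mil values.
#' @export
#' @examples
#' # VPDB -> VSMOW scale conversion of 0 per mil
#' apply_chain(0, list(correction_step("vpdb_to_vsmow", 1.03091, 30.91)))
apply_chain <- function(raw_value, chain = list()) {
  if (!is.numeric(raw_value) || any(!is.finite(raw_value)))
    stop("raw_value must be finite numeric", call. = FALSE)
  if (inherits(chain, "correction_step")) chain <- list(chain)
  v <- raw_value
  for (step in chain) {
    if (!inherits(step, "correction_step"))
      stop("chain must contain correction_step objects", call. = FALSE)
    v <- step$slope * v + step$intercept
  }
  v
}

#' Default chain from bone carbonate delta18O (VPDB) to drinking-water
#' delta18O (VSMOW)
#'
#' Three canonical steps: the VPDB to VSMOW scale conversion
#' (`v <- 1.03091 v + 30.91`), a constant carbonate-to-phosphate offset
#' (`-8.5` per mil), and the inversion of the phosphate--water body
#' fractionation (`v <- (v - 22.7) / 0.78`). These are conventional
#' literature stand-ins; every step is replaceable, and corrected values
#' can also be supplied directly (see [read_samples()]), in which case no
#' chain is applied.
#'
#' @return List of three [correction_step()] objects.
#' @export
default_d18o_chain <- function() {
  list(
    correction_step("vpdb_to_vsmow", 1.03091, 30.91,
                    "carbonate scale conversion"),
    correction_step("carbonate_to_phosphate", 1, -8.5,
                    "structural carbonate vs phosphate offset"),
    correction_step("phosphate_to_water", 1 / 0.78, -22.7 / 0.78,
                    "inverted body-water fractionation")
  )
}

#' Named delta13C correction constants
#'
#' Additive corrections used when placing bone and comparative plant or
#' camelid values on a common dietary scale: the post-industrial fossil
#' fuel (Suess) effect `+1.5` per mil, trophic enrichment `+5` per mil,
#' carbonization of plant charcoal `+1` per mil, and the conventional
#' apatite-to-diet enrichment `-9.4` per mil (the first three are
#' literature-printed constants, the last a conventional default).
#'
#' @param which optional character vector selecting a sub-chain, in order.
#' @return Named list of [correction_step()] objects.
#' @export
#' @examples
#' apply_chain(-10, d13c_corrections("suess"))
d13c_corrections <- function(which = NULL) {
  all <- list(
    suess = correction_step("suess", 1, 1.5, "post-industrial fossil fuel"),
    trophic = correction_step("trophic", 1, 5, "diet-to-consumer enrichment"),
    carbonization = correction_step("carbonization", 1, 1,
                                    "charring fractionation"),
    apatite_to_diet = correction_step("apatite_to_diet", 1, -9.4,
                                      "bioapatite-diet spacing")
  )
  if (is.null(which)) return(all)
  missing <- setdiff(which, names(all))
  if (length(missing))
    stop("unknown correction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  all[which]
}

#' Read a declarative correction-chain configuration
#'
#' Accepts a data frame (or CSV path) with columns `name`, `slope`,
#' `intercept` and returns the corresponding ordered chain, so that the
#' default chains can be swapped for project-specific fractionation
#' equations without code changes.
#'
#' @param x data frame or path to a CSV file.
#' @return List of [correction_step()] objects in row order.
#' @export
read_chain_config <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("name", "slope", "intercept")
  if (!all(need %in% names(x)))
    stop("chain config needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(x)), function(i)
    correction_step(x$name[i], x$slope[i], x$intercept[i]))
}
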