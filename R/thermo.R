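#' Convert a fractional Lo intensity to a partitioning free energy
#'
#' The partitioning free energy of a membrane-anchored construct between the
#' liquid-ordered (Lo) and liquid-disordered (Ld) phases is defined from its
#' fractional Lo fluorescence intensity \eqn{f = I_{Lo}/(I_{Lo}+I_{Ld})} as
#' \deqn{\Delta G_{p,Lo} = -\ln\frac{f}{1-f}}
#' in units of \eqn{k_B T} (natural logarithm).  Negative values indicate a
#' preference for the Lo phase; \eqn{f = 0.5} maps to \eqn{\Delta G = 0}
#' (no partitioning).
#'
#' @param f numeric vector of fractional Lo intensities, strictly inside
#'   (0, 1).
#' @return numeric vector of free energies in kBT units.
#' @seealso [dG_to_fraction()] for the inverse map.
#' @examples
#' fraction_to_dG(0.6)   # ~ -0.41 kBT, marginal Lo preference
#' fraction_to_dG(0.5)   # exactly 0
#' @export
fraction_to_dG <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("`f` must be finite and lie in [0, 1]", call. = FALSE)
  }
  if (any(f == 0 | f == 1)) {
    stop("unbounded free energy: `f` must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  -log(f / (1 - f))
}

#' Convert a partitioning free energy to a fractional Lo intensity
#'
#' Inverse of [fraction_to_dG()]: \eqn{f = 1/(1 + e^{\Delta G})}, the logistic
#' map.  Exact round-trip with [fraction_to_dG()] to within 1e-12 over
#' f in (0.001, 0.999).
#'
#' @param dG numeric vector of free energies in kBT units.
#' @return numeric vector of fractions in (0, 1).
#' @export
dG_to_fraction <- function(dG) {
  if (!is.numeric(dG) || any(!is.finite(dG))) {
    stop("`dG` must be finite", call. = FALSE)
  }
  1 / (1 + exp(dG))
}

#' Lo:Ld concentration ratio implied by a partitioning free energy
#'
#' Assuming recorded fluorescence intensities are proportional to construct
#' concentrations, a free energy `dG` (kBT) implies an Lo:Ld concentration
#' ratio of \eqn{e^{-\Delta G}}.  Used by the synthetic generator to set the
#' construct-channel contrast between the two membrane arcs.
#'
#' @param dG numeric vector, kBT units.
#' @return numeric vector of Lo:Ld ratios; strictly decreasing in `dG`.
#' @export
intensity_ratio_from_dG <- function(dG) {
  if (!is.numeric(dG) || any(!is.finite(dG))) {
    stop("`dG` must be finite", call. = FALSE)
  }
  exp(-dG)
}

#' Describe a multi-anchor construct design
#'
#' A construct is an ordered inventory of hydrophobic anchor modules, each
#' contributing a per-anchor partitioning free energy (kBT).  Anchor tags
#' follow the field's shorthand: `sC` (single cholesteryl-TEG), `dC` (double
#' cholesteryl), `sT` (single tocopherol).
#'
#' @param name character tag for the construct (e.g. `"dC"`, `"sC+sT"`).
#' @param anchors numeric vector of per-anchor dG contributions in kBT,
#'   optionally named by anchor tag; at least one anchor.
#' @return an object of class `construct_design`.
#' @export
construct_design <- function(name, anchors) {
  if (!is.character(name) || length(name) != 1L) {
    stop("`name` must be a single string", call. = FALSE)
  }
  if (!is.numeric(anchors) || length(anchors) < 1L || any(!is.finite(anchors))) {
    stop("`anchors` must be a non-empty numeric vector of finite dG values",
         call. = FALSE)
  }
  structure(list(name = name, anchors = anchors), class = "construct_design")
}

#' @export
print.construct_design <- function(x, ...) {
  cat("<construct_design> ", x$name, ": ",
      paste(signif(x$anchors, 3), collapse = " + "),
      " = ", signif(sum(x$anchors), 3), " kBT\n", sep = "")
  invisible(x)
}

#' Additive multi-anchor free-energy prediction
#'
#' Predicts the partitioning free energy of a multi-anchor construct as the
#' sum of the per-anchor contributions,
#' \deqn{\Delta G_{pred} = \sum_i \Delta G_i,}
#' the additivity rule that holds in the absence of anchor co-operativity.
#' The prediction is permutation-invariant in anchor order and linear in the
#' contributions.
#'
#' @param design a [construct_design()].
#' @return predicted dG in kBT.
#' @examples
#' predict_additive(construct_design("dC", c(sC = -0.4, sC = -0.4)))  # -0.8
#' @export
predict_additive <- function(design) {
  if (!inherits(design, "construct_design")) {
    stop("`design` must be a construct_design", call. = FALSE)
  }
  sum(design$anchors)
}

#' Deviation of a measured free energy from the additive prediction
#'
#' Returns `measured - predicted` (kBT).  Negative values mean the construct
#' prefers the Lo phase more strongly than the additive rule predicts.
#'
#' @param measured,predicted free energies in kBT.
#' @return nonadditivity in kBT.
#' @export
nonadditivity <- function(measured, predicted) {
  if (any(!is.finite(measured)) || any(!is.finite(predicted))) {
    stop("inputs must be finite", call. = FALSE)
  }
  measured - predicted
}

#' Default anchor free-energy library
#'
#' Per-anchor partitioning free energies (kBT, ternary
#' DOPC/DPPC/cholesterol-type membranes) measured for single-anchor
#' constructs: cholesteryl-TEG `sC` (-0.4), double-cholesteryl `dC` (-0.8),
#' tocopherol `sT` (+1.9).  These ship as overridable defaults; quaternary
#' or otherwise different lipid mixtures require user-supplied tables.
#'
#' @return data.frame with columns `tag`, `dG`, `note`.
#' @export
default_anchor_library <- function() {
  data.frame(
    tag  = c("sC", "dC", "sT"),
    dG   = c(-0.4, -0.8, 1.9),
    note = c("single cholesteryl-TEG, ternary mixture",
             "double cholesteryl, ternary mixture",
             "single tocopherol, ternary mixture"),
    stringsAsFactors = FALSE
  )
}

#' Look up an anchor's dG in a library table
#'
#' @param library data.frame with columns `tag` and `dG`.
#' @param tag anchor tag to look up.
#' @return dG in kBT.
#' @keywords internal
anchor_dG <- function(library, tag) {
  i <- match(tag, library$tag)
  if (is.na(i)) {
    stop("anchor library has no entry for '", tag, "'", call. = FALSE)
  }
  library$dG[i]
}
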