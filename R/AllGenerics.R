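#' @include AllClasses.R
NULL

#' Accessors for localization data
#'
#' \code{coords} and \code{precisions} return the K x D coordinate and
#' precision matrices (nm); \code{channels}, \code{frames} and \code{photons}
#' the per-localization metadata; \code{nLocs} the number of localizations K
#' and \code{locDim} the dimensionality D.
#'
#' @param object a \linkS4class{LocalizationSet} or \linkS4class{Site}.
#' @return matrices / vectors as described; scalars for \code{nLocs},
#'   \code{locDim}.
#' @name locdata-accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname locdata-accessors
#' @export
setGeneric("precisions", function(object) standardGeneric("precisions"))

#' @rdname locdata-accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))

#' @rdname locdata-accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname locdata-accessors
#' @export
setGeneric("photons", function(object) standardGeneric("photons"))

#' @rdname locdata-accessors
#' @export
setGeneric("nLocs", function(object) standardGeneric("nLocs"))

#' @rdname locdata-accessors
#' @export
setGeneric("locDim", function(object) standardGeneric("locDim"))

#' Site accessors
#'
#' @param object a \linkS4class{Site}.
#' @return \code{localizations}: the contained
#'   \linkS4class{LocalizationSet} (site-local coordinates);
#'   \code{siteSide}: the box side length d in nm; \code{siteCenter}: the
#'   original center position.
#' @name site-accessors
#' @export
setGeneric("localizations", function(object) standardGeneric("localizations"))

#' @rdname site-accessors
#' @export
setGeneric("siteSide", function(object) standardGeneric("siteSide"))

#' @rdname site-accessors
#' @export
setGeneric("siteCenter", function(object) standardGeneric("siteCenter"))

#' FitResult accessors
#'
#' @param object a \linkS4class{FitResult}.
#' @return \code{estimates}: named numeric parameter estimates;
#'   \code{maxLogLik}: the maximized log-likelihood; \code{confint95}: 95\%
#'   confidence intervals (matrix with columns lo, hi).
#' @name fitresult-accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname fitresult-accessors
#' @export
setGeneric("maxLogLik", function(object) standardGeneric("maxLogLik"))

#' @rdname fitresult-accessors
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))

#' Corrected Akaike information criterion
#'
#' For a fit with maximum log-likelihood lnL, P free parameters and sample
#' size K (the number of localizations): \code{AIC = 2 P - 2 lnL} and
#' \code{AICc = AIC + (2 P^2 + 2 P) / (K - P - 1)}. For visual comparison the
#' AICc is additionally normalized by K. Lower values indicate the better
#' model when fitting the same data. Requires \code{K > P + 1}.
#'
#' @param object either the maximum log-likelihood (a scalar) or a
#'   \linkS4class{FitResult}.
#' @param nParams number of free parameters P (scalar method only).
#' @param nLocs sample size K (scalar method only).
#' @param ... unused.
#' @return a list with elements \code{aic}, \code{aicc}, \code{aiccPerLoc}.
#' @examples
#' aicc(-10, nParams = 2, nLocs = 10)  # aic 24, aicc 24 + 12/7
#' @export
setGeneric("aicc", function(object, ...) standardGeneric("aicc"))

## ---- basic methods ---------------------------------------------------------

#' @rdname locdata-accessors
setMethod("coords", "LocalizationSet", function(object) object@coords)
#' @rdname locdata-accessors
setMethod("precisions", "LocalizationSet", function(object) object@precisions)
#' @rdname locdata-accessors
setMethod("channels", "LocalizationSet", function(object) object@channel)
#' @rdname locdata-accessors
setMethod("frames", "LocalizationSet", function(object) object@frame)
#' @rdname locdata-accessors
setMethod("photons", "LocalizationSet", function(object) object@photons)
#' @rdname locdata-accessors
setMethod("nLocs", "LocalizationSet", function(object) nrow(object@coords))
#' @rdname locdata-accessors
setMethod("locDim", "LocalizationSet", function(object) ncol(object@coords))

#' @rdname locdata-accessors
setMethod("coords", "Site", function(object) object@localizations@coords)
#' @rdname locdata-accessors
setMethod("precisions", "Site",
          function(object) object@localizations@precisions)
#' @rdname locdata-accessors
setMethod("nLocs", "Site", function(object) nrow(object@localizations@coords))
#' @rdname locdata-accessors
setMethod("locDim", "Site", function(object) ncol(object@localizations@coords))
#' @rdname site-accessors
setMethod("localizations", "Site", function(object) object@localizations)
#' @rdname site-accessors
setMethod("siteSide", "Site", function(object) object@sideLength)
#' @rdname site-accessors
setMethod("siteCenter", "Site", function(object) object@center)

#' @rdname fitresult-accessors
setMethod("estimates", "FitResult", function(object) object@estimates)
#' @rdname fitresult-accessors
setMethod("maxLogLik", "FitResult", function(object) object@maxLogLik)
#' @rdname fitresult-accessors
setMethod("confint95", "FitResult", function(object) object@ci95)

setMethod("show", "LocalizationSet", function(object) {
  cat(sprintf("LocalizationSet: %d localizations, %dD, %d channel(s)\n",
              nLocs(object), locDim(object),
              length(unique(object@channel))))
  if (nLocs(object) > 0) {
    rng <- apply(object@coords, 2, range)
    cat(sprintf("  coordinate range [nm]: %s\n",
                paste(sprintf("[%.1f, %.1f]", rng[1, ], rng[2, ]),
                      collapse = " x ")))
    cat(sprintf("  median precision [nm]: %s\n",
                paste(sprintf("%.2f", apply(object@precisions, 2, median)),
                      collapse = ", ")))
  }
})

setMethod("show", "Site", function(object) {
  cat(sprintf("Site '%s': d = %.0f nm, K = %d localizations (%dD)\n",
              if (length(object@id)) object@id else "?",
              object@sideLength, nLocs(object), locDim(object)))
})

setMethod("show", "GeometricModel", function(object) {
  cat(sprintf("GeometricModel '%s' (%s, %dD)\n", object@name, object@kind,
              object@dim))
  if (length(object@params)) {
    pn <- names(object@params)
    cat("  intrinsic parameters:\n")
    for (p in pn)
      cat(sprintf("    %-10s = %-10.4g in [%g, %g]\n", p,
                  as.numeric(object@params[[p]]), object@lower[[p]],
                  object@upper[[p]]))
  }
})

setMethod("show", "Pose", function(object) {
  cat(sprintf(paste0("Pose: x0 = (%.1f, %.1f, %.1f) nm, angles = ",
                     "(%.3f, %.3f, %.3f) rad,\n      scale = (%g, %g, %g), ",
                     "eps = %.2f nm, w_bg = %.3f\n"),
              object@x0[1], object@x0[2], object@x0[3],
              object@angles[1], object@angles[2], object@angles[3],
              object@scale[1], object@scale[2], object@scale[3],
              object@extraSigma, object@bgWeight))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: LL = %.4f, P = %d free parameters, K = %d\n",
              object@maxLogLik, object@nParams, object@nLocs))
  cat(sprintf("  AIC = %.3f, AICc = %.3f (%.5f per localization)\n",
              object@aic, object@aicc, object@aiccPerLoc))
  est <- object@estimates[object@freeNames]
  has_ci <- nrow(object@ci95) == length(est)
  for (i in seq_along(est)) {
    if (has_ci)
      cat(sprintf("  %-10s = %10.4f  [%.4f, %.4f]\n", names(est)[i], est[i],
                  object@ci95[i, 1], object@ci95[i, 2]))
    else
      cat(sprintf("  %-10s = %10.4f\n", names(est)[i], est[i]))
  }
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "Template", function(object) {
  cat(sprintf("Template: %d fused localizations, score = %.2f, %d iterations\n",
              nLocs(object@localizations), object@score, object@iterations))
})

setMethod("show", "DistortionModel", function(object) {
  cat(sprintf(
    "DistortionModel: s(z) = %.3g z^2 + %.3g z + %.3g, E(s) = %.1f nm, z0 = %.1f nm\n",
    object@coef[1], object@coef[2], object@coef[3],
    object@expectedSeparation, object@z0))
})
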