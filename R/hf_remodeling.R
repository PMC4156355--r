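# Heart-failure ionic remodeling profiles.
#
# The homogeneous profile rescales a fixed set of currents/fluxes identically
# in every cell class (AP prolongation, depressed SERCA, enhanced NCX and SR
# leak, reduced I_to/I_K1/I_NaK, late Na+ current up-regulation).  The
# heterogeneous variants start from the homogeneous profile and override the
# Na+/Ca2+ exchanger and/or SERCA factors with transmurally graded values
# (NCX: 2.0x epi, 1.6x M and endo; SERCA: 0.75x epi, 0.60x M, 0.45x endo).
# Factors are shipped as a structured key-value file (extdata) so they are
# data, not code.

#' Supported remodeling modes
#' @export
REMODELING_MODES <- c("CONTROL", "HF_HOMOG", "HF_HET_NCX", "HF_HET_SERCA",
                      "HF_HET_BOTH")

.remodeling_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "hf_remodeling_factors.json",
                          package = "hfstrand")
      cache <<- jsonlite::fromJSON(path)
    }
    cache
  }
})

# map from factor names (as in the remodeling tables) to model parameters
.gpb_factor_map <- list(
  I_NaL = "GNaL", tau_hL = "tau_hL", I_to = c("GtoSlow", "GtoFast"),
  I_K1 = "GK1", I_NaK = "IbarNaK", I_Nab = "GNaB", I_Cab = "GCaB",
  I_NCX = "IbarNCX", J_SERCA = "Vmax_SERCA", I_leak = "leak_const",
  EC_50SR = "EC50_SR")

.ord_factor_map <- list(
  I_NaL = "GNaL", tau_hL = "tau_hL", I_to = "Gto", I_K1 = "GK1",
  I_NaK = "Pnak", I_Nab = "PNab", I_NCX = "Gncx", J_SERCA = "Jup_base",
  I_leak = "leak_base", CaMKa = "CaMK_scale", Jrel_NP_Ca_sens = "Jrel_EC50")

#' Build a heart-failure remodeling profile
#'
#' Assembles the table of dimensionless scale factors for the requested model
#' and remodeling mode.  `HF_HET_*` modes start from the homogeneous
#' heart-failure profile and replace only the heterogeneous entries (`I_NCX`
#' and/or `J_SERCA`) by class-resolved factors.
#'
#' @param model_id `"GPB"` or `"ORd"`.
#' @param mode One of `"CONTROL"`, `"HF_HOMOG"`, `"HF_HET_NCX"`,
#'   `"HF_HET_SERCA"`, `"HF_HET_BOTH"`.
#' @return A `remodeling_profile`: list with `model_id`, `mode` and
#'   `factors`, a named list whose entries are either a single factor or a
#'   named vector with one factor per cell class (`ENDO`, `MID`, `EPI`).
#' @examples
#' pr <- build_profile("GPB", "HF_HOMOG")
#' pr$factors$J_SERCA   # 0.5: SERCA maximum uptake rate halved
#' @export
build_profile <- function(model_id, mode = "CONTROL") {
  model_id <- match.arg(model_id, c("GPB", "ORd"))
  if (!mode %in% REMODELING_MODES) {
    stop("unknown remodeling mode: ", mode, call. = FALSE)
  }
  tab <- .remodeling_tables()[[model_id]]
  homog <- as.list(tab$homogeneous)
  if (mode == "CONTROL") {
    factors <- lapply(homog, function(x) 1.0)
  } else {
    factors <- homog
    if (mode %in% c("HF_HET_NCX", "HF_HET_BOTH")) {
      factors$I_NCX <- unlist(tab$heterogeneous$I_NCX)
    }
    if (mode %in% c("HF_HET_SERCA", "HF_HET_BOTH")) {
      factors$J_SERCA <- unlist(tab$heterogeneous$J_SERCA)
    }
  }
  structure(list(model_id = model_id, mode = mode, factors = factors),
            class = "remodeling_profile")
}

#' Apply a remodeling profile to an ionic parameter set
#'
#' Multiplies each remodeled parameter by its scale factor, resolving
#' class-specific factors with `cell_class`.  Parameters not named by the
#' profile are returned untouched; the input is not modified.
#'
#' @param params An `ionic_params` vector (see [default_params()]).
#' @param profile A `remodeling_profile` for the same model.
#' @param cell_class Cell class used to resolve heterogeneous factors;
#'   defaults to the class the parameters were built for.
#' @return A new `ionic_params` vector.
#' @export
apply_profile <- function(params, profile,
                          cell_class = attr(params, "cell_class")) {
  stopifnot(inherits(profile, "remodeling_profile"))
  if (attr(params, "model_id") != profile$model_id) {
    stop("profile is for model ", profile$model_id, ", params for ",
         attr(params, "model_id"), call. = FALSE)
  }
  fmap <- if (profile$model_id == "GPB") .gpb_factor_map else .ord_factor_map
  out <- params
  for (nm in names(profile$factors)) {
    if (!nm %in% names(fmap)) {
      stop("factor '", nm, "' has no parameter mapping for model ",
           profile$model_id, call. = FALSE)
    }
    f <- profile$factors[[nm]]
    if (length(f) > 1) {
      if (!cell_class %in% names(f)) {
        stop("heterogeneous factor '", nm, "' defines no value for class ",
             cell_class, call. = FALSE)
      }
      f <- f[[cell_class]]
    }
    targets <- fmap[[nm]]
    if (!all(targets %in% names(out))) {
      stop("parameter(s) ", paste(setdiff(targets, names(out)), collapse = ", "),
           " absent from ", profile$model_id, " registry", call. = FALSE)
    }
    out[targets] <- out[targets] * f
  }
  out
}
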