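#' Default run configuration
#'
#' Nested list of every tunable parameter of the pipeline with its default.
#' See the methods vignette for units and rationale.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    qc = list(
      min_raw_reads        = 1000,
      min_pct_aligned      = 80,
      min_seq_saturation   = 50,
      min_neg_geomean      = 10,
      max_ntc_count        = 60,
      min_nuclei           = 100,
      min_area_um2         = 600,
      probe_ratio_max      = 0.1,
      grubbs_fail_fraction = 0.20,
      grubbs_alpha         = 0.05,
      loq_n_sd             = 2,
      background_min_ratio = 2,
      drop_flagged         = FALSE
    ),
    normalize = list(
      pseudocount    = 1,
      above_loq_only = FALSE
    ),
    enrichment = list(
      alpha     = 0.25,
      r_min     = 0.6,
      min_genes = 2
    ),
    differential = list(
      p_cut      = 0.05,
      log2fc_cut = 0.5,
      fdr_cut    = 0.05,
      var_equal  = FALSE
    ),
    seed = 1L
  )
}

.merge_config <- function(defaults, user, prefix = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      if (!is.list(user[[k]]))
        stop("configuration key ", prefix, k, " must be a section")
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     prefix = paste0(prefix, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML configuration file, fills unspecified fields with the
#' package defaults, and echoes the fully resolved configuration. Unknown
#' keys are an error (no silent typo tolerance).
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @param quiet Suppress the resolved-config echo.
#' @return The resolved configuration list.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(default_config(), user)
  if (!quiet)
    message("resolved configuration:\n", yaml::as.yaml(cfg))
  cfg
}
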