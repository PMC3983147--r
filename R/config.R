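#' Pipeline configuration with documented defaults
#'
#' Collects every tunable threshold used across the pipeline into one named
#' list. Each default reflects either a rule stated by the underlying
#' re-annotation procedure (read filters, replicate thresholds, the Poisson
#' signal-to-noise floor, the >50 bp "significant gap" rule) or a documented
#' package choice where no value is prescribed (cluster gap, motif scan
#' window, internal-priming rule, arm-pair bounds). See the package vignette
#' for the rationale behind each value.
#'
#' @param ... named overrides for any default; unknown names are an error.
#'
#' @return A named list of class `pipeline_config`.
#'
#' @details Key parameters:
#' \describe{
#'   \item{max_indels}{maximum alignment indels tolerated ("fewer than
#'     four"), default 3.}
#'   \item{min_read_length}{minimum read length in bp, default 25
#'     (inclusive comparison).}
#'   \item{min_reads_per_replicate}{minimum 3'-end count at a position in
#'     every required replicate, default 3.}
#'   \item{snr_min}{Poisson signal-to-noise floor (total / sqrt(total)),
#'     default 3; applied in multi-replicate mode only.}
#'   \item{max_cluster_gap}{single-linkage clustering gap in bp, default 25.}
#'   \item{pas_window}{upstream scan window for poly(A)-signal hexamers,
#'     c(min, max) bp from motif 3' end to cleavage site, default c(10, 40).}
#'   \item{min_gap_len}{coverage gap length considered significant,
#'     default 50 bp.}
#'   \item{search_cap}{how far downstream of an annotated 3' end candidate
#'     clusters are sought, default 10000 bp; `baseline_window = 300` bp is
#'     the compatibility mode reproducing window-limited automated
#'     re-annotation.}
#' }
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    ## read filtering
    require_unique          = TRUE,
    max_indels              = 3L,
    min_read_length         = 25L,
    min_mapq                = 20L,
    ## replicate/position filtering
    min_reads_per_replicate = 3L,
    min_replicates          = NA_integer_,  # NA = all replicates
    singleton_mode          = FALSE,
    snr_min                 = 3,
    ## clustering
    max_cluster_gap         = 25L,
    ## poly(A)-signal motif scan
    pas_window              = c(10L, 40L),
    pas_modal_distance      = 19L,
    ## internal priming
    priming_window_down     = 10L,
    priming_min_a_run       = 6L,
    priming_a_fraction      = 0.7,
    ## bridging
    min_gap_len             = 50L,
    unbridged_max           = 500L,
    min_covered_frac        = 0.5,
    terminus_tol            = 10L,
    ## junction support
    min_spanning_reads      = 3L,
    ## downstream search
    search_cap              = 10000L,
    baseline_mode           = FALSE,
    baseline_window         = 300L,
    ## novel-feature separation
    separation_min          = 100L,
    ## sRNA arm pairs
    arm_footprint           = c(18L, 25L),
    arm_gap                 = c(10L, 60L),
    arm_dominance_ratio     = 1.25,
    srna_peak_percentile    = 0.95,
    ## misc
    seed                    = 1L,
    genome_build            = "synthetic"
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("pipeline_config() overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown pipeline_config parameter(s): ",
           paste(unknown, collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "pipeline_config")
}

#' Read or write a pipeline configuration file
#'
#' Configuration round-trips losslessly through YAML: every key written by
#' [write_config()] is restored by [read_config()], and keys absent from the
#' file keep their documented defaults.
#'
#' @param path file path.
#' @param config a `pipeline_config` list.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  template <- pipeline_config()
  vals <- vals[intersect(names(vals), names(template))]
  ## yaml scalarizes length-2 integer vectors fine, but coerce types back
  for (nm in names(vals)) {
    proto <- template[[nm]]
    if (is.integer(proto)) vals[[nm]] <- as.integer(vals[[nm]])
    if (is.logical(proto)) vals[[nm]] <- as.logical(vals[[nm]])
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config with", length(x), "parameters\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
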