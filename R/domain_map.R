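# Residue-range bookkeeping: the domain map names every residue range the
# analyses select (human dynamin-2 numbering, 1-based, no insertion codes).

#' Default dynamin-2 domain map
#'
#' Inclusive residue ranges for the four structural domains and the anchor
#' ranges used by the inter-domain angle and interface analyses.  Every entry
#' can be overridden (e.g. from a YAML run config); ranges are stored as
#' integer vectors of residue numbers.
#'
#' The G-BSE angle is measured at the centroid of residues 291-293 between
#' arms ending at the centroids of 277-285 and 299-306.  The BSE-stalk angle
#' starts at the pooled centroid of the hinge (315-321 and 702-711) with arms
#' to the G-domain center (30-36 and 170-176) and the stalk center (410-422
#' and 610-626).
#'
#' @param overrides named list; each element replaces the default entry.
#'   Ranges may be given as `c(from, to)` pairs, lists of pairs, or explicit
#'   residue vectors.
#' @return object of class `domain_map` (named list of integer vectors).
#' @export
default_domain_map <- function(overrides = NULL) {
  rng <- function(a, b) seq.int(a, b)
  map <- list(
    g_domain     = rng(30, 293),
    bse          = c(rng(1, 29), rng(294, 324), rng(699, 746)),
    stalk        = c(rng(325, 515), rng(601, 698)),
    ph           = rng(516, 600),
    g_bse_vertex = rng(291, 293),
    g_bse_arm1   = rng(277, 285),
    g_bse_arm2   = rng(299, 306),
    hinge        = c(rng(315, 321), rng(702, 711)),
    g_center     = c(rng(30, 36), rng(170, 176)),
    stalk_center = c(rng(410, 422), rng(610, 626)),
    l1ns         = rng(390, 400),
    if2_core     = c(rng(455, 495), rng(660, 690)),
    mutation_site = 465L,
    interface1_anchors = c(330L, 692L))
  if (!is.null(overrides)) {
    for (nm in names(overrides)) map[[nm]] <- as_residue_set(overrides[[nm]])
  }
  for (nm in setdiff(names(map), "mutation_site")) {
    if (length(map[[nm]]) < 1L || any(map[[nm]] < 0L))
      stop("domain map: range '", nm, "' empty or negative", call. = FALSE)
  }
  structure(map, class = "domain_map")
}

# Accept c(from, to), list(c(a,b), c(c,d)) or explicit residue vectors.
as_residue_set <- function(x) {
  if (is.list(x)) return(as.integer(sort(unique(unlist(lapply(x, as_residue_set))))))
  x <- as.integer(x)
  if (length(x) == 2L && x[2L] > x[1L] + 1L) x <- seq.int(x[1L], x[2L])
  sort(unique(x))
}

# Which structural domain does a residue belong to?
domain_of <- function(residue_numbers, map) {
  out <- rep("other", length(residue_numbers))
  for (d in c("g_domain", "bse", "stalk", "ph")) {
    out[residue_numbers %in% map[[d]]] <- d
  }
  out
}

#' Read a run configuration from YAML
#'
#' The YAML file may carry `domain_map` overrides, window specifications
#' (`window: {mode: last_t_ns, value: 500}`), interface/SASA cutoffs and
#' group input paths.  Missing entries fall back to package defaults.
#'
#' @param path YAML file path.
#' @return named list with elements `groups`, `domain_map`, `window`,
#'   `interface_config`, `sasa_config`, `stats_method`, `outdir`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  list(
    groups = y$groups,
    domain_map = default_domain_map(y$domain_map),
    window = if (!is.null(y$window))
      window_spec(y$window$mode, y$window$value) else window_spec("all"),
    interface_config = do.call(interface_config,
                               if (is.null(y$interface)) list() else y$interface),
    sasa_config = do.call(sasa_config, if (is.null(y$sasa)) list() else y$sasa),
    stats_method = if (is.null(y$stats_method)) "kw_dunn" else y$stats_method,
    outdir = if (is.null(y$outdir)) "." else y$outdir,
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
}

#' Empirical maximal per-residue SASA table
#'
#' Theoretical Gly-X-Gly maximum solvent accessibilities (A^2) used to
#' normalize residue SASA values into relative accessibilities.  Users can
#' supply their own table with the same columns (`residue`, `max_sasa_A2`).
#'
#' @param path optional CSV path overriding the packaged table.
#' @return named numeric vector keyed by three-letter residue code.
#' @export
max_sasa_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "max_sasa.csv", package = "dynhelix")
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- stats::setNames(tb$max_sasa_A2, tb$residue)
  if (!all(v > 0)) stop("max SASA table: values must be > 0", call. = FALSE)
  v
}

#' Particle radius table for SASA
#'
#' Van der Waals radii by atom/bead name prefix; coarse-grained beads
#' (`BB`, `SC1`..`SC4`) default to 2.3 Angstrom.
#'
#' @param path optional CSV overriding the packaged table (`name`, `radius_A`).
#' @return named numeric vector.
#' @export
radii_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "radii.csv", package = "dynhelix")
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tb$radius_A, tb$name)
}
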