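#' Desikan-Killiany region atlas
#'
#' Loads the packaged 68-region Desikan-Killiany cortical parcellation
#' (34 regions per hemisphere). Region identifiers follow the FreeSurfer
#' `aparc` names with a `_L` / `_R` hemisphere suffix, ordered left
#' hemisphere alphabetically, then right. This ordering is the frozen
#' node-order contract used by every network and edge index in the package.
#'
#' Columns: `region` (canonical identifier), `fs_name` (FreeSurfer name),
#' `abbrev` (short code, e.g. `ENT_L`), `hemi`, `lobe` (frontal, temporal,
#' parietal, occipital, cingulate, insula) and `class` (primary,
#' association, paralimbic cortex).
#'
#' @return A data.frame with 68 rows, one per cortical region, in canonical
#'   order.
#' @examples
#' atlas <- dk_atlas()
#' nrow(atlas)           # 68
#' head(atlas$abbrev)
#' @export
dk_atlas <- function() {
  path <- system.file("extdata", "dk_atlas.tsv", package = "morphnet",
                      mustWork = TRUE)
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_atlas(atlas)
  atlas
}

validate_atlas <- function(atlas) {
  stopifnot(nrow(atlas) == 68L)
  stopifnot(!anyDuplicated(atlas$region), !anyDuplicated(atlas$abbrev))
  stopifnot(all(atlas$hemi %in% c("L", "R")),
            sum(atlas$hemi == "L") == 34L)
  # left/right mirror: same base names in the same order per hemisphere
  stopifnot(identical(atlas$fs_name[atlas$hemi == "L"],
                      atlas$fs_name[atlas$hemi == "R"]))
  stopifnot(all(atlas$lobe %in% c("frontal", "temporal", "parietal",
                                  "occipital", "cingulate", "insula")))
  stopifnot(all(atlas$class %in% c("primary", "association", "paralimbic")))
  invisible(atlas)
}

#' Canonical morphometric feature names
#'
#' The five regional features used to build individual morphological
#' networks: cortical thickness (mm), gray-matter volume (mm^3), surface
#' area (mm^2), mean curvature (mm^-1) and fold index (unitless).
#'
#' @return Character vector of length 5.
#' @export
morph_features <- function() {
  c("thickness", "volume", "area", "meancurv", "foldind")
}

#' Edge index over the canonical region order
#'
#' Enumerates the 2278 unique region pairs (68 choose 2) of the upper
#' triangle in row-major order: (1,2), (1,3), ..., (1,68), (2,3), ...
#' This ordering is frozen so edge identifiers are reproducible across runs.
#'
#' @param regions Character vector of region identifiers (default the
#'   canonical atlas order).
#' @return data.frame with columns `i`, `j` (integer indices, i < j),
#'   `region_a`, `region_b` and `edge` (string id `"a--b"`).
#' @export
edge_index <- function(regions = dk_atlas()$region) {
  n <- length(regions)
  pairs <- t(utils::combn(n, 2L))
  data.frame(
    i = pairs[, 1L], j = pairs[, 2L],
    region_a = regions[pairs[, 1L]], region_b = regions[pairs[, 2L]],
    edge = paste(regions[pairs[, 1L]], regions[pairs[, 2L]], sep = "--"),
    stringsAsFactors = FALSE
  )
}

#' Reported aberrant-edge table
#'
#' The 52 interregional connections reported as significantly altered
#' between the normal-control and Alzheimer's groups, with the printed
#' group-mean correlations, t values and four-way change classification
#' (decrease/increase in positive/negative correlations). Shipped as a
#' worked example for `classify_edge_change()` and as default implant
#' targets for the synthetic cohort generator.
#'
#' @return data.frame with columns `region_a`, `region_b` (abbreviations),
#'   `r_nc`, `r_ad`, `t`, `change_class`.
#' @export
aberrant_edges <- function() {
  path <- system.file("extdata", "table1_edges.tsv", package = "morphnet",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reported consensus hub tables
#'
#' The published group-consensus hub lists (regions that are an individual
#' hub in at least 30% of a group's subjects), with lobe, cortex class,
#' subject fraction and average betweenness centrality.
#'
#' @param group `"NC"` or `"AD"`.
#' @return data.frame with columns `region`, `lobe`, `class`, `fraction`,
#'   `avg_bc`.
#' @export
reported_hubs <- function(group = c("NC", "AD")) {
  group <- match.arg(group)
  file <- if (group == "NC") "consensus_hubs_nc.tsv" else "consensus_hubs_ad.tsv"
  path <- system.file("extdata", file, package = "morphnet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Synthetic region centroids for viewer export
#'
#' Approximate MNI-like centroid coordinates for the 68 DK regions, used
#' only to lay out BrainNet-Viewer-style `.node` files. These are synthetic
#' stand-ins, not surface-derived measurements.
#'
#' @return data.frame with columns `region`, `x`, `y`, `z` in canonical
#'   region order.
#' @export
dk_centroids <- function() {
  path <- system.file("extdata", "dk_centroids_synthetic.tsv",
                      package = "morphnet", mustWork = TRUE)
  left <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  right <- left
  right$region <- sub("_L$", "_R", right$region)
  right$x <- -right$x
  out <- rbind(left, right)
  atlas <- dk_atlas()
  out <- out[match(atlas$region, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# abbrev -> canonical region id (and identity for canonical ids)
resolve_regions <- function(x, atlas = dk_atlas()) {
  out <- ifelse(x %in% atlas$region, x,
                atlas$region[match(x, atlas$abbrev)])
  if (anyNA(out)) {
    stop("unknown region identifier(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}
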