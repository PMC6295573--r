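#' Specify a synthetic cohort
#'
#' Parameters of the generator that emulates the study's data structure:
#' two groups of subjects, 68 regions with 5 morphometric features each,
#' group-level interregional correlation templates with implanted
#' NC-vs-AD edge differences, and MMSE scores coupled to each subject's
#' realized global efficiency.
#'
#' The generative mechanism is cross-feature correlation: a subject's
#' region-by-feature matrix is drawn so that region rows have the group
#' template as their population correlation, which makes implanted effect
#' sizes directly specifiable in correlation units — exactly the statistic
#' the pipeline analyzes.
#'
#' @param n_nc,n_ad subjects per group (defaults 20/20, the study sizes).
#' @param n_features k, features per region (default 5; larger k is a
#'   convergence-testing device only).
#' @param base_within,base_between template correlations inside/between
#'   lobes before implants (defaults 0.3 / 0.1).
#' @param effect_edges data.frame with `region_a`, `region_b`, `r_nc`,
#'   `r_ad` implant targets; default [aberrant_edges()]. Use
#'   `effect_edges = NULL` explicitly for a null cohort (identical
#'   templates).
#' @param mmse_intercept named vector `c(nc =, ad =)` of group MMSE means
#'   (defaults 29 / 26.3, the reported group averages).
#' @param mmse_slope MMSE points per within-cohort SD of global
#'   efficiency (default 1).
#' @param mmse_sd residual MMSE noise SD (default 1.5).
#' @param mmse_clip score clamp (default `c(20, 30)`, the observed range).
#' @param feature_scale,feature_offset per-feature affine applied to the
#'   raw draws so features carry realistic, non-commensurate units
#'   (thickness ~mm, volume ~mm^3, ...); removed again by z-scoring.
#' @param seed integer seed fixing the whole cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nc = 20L, n_ad = 20L, n_features = 5L,
                        base_within = 0.3, base_between = 0.1,
                        effect_edges = aberrant_edges(),
                        mmse_intercept = c(nc = 29, ad = 26.3),
                        mmse_slope = 1, mmse_sd = 1.5,
                        mmse_clip = c(20, 30),
                        feature_scale = c(0.25, 3000, 1500, 0.05, 2),
                        feature_offset = c(2.5, 10000, 2500, 0.15, 3),
                        seed = NULL) {
  stopifnot(n_nc >= 2L, n_ad >= 2L, n_features >= 2L,
            abs(base_within) < 1, abs(base_between) < 1)
  if (!is.null(effect_edges)) {
    stopifnot(all(c("region_a", "region_b", "r_nc", "r_ad") %in%
                    names(effect_edges)))
    stopifnot(all(abs(effect_edges$r_nc) < 1),
              all(abs(effect_edges$r_ad) < 1))
  }
  structure(
    list(n_nc = as.integer(n_nc), n_ad = as.integer(n_ad),
         n_regions = 68L, n_features = as.integer(n_features),
         base_within = base_within, base_between = base_between,
         effect_edges = effect_edges, mmse_intercept = mmse_intercept,
         mmse_slope = mmse_slope, mmse_sd = mmse_sd, mmse_clip = mmse_clip,
         feature_scale = feature_scale, feature_offset = feature_offset,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Nearest positive-definite repair of a correlation matrix
#'
#' Clips negative eigenvalues to a small floor, reconstructs, and rescales
#' to unit diagonal. The returned matrix is symmetric positive-definite.
#'
#' @param m symmetric matrix with unit diagonal.
#' @param eig_floor eigenvalue floor (default 1e-6).
#' @return repaired correlation matrix.
#' @export
nearest_pd <- function(m, eig_floor = 1e-6) {
  dn <- dimnames(m)
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(m)
  vals <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- stats::cov2cor(out)
  out <- (out + t(out)) / 2
  dimnames(out) <- dn
  out
}

#' Build the group correlation templates
#'
#' Starts from a lobe-block base (one correlation inside lobes, another
#' between), implants the per-edge NC/AD targets, and repairs each
#' template to positive definiteness. Implants moved by more than 0.05
#' during repair are reported with a warning.
#'
#' @param spec a [cohort_spec()].
#' @param atlas atlas data.frame.
#' @return list with `nc`, `ad` (68 x 68 PD correlation matrices) and
#'   `repair_log` (data.frame of implant displacements).
#' @export
make_templates <- function(spec, atlas = dk_atlas()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_regions
  lobes <- atlas$lobe
  base <- matrix(spec$base_between, n, n)
  same_lobe <- outer(lobes, lobes, "==")
  base[same_lobe] <- spec$base_within
  diag(base) <- 1
  dimnames(base) <- list(atlas$region, atlas$region)

  implant <- function(m, col) {
    if (is.null(spec$effect_edges)) return(m)
    a <- resolve_regions(spec$effect_edges$region_a, atlas)
    b <- resolve_regions(spec$effect_edges$region_b, atlas)
    r <- spec$effect_edges[[col]]
    m[cbind(a, b)] <- r
    m[cbind(b, a)] <- r
    m
  }
  t_nc <- nearest_pd(implant(base, "r_nc"))
  t_ad <- nearest_pd(implant(base, "r_ad"))

  repair_log <- NULL
  if (!is.null(spec$effect_edges)) {
    a <- resolve_regions(spec$effect_edges$region_a, atlas)
    b <- resolve_regions(spec$effect_edges$region_b, atlas)
    repair_log <- data.frame(
      region_a = a, region_b = b,
      target_nc = spec$effect_edges$r_nc,
      realized_nc = t_nc[cbind(a, b)],
      target_ad = spec$effect_edges$r_ad,
      realized_ad = t_ad[cbind(a, b)],
      stringsAsFactors = FALSE)
    moved <- pmax(abs(repair_log$target_nc - repair_log$realized_nc),
                  abs(repair_log$target_ad - repair_log$realized_ad))
    if (any(moved > 0.05)) {
      warning("positive-definite repair moved implant(s) by > 0.05: ",
              paste(paste(a, b, sep = "--")[moved > 0.05], collapse = ", "))
    }
  }
  list(nc = t_nc, ad = t_ad, repair_log = repair_log)
}

#' Draw one subject's region-by-feature matrix
#'
#' Model: `X = T^{1/2} Z` with Z a 68 x k matrix of independent standard
#' normals, so region rows have cross-feature correlation structure T and
#' the subject's empirical interregional Pearson matrix is a k-sample
#' estimate of T. With k = 5 this reproduces the very noisy sampling
#' regime of real 5-feature morphometry.
#'
#' @param template PD correlation matrix (68 x 68).
#' @param k features per region.
#' @param sqrt_t optional precomputed symmetric square root of `template`.
#' @return matrix `[68, k]`.
#' @export
sample_subject <- function(template, k, sqrt_t = NULL) {
  if (is.null(sqrt_t)) sqrt_t <- sym_sqrt(template)
  n <- nrow(sqrt_t)
  z <- matrix(stats::rnorm(n * k), n, k)
  x <- sqrt_t %*% z
  rownames(x) <- rownames(template)
  x
}

sym_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Generate a synthetic cohort
#'
#' Draws the full cohort from the spec: raw feature tensor (with
#' per-feature units applied), covariate table (group, age, sex, CDR) and
#' integer MMSE scores coupled to each subject's realized global
#' efficiency computed through the actual pipeline (z-score, network,
#' efficiency). One seed fixes everything, MMSE included.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with `tensor` (raw
#'   [feature_tensor()]), `cohort` (covariate data.frame), `templates`
#'   (from [make_templates()]), `e_global` (per subject) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  run <- function() {
    atlas <- dk_atlas()
    tpl <- suppressWarnings(make_templates(spec, atlas))
    sq_nc <- sym_sqrt(tpl$nc)
    sq_ad <- sym_sqrt(tpl$ad)
    n_tot <- spec$n_nc + spec$n_ad
    group <- rep(c("NC", "AD"), c(spec$n_nc, spec$n_ad))
    subjects <- sprintf("S%03d", seq_len(n_tot))
    k <- spec$n_features
    values <- array(NA_real_, dim = c(n_tot, spec$n_regions, k))
    for (s in seq_len(n_tot)) {
      x <- sample_subject(if (group[s] == "NC") tpl$nc else tpl$ad, k,
                          if (group[s] == "NC") sq_nc else sq_ad)
      # apply per-feature units (recycled if k > 5)
      sc <- rep_len(spec$feature_scale, k)
      of <- rep_len(spec$feature_offset, k)
      values[s, , ] <- sweep(sweep(x, 2, sc, "*"), 2, of, "+")
    }
    feats <- if (k == 5L) morph_features() else paste0("f", seq_len(k))
    tensor <- feature_tensor(values, subjects, atlas$region, feats)

    # realized global efficiency through the real pipeline
    z <- zscore_features(tensor)
    e_glob <- vapply(subjects, function(s)
      global_efficiency(to_weights(build_network(z, s), "abs")),
      numeric(1))

    eg_z <- (e_glob - mean(e_glob)) / stats::sd(e_glob)
    mmse <- ifelse(group == "NC", spec$mmse_intercept[["nc"]],
                   spec$mmse_intercept[["ad"]]) +
      spec$mmse_slope * eg_z + stats::rnorm(n_tot, 0, spec$mmse_sd)
    mmse <- as.integer(round(pmin(pmax(mmse, spec$mmse_clip[1]),
                                  spec$mmse_clip[2])))
    age <- as.integer(round(pmin(pmax(stats::rnorm(n_tot, 73.3, 2.3),
                                      70), 79)))
    sex <- unlist(lapply(c(spec$n_nc, spec$n_ad), function(m)
      sample(rep_len(c("F", "M"), m))))
    cohort <- data.frame(subject = subjects, group = group, age = age,
                         sex = sex, mmse = mmse,
                         cdr = ifelse(group == "NC", 0, 0.5),
                         stringsAsFactors = FALSE)
    structure(list(tensor = tensor, cohort = cohort, templates = tpl,
                   e_global = e_glob, spec = spec),
              class = "synthetic_cohort")
  }
  if (is.null(spec$seed)) run() else with_seed(spec$seed, run())
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d NC + %d AD subjects, %d regions x %d features\n",
              x$spec$n_nc, x$spec$n_ad, x$spec$n_regions,
              x$spec$n_features))
  invisible(x)
}

#' Write a synthetic cohort as an on-disk fixture set
#'
#' Emits the same files the ingest stage reads: wide per-feature TSVs, a
#' long-format TSV, the cohort covariate TSV and a JSON echo of the spec.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_cohort_files <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- write_feature_tables(cohort$tensor, dir)
  long <- file.path(dir, "morphometry_long.tsv")
  write_long_table(cohort$tensor, long)
  cov <- file.path(dir, "cohort.tsv")
  utils::write.table(cohort$cohort, cov, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec_path <- file.path(dir, "cohort_spec.json")
  sp <- cohort$spec
  sp$effect_edges <- NULL  # tabular; re-derivable from the packaged table
  jsonlite::write_json(unclass(sp), spec_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(wide = wide, long = long, cohort = cov, spec = spec_path))
}
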