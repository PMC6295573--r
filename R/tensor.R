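#' Construct a feature tensor
#'
#' A feature tensor holds regional morphometric measurements for a cohort:
#' a 3-axis numeric array `[subject, region, feature]`. The region axis is
#' always aligned to the canonical 68-region atlas order.
#'
#' @param values numeric array `[n_subjects, n_regions, n_features]`, or a
#'   matrix `[region, feature]` for a single subject.
#' @param subjects character vector of subject identifiers.
#' @param regions character vector of region identifiers (canonical order).
#' @param features character vector of feature names.
#' @param standardized logical; TRUE if each (subject, feature) slice has
#'   been z-scored across regions.
#' @return An object of class `feature_tensor`.
#' @export
feature_tensor <- function(values, subjects, regions, features,
                           standardized = FALSE) {
  if (length(dim(values)) == 2L) {
    values <- array(values, dim = c(1L, dim(values)))
  }
  stopifnot(length(dim(values)) == 3L)
  stopifnot(dim(values)[1L] == length(subjects),
            dim(values)[2L] == length(regions),
            dim(values)[3L] == length(features))
  if (length(features) < 2L) {
    stop("feature tensor needs at least 2 features (got ",
         length(features), ")")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at subject '%s', region '%s', feature '%s'",
                 subjects[bad[1L]], regions[bad[2L]], features[bad[3L]]))
  }
  dimnames(values) <- list(subjects, regions, features)
  structure(
    list(values = values, subjects = subjects, regions = regions,
         features = features, standardized = isTRUE(standardized)),
    class = "feature_tensor"
  )
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> %d subjects x %d regions x %d features%s\n",
              length(x$subjects), length(x$regions), length(x$features),
              if (x$standardized) " (z-scored within subject)" else ""))
  cat("features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_tensor <- function(x) dim(x$values)

#' Read wide per-feature morphometry tables
#'
#' Ingests one wide tab-separated table per feature, in the layout produced
#' by FreeSurfer's `aparcstats2table`: a subject column followed by one
#' column per region-measure named `lh_<region>_<meas>` / `rh_<region>_<meas>`
#' (a bare `lh_<region>` is also accepted). All files must cover the same
#' subjects; every atlas region must be present in every file.
#'
#' @param paths named character vector, one TSV path per feature; names are
#'   the feature labels (e.g. `thickness`).
#' @param atlas atlas data.frame from [dk_atlas()].
#' @return A [feature_tensor()] aligned to the canonical region order, with
#'   attribute `"unknown_columns"` listing any ignored columns.
#' @export
read_feature_tables <- function(paths, atlas = dk_atlas()) {
  stopifnot(length(paths) >= 2L, !is.null(names(paths)),
            all(nzchar(names(paths))))
  features <- names(paths)
  tabs <- lapply(paths, function(p)
    utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"))

  subj_col <- function(tab) {
    cand <- intersect(c("subject", "subjects", "id"), tolower(names(tab)))
    if (length(cand)) which(tolower(names(tab)) == cand[1L])[1L] else 1L
  }
  subjects <- NULL
  unknown <- character(0)
  n_regions <- nrow(atlas)
  slices <- vector("list", length(features))

  for (f in seq_along(features)) {
    tab <- tabs[[f]]
    sc <- subj_col(tab)
    subj <- tab[[sc]]
    if (is.null(subjects)) {
      subjects <- subj
    } else if (!setequal(subjects, subj)) {
      stop(sprintf("subject sets differ between feature tables ('%s' vs '%s')",
                   features[1L], features[f]))
    }
    cols <- names(tab)[-sc]
    # accepted names per region: lh_<fs>_<feat>, lh_<fs>, rh_...
    prefix <- ifelse(atlas$hemi == "L", "lh_", "rh_")
    want_full <- paste0(prefix, atlas$fs_name, "_", features[f])
    want_bare <- paste0(prefix, atlas$fs_name)
    hit <- ifelse(want_full %in% cols, want_full,
                  ifelse(want_bare %in% cols, want_bare, NA))
    if (anyNA(hit)) {
      stop(sprintf("feature table '%s' is missing region column(s): %s",
                   features[f],
                   paste(want_full[is.na(hit)], collapse = ", ")))
    }
    unknown <- c(unknown, setdiff(cols, hit))
    m <- matrix(NA_real_, nrow = length(subj), ncol = n_regions)
    for (r in seq_len(n_regions)) {
      v <- suppressWarnings(as.numeric(tab[[hit[r]]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1L]
        stop(sprintf(
          "non-numeric value in feature '%s', subject '%s', column '%s': '%s'",
          features[f], subj[bad], hit[r], tab[[hit[r]]][bad]))
      }
      m[, r] <- v
    }
    rownames(m) <- subj
    slices[[f]] <- m[subjects[order(subjects)], , drop = FALSE]
  }

  subjects <- sort(subjects)
  values <- array(NA_real_,
                  dim = c(length(subjects), n_regions, length(features)))
  for (f in seq_along(features)) values[, , f] <- slices[[f]]
  out <- feature_tensor(values, subjects, atlas$region, features)
  if (length(unknown)) {
    message("ignored unknown column(s): ",
            paste(unique(unknown), collapse = ", "))
  }
  attr(out, "unknown_columns") <- unique(unknown)
  out
}

#' Read or write a long-format morphometry table
#'
#' Long format has columns `subject`, `region`, `feature`, `value` (tab
#' separated). The writer records values at full double precision so the
#' round trip is lossless.
#'
#' @param path file path.
#' @param atlas atlas data.frame from [dk_atlas()].
#' @return `read_long_table()` returns a [feature_tensor()];
#'   `write_long_table()` returns `path` invisibly.
#' @export
read_long_table <- function(path, atlas = dk_atlas()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "region", "feature", "value")
  if (!all(need %in% names(tab))) {
    stop("long table must have columns: ", paste(need, collapse = ", "))
  }
  tab$region <- resolve_regions(tab$region, atlas)
  subjects <- sort(unique(tab$subject))
  features <- unique(tab$feature)
  values <- array(NA_real_, dim = c(length(subjects), nrow(atlas),
                                    length(features)))
  si <- match(tab$subject, subjects)
  ri <- match(tab$region, atlas$region)
  fi <- match(tab$feature, features)
  if (!is.numeric(tab$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$value))))[1L]
    stop(sprintf("non-numeric value at row %d (subject '%s', region '%s')",
                 bad, tab$subject[bad], tab$region[bad]))
  }
  values[cbind(si, ri, fi)] <- tab$value
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing measurement: subject '%s', region '%s', feature '%s'",
                 subjects[bad[1L]], atlas$region[bad[2L]], features[bad[3L]]))
  }
  feature_tensor(values, subjects, atlas$region, features)
}

#' @rdname read_long_table
#' @param tensor a [feature_tensor()].
#' @export
write_long_table <- function(tensor, path) {
  stopifnot(inherits(tensor, "feature_tensor"))
  g <- expand.grid(subject = tensor$subjects, region = tensor$regions,
                   feature = tensor$features, stringsAsFactors = FALSE)
  g$value <- as.vector(tensor$values)
  # full precision for a lossless round trip
  g$value <- sprintf("%.17g", g$value)
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write wide per-feature morphometry tables
#'
#' Inverse of [read_feature_tables()]: one TSV per feature with columns
#' `subject`, `lh_<region>_<feature>`, `rh_<region>_<feature>`.
#'
#' @param tensor a [feature_tensor()].
#' @param dir output directory (created if needed).
#' @param atlas atlas data.frame.
#' @return Named vector of written paths, invisibly.
#' @export
write_feature_tables <- function(tensor, dir, atlas = dk_atlas()) {
  stopifnot(inherits(tensor, "feature_tensor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- ifelse(atlas$hemi == "L", "lh_", "rh_")
  paths <- character(0)
  for (f in seq_along(tensor$features)) {
    feat <- tensor$features[f]
    m <- tensor$values[, , f, drop = FALSE]
    dim(m) <- dim(tensor$values)[1:2]
    df <- data.frame(subject = tensor$subjects, stringsAsFactors = FALSE)
    cols <- paste0(prefix, atlas$fs_name, "_", feat)
    for (r in seq_len(nrow(atlas))) df[[cols[r]]] <- sprintf("%.17g", m[, r])
    p <- file.path(dir, paste0(feat, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[feat] <- p
  }
  invisible(paths)
}

#' Read a cohort covariate table
#'
#' Tab-separated with columns `subject`, `group` (NC/AD), `age`, `sex`
#' (F/M), `mmse` (integer 0-30) and optionally `cdr`. When both `group`
#' and `cdr` are present their consistency is checked (CDR 0 for NC,
#' CDR 0.5 for the early-stage AD group studied here).
#'
#' @param path file path.
#' @return data.frame, one row per subject.
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("subject", "group", "age", "sex", "mmse")
  if (!all(need %in% names(tab))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(tab$group %in% c("NC", "AD")),
            all(tab$sex %in% c("F", "M")))
  if (any(tab$mmse < 0 | tab$mmse > 30)) {
    stop("MMSE scores must lie in 0..30")
  }
  if ("cdr" %in% names(tab)) {
    stopifnot(all(tab$cdr %in% c(0, 0.5, 1, 2, 3)))
    bad <- (tab$group == "NC" & tab$cdr != 0) |
      (tab$group == "AD" & tab$cdr != 0.5)
    if (any(bad)) {
      stop("group/CDR mismatch for subject(s): ",
           paste(tab$subject[bad], collapse = ", "))
    }
  }
  tab
}

#' Z-score features across regions
#'
#' Standardizes measurements so the five features are commensurate inside
#' each subject's region vectors: by default each (subject, feature) slice
#' is centered and scaled across the 68 regions using the sample standard
#' deviation (denominator n - 1). This is required before Pearson network
#' construction because raw feature magnitudes span several orders
#' (thickness in mm vs volume in mm^3).
#'
#' @param tensor a [feature_tensor()]; must not already be standardized.
#' @param scope `"subject"` (default; z across regions within each subject)
#'   or `"cohort"` (z across subjects within each region-feature cell,
#'   offered for cross-subject covariance analyses).
#' @return A standardized [feature_tensor()].
#' @export
zscore_features <- function(tensor, scope = c("subject", "cohort")) {
  stopifnot(inherits(tensor, "feature_tensor"))
  scope <- match.arg(scope)
  if (tensor$standardized) {
    stop("tensor is already standardized")
  }
  v <- tensor$values
  if (scope == "subject") {
    for (s in seq_along(tensor$subjects)) {
      for (f in seq_along(tensor$features)) {
        x <- v[s, , f]
        sdx <- stats::sd(x)
        if (!is.finite(sdx) || sdx == 0) {
          stop(sprintf(
            "constant feature: subject '%s', feature '%s' has zero SD across regions",
            tensor$subjects[s], tensor$features[f]))
        }
        v[s, , f] <- (x - mean(x)) / sdx
      }
    }
  } else {
    for (r in seq_along(tensor$regions)) {
      for (f in seq_along(tensor$features)) {
        x <- v[, r, f]
        sdx <- stats::sd(x)
        if (!is.finite(sdx) || sdx == 0) {
          stop(sprintf(
            "constant across subjects: region '%s', feature '%s' has zero SD",
            tensor$regions[r], tensor$features[f]))
        }
        v[, r, f] <- (x - mean(x)) / sdx
      }
    }
  }
  feature_tensor(v, tensor$subjects, tensor$regions, tensor$features,
                 standardized = TRUE)
}
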